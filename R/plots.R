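#' Forest plot of per-SNP Wald ratios
#'
#' @param data Output of [single_snp_table()] or [leave_one_out()].
#' @param estimate_col,lcl_col,ucl_col,label_col Column names.
#' @return A ggplot object.
#' @export
plot_forest <- function(data, estimate_col = "ratio", lcl_col = "lcl",
                        ucl_col = "ucl", label_col = "rsid") {
  if (!estimate_col %in% names(data) && "beta" %in% names(data)) {
    estimate_col <- "beta"
  }
  if (!label_col %in% names(data) && "omitted" %in% names(data)) {
    label_col <- "omitted"
  }
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data[[estimate_col]],
    y = stats::reorder(.data[[label_col]], .data[[estimate_col]]))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data[[lcl_col]],
                                         xmax = .data[[ucl_col]]),
                            height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Estimate (outcome units per exposure SD)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Funnel plot of ratio precision against the ratio
#'
#' Asymmetry about the pooled estimate suggests directional pleiotropy.
#'
#' @param data Output of [single_snp_table()].
#' @param pooled Optional pooled estimate drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_funnel <- function(data, pooled = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$ratio,
                                          y = .data$precision)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Wald ratio", y = "Precision (1/se)") +
    ggplot2::theme_minimal()
  if (!is.null(pooled)) {
    p <- p + ggplot2::geom_vline(xintercept = pooled, linetype = 2)
  }
  p
}

#' @export
autoplot.mediation_decomp <- function(object, ...) {
  object$component <- factor(object$component,
                             levels = c("total", "direct", "indirect"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta,
                                       y = .data$component)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lcl,
                                         xmax = .data$ucl), height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Effect (kg per exposure SD)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mr_estimate <- function(object, ...) {
  lab <- if ("term" %in% names(object)) {
    paste(object$method, object$term)
  } else {
    object$method
  }
  df <- mutate(as_tibble(object), label = lab)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lcl,
                                         xmax = .data$ucl), height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Estimate", y = NULL) +
    ggplot2::theme_minimal()
}
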