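#' @export
tidy.mr_estimate <- function(x, ...) {
  out <- as_tibble(x)
  if (!"term" %in% names(out)) out$term <- out$exposure
  select(out, "term", "method", estimate = "beta", std.error = "se",
         conf.low = "lcl", conf.high = "ucl", p.value = "pval")
}

#' @export
glance.mr_estimate <- function(x, ...) {
  keep <- intersect(c("method", "k", "Q", "Q_p", "I2", "intercept",
                      "intercept_se", "intercept_p", "cond_F", "Q_A",
                      "n_boot", "seed"), names(x))
  dplyr::distinct(select(as_tibble(x), dplyr::all_of(keep)))
}

#' @export
tidy.mediation_decomp <- function(x, ...) {
  select(as_tibble(x), term = "component", "method", estimate = "beta",
         std.error = "se", conf.low = "lcl", conf.high = "ucl",
         p.value = "pval")
}

#' @export
glance.mediation_decomp <- function(x, ...) {
  tibble(
    arm = attr(x, "arm") %||% unique(x$arm),
    exposure = unique(x$exposure),
    stratum = unique(x$stratum),
    proportion_mediated = attr(x, "proportion_mediated") %||% NA_real_
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat("<mr_estimate>\n")
  NextMethod()
}
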