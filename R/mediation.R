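new_decomp <- function(df, arm) {
  out <- structure(as_tibble(df),
                   class = c("mediation_decomp",
                             class(as_tibble(df))))
  attr(out, "arm") <- arm
  out
}

decomp_row <- function(component, beta, se, method, arm, exposure, stratum) {
  tibble(arm = arm, stratum = stratum, exposure = exposure,
         component = component, beta = beta, se = se,
         lcl = beta - CI_Z * se, ucl = beta + CI_Z * se,
         pval = norm_p(beta, se), method = method)
}

#' Propagation-of-errors standard error for a difference of estimates
#'
#' `sqrt(se_total^2 + se_direct^2)`, assuming zero covariance between the
#' two estimates (as holds for the univariable and multivariable MR
#' estimates computed from shared summary data only approximately, and is
#' the convention for difference-method indirect effects).
#'
#' @param se_total,se_direct Standard errors (non-negative).
#' @return The propagated standard error.
#' @export
propagation_se <- function(se_total, se_direct) {
  check_number(se_total, "se_total", min = 0)
  check_number(se_direct, "se_direct", min = 0)
  sqrt(se_total^2 + se_direct^2)
}

#' Difference-method mediation decomposition for the MR arm
#'
#' Subtracts the direct effect (from multivariable MR) from the total effect
#' (from univariable MR): `indirect = total - direct`, with the indirect SE
#' by [propagation_se()]. The two inputs must refer to the same exposure,
#' stratum and outcome scale.
#'
#' @param total One-row `mr_estimate` (e.g. from [ivw()]).
#' @param direct One-row `mr_estimate` for the same exposure (e.g. the
#'   exposure row of [mvmr_ivw()] or [qhet_estimate()]).
#' @param proportion_mediated Also report `indirect/total` (only when the
#'   total effect is distinguishable from zero, `|total| > 2 se_total`).
#' @return A `mediation_decomp` tibble with rows `total`, `direct`,
#'   `indirect`; attribute `proportion_mediated` when computable.
#' @export
difference_method <- function(total, direct, proportion_mediated = TRUE) {
  if (nrow(total) != 1L || nrow(direct) != 1L) {
    abort("`total` and `direct` must be single estimate rows.")
  }
  if (!identical(total$exposure, direct$exposure) ||
      !identical(total$stratum, direct$stratum)) {
    abort(sprintf(
      "Total (%s/%s) and direct (%s/%s) estimates refer to different %s.",
      total$exposure, total$stratum, direct$exposure, direct$stratum,
      "exposure/stratum pairs"))
  }
  ind_beta <- total$beta - direct$beta
  ind_se <- propagation_se(total$se, direct$se)
  out <- bind_rows(
    decomp_row("total", total$beta, total$se, total$method, "MR",
               total$exposure, total$stratum),
    decomp_row("direct", direct$beta, direct$se, direct$method, "MR",
               total$exposure, total$stratum),
    decomp_row("indirect", ind_beta, ind_se,
               paste0("difference(", total$method, " - ", direct$method, ")"),
               "MR", total$exposure, total$stratum)
  )
  out <- new_decomp(out, "MR")
  if (proportion_mediated && abs(total$beta) > 2 * total$se) {
    attr(out, "proportion_mediated") <- ind_beta / total$beta
  }
  out
}

#' Prepare individual-level phenotypes for the observational arm
#'
#' Grip strength is the maximum recorded value (greater than zero) from
#' either hand, with zeros treated as missing; the exposure is z-scored
#' within stratum; CRP is transformed to the natural log scale (non-positive
#' values dropped with a reason). Rows with any missing analysis variable
#' are dropped and counted.
#'
#' @param raw Tibble of raw phenotypes.
#' @param exposure Name of the exposure column.
#' @param covariates Covariate column names carried through.
#' @param grip_cols Left/right grip columns (default
#'   `c("grip_left", "grip_right")`).
#' @param crp_col CRP column (default `"crp"`).
#' @param stratum_col Optional stratum column for within-stratum
#'   standardisation.
#' @return Tibble with the standardised exposure (original name), `log_crp`,
#'   `grip`, covariates and stratum; attribute `drop_report`.
#' @export
prepare_phenotypes <- function(raw, exposure, covariates = character(),
                               grip_cols = c("grip_left", "grip_right"),
                               crp_col = "crp", stratum_col = NULL) {
  df <- as_tibble(raw)
  for (col in c(exposure, covariates, grip_cols, crp_col, stratum_col)) {
    if (!col %in% names(df)) abort(sprintf("Column `%s` not found.", col))
  }
  left <- df[[grip_cols[1]]]; right <- df[[grip_cols[2]]]
  if (any(left < 0 | right < 0, na.rm = TRUE)) {
    abort("Grip columns must be non-negative.")
  }
  left[left == 0] <- NA; right[right == 0] <- NA
  grip <- pmax(left, right, na.rm = TRUE)
  grip[is.na(left) & is.na(right)] <- NA

  crp <- df[[crp_col]]
  n_crp_nonpos <- sum(crp <= 0, na.rm = TRUE)
  crp[crp <= 0] <- NA

  out <- tibble(.rows = nrow(df))
  out$stratum <- if (is.null(stratum_col)) "combined" else
    as.character(df[[stratum_col]])
  out[[exposure]] <- df[[exposure]]
  out$log_crp <- log(crp)
  out$grip <- grip
  for (cv in covariates) out[[cv]] <- df[[cv]]

  keep <- complete.cases(out)
  n_missing <- sum(!keep) - n_crp_nonpos
  out <- out[keep, , drop = FALSE]
  out <- out |>
    group_by(.data$stratum) |>
    mutate(across(dplyr::all_of(exposure),
                  ~ (.x - mean(.x)) / stats::sd(.x))) |>
    ungroup()
  attr(out, "drop_report") <- tibble(
    reason = c("nonpositive_crp", "missing_values"),
    n = c(n_crp_nonpos, max(n_missing, 0))
  )
  out
}

#' Observational two-regression mediation analysis
#'
#' Fits, by least squares, (i) mediator ~ exposure + covariates, (ii)
#' outcome ~ exposure + mediator + covariates, and the total-effect model
#' outcome ~ exposure + covariates. The direct effect is the exposure
#' coefficient of model (ii), the total effect the exposure coefficient of
#' the total model, and the indirect effect their difference — which, with
#' identical covariate sets, equals the product `a1 * b2` of the
#' exposure -> mediator and mediator -> outcome coefficients exactly (an OLS
#' identity asserted at run time). The indirect SE uses the delta method on
#' the product form.
#'
#' @param data Analysis tibble (e.g. from [prepare_phenotypes()]).
#' @param exposure,mediator,outcome Column names.
#' @param covariates Covariate column names (identical across the three
#'   fits).
#' @param stratum Stratum label for the output rows.
#' @return A `mediation_decomp` tibble (rows total/direct/indirect);
#'   attribute `fits` holds the three `lm` objects, attribute
#'   `product_difference_gap` the assertion residual.
#' @export
observational_mediation <- function(data, exposure, mediator, outcome,
                                    covariates = character(),
                                    stratum = "combined") {
  df <- as_tibble(data)
  n <- nrow(df)
  if (n <= length(covariates) + 3) abort("Too few rows for the fits.")
  rhs <- function(terms) paste(terms, collapse = " + ")
  f_med <- stats::as.formula(paste(mediator, "~",
                                   rhs(c(exposure, covariates))))
  f_out <- stats::as.formula(paste(outcome, "~",
                                   rhs(c(exposure, mediator, covariates))))
  f_tot <- stats::as.formula(paste(outcome, "~",
                                   rhs(c(exposure, covariates))))
  fits <- list(mediator_model = lm(f_med, data = df),
               outcome_model = lm(f_out, data = df),
               total_model = lm(f_tot, data = df))
  for (nm in names(fits)) {
    cf <- coef(fits[[nm]])
    if (anyNA(cf)) {
      abort(paste0("Rank-deficient fit in ", nm, "; aliased column(s): ",
                   paste(names(cf)[is.na(cf)], collapse = ", ")))
    }
  }
  a1 <- coef(fits$mediator_model)[[exposure]]
  se_a1 <- sqrt(diag(vcov(fits$mediator_model))[[exposure]])
  b2 <- coef(fits$outcome_model)[[mediator]]
  se_b2 <- sqrt(diag(vcov(fits$outcome_model))[[mediator]])
  direct <- coef(fits$outcome_model)[[exposure]]
  se_direct <- sqrt(diag(vcov(fits$outcome_model))[[exposure]])
  total <- coef(fits$total_model)[[exposure]]
  se_total <- sqrt(diag(vcov(fits$total_model))[[exposure]])

  indirect <- total - direct
  gap <- abs(indirect - a1 * b2)
  if (gap > 1e-8 * max(1, abs(indirect))) {
    abort("Product-difference identity violated; covariate sets differ?")
  }
  se_indirect <- sqrt(b2^2 * se_a1^2 + a1^2 * se_b2^2)

  out <- bind_rows(
    decomp_row("total", total, se_total, "OLS", "observational",
               exposure, stratum),
    decomp_row("direct", direct, se_direct, "OLS", "observational",
               exposure, stratum),
    decomp_row("indirect", indirect, se_indirect, "delta(product)",
               "observational", exposure, stratum)
  )
  out <- new_decomp(out, "observational")
  attr(out, "fits") <- fits
  attr(out, "product_difference_gap") <- gap
  if (abs(total) > 2 * se_total) {
    attr(out, "proportion_mediated") <- indirect / total
  }
  out
}
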