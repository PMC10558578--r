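# shared internal helpers

CI_Z <- 1.96

norm_p <- function(beta, se) {
  p <- 2 * pnorm(-abs(beta / se))
  p[se <= 0 | !is.finite(beta / se)] <- NA_real_
  p
}

# seed handling: every stochastic routine takes an explicit seed and restores
# the caller's RNG state afterwards
with_seed <- function(seed, code) {
  force(seed)
  withr::with_seed(as.integer(seed), code)
}

check_number <- function(x, name, min = -Inf, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < min) abort(sprintf("`%s` must be >= %s.", name, format(min)))
  invisible(x)
}

new_estimate_tbl <- function(df) {
  structure(as_tibble(df), class = c("mr_estimate", class(as_tibble(df))))
}

estimate_row <- function(method, exposure, stratum, beta, se, k,
                         Q = NA_real_, Q_p = NA_real_, I2 = NA_real_,
                         intercept = NA_real_, intercept_se = NA_real_,
                         intercept_p = NA_real_, pval = NULL,
                         lcl = NULL, ucl = NULL) {
  tibble(
    method = method, exposure = exposure, stratum = stratum,
    beta = beta, se = se,
    lcl = lcl %||% (beta - CI_Z * se), ucl = ucl %||% (beta + CI_Z * se),
    pval = pval %||% norm_p(beta, se),
    k = as.integer(k), Q = Q, Q_p = Q_p, I2 = I2,
    intercept = intercept, intercept_se = intercept_se,
    intercept_p = intercept_p
  )
}

panel_labels <- function(panel) {
  list(
    exposure = attr(panel, "exposure") %||% "exposure",
    mediator = attr(panel, "mediator") %||% "mediator",
    outcome = attr(panel, "outcome") %||% "outcome",
    stratum = attr(panel, "stratum") %||% "combined"
  )
}
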