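#' Per-SNP Wald ratios and inverse-variance weights
#'
#' Ratio `r_j = beta_outcome_j / beta_exposure_j` with first-order standard
#' error `se(r_j) = se_outcome_j / |beta_exposure_j|` and weight
#' `w_j = 1 / se(r_j)^2 = beta_exposure_j^2 / se_outcome_j^2`. SNPs with a
#' zero exposure beta are dropped with a warning (the ratio is undefined).
#'
#' @param panel An `mr_panel` (or data frame with the panel beta/se columns).
#' @return Tibble with `rsid`, `ratio`, `se`, `weight`.
#' @export
wald_ratios <- function(panel) {
  zero <- panel$beta_exposure == 0
  if (any(zero)) {
    warn(sprintf("%d SNP(s) with zero exposure beta dropped from ratios.",
                 sum(zero)))
    panel <- panel[!zero, , drop = FALSE]
  }
  tibble(
    rsid = panel$rsid,
    ratio = panel$beta_outcome / panel$beta_exposure,
    se = panel$se_outcome / abs(panel$beta_exposure),
    weight = panel$beta_exposure^2 / panel$se_outcome^2
  )
}

#' Cochran's Q heterogeneity statistic for Wald ratios
#'
#' `Q = sum w_j (r_j - pooled)^2` on `k - 1` degrees of freedom, with
#' `I^2 = max(0, (Q - df) / Q) * 100`. With fewer than two SNPs a defined
#' null row (all `NA`) is returned rather than an error.
#'
#' @param ratios Output of [wald_ratios()].
#' @param pooled Pooled estimate the ratios are contrasted against (the IVW
#'   estimate in standard use).
#' @return One-row tibble with `Q`, `df`, `I2` (percent), `p`.
#' @export
cochran_q <- function(ratios, pooled) {
  k <- nrow(ratios)
  if (k < 2L) {
    return(tibble(Q = NA_real_, df = NA_integer_, I2 = NA_real_,
                  p = NA_real_))
  }
  Q <- sum(ratios$weight * (ratios$ratio - pooled)^2)
  df <- k - 1L
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  tibble(Q = Q, df = df, I2 = I2, p = pchisq(Q, df, lower.tail = FALSE))
}

#' Inverse-variance-weighted MR estimate (multiplicative random effects)
#'
#' The IVW estimate is the weighted mean of the Wald ratios with weights
#' `beta_exposure^2 / se_outcome^2`. The fixed-effect standard error
#' `1/sqrt(sum w)` is inflated by `max(1, sqrt(Q / (k - 1)))` — the
#' multiplicative random-effects convention under which under-dispersion
#' never shrinks the SE. With one SNP the estimate is the single Wald ratio.
#'
#' @inheritParams wald_ratios
#' @return One-row `mr_estimate` tibble (method `"IVW"`) with `beta`, `se`,
#'   95% CI, `pval`, `k`, `Q`, `Q_p`, `I2`.
#' @export
ivw <- function(panel) {
  lab <- panel_labels(panel)
  r <- wald_ratios(panel)
  k <- nrow(r)
  if (k == 0L) abort("No usable SNPs for IVW.")
  beta <- sum(r$weight * r$ratio) / sum(r$weight)
  se_fe <- 1 / sqrt(sum(r$weight))
  q <- cochran_q(r, beta)
  phi <- if (k >= 2L) max(1, sqrt(q$Q / (k - 1L))) else 1
  out <- new_estimate_tbl(estimate_row(
    "IVW", lab$exposure, lab$stratum, beta, se_fe * phi, k,
    Q = q$Q, Q_p = q$p, I2 = q$I2
  ))
  attr(out, "ratios") <- r
  out
}

orient_positive <- function(panel) {
  neg <- panel$beta_exposure < 0
  for (col in intersect(c("beta_exposure", "beta_mediator", "beta_outcome"),
                        names(panel))) {
    panel[[col]][neg] <- -panel[[col]][neg]
  }
  panel
}

wls_fit <- function(X, y, w) {
  XtW <- t(X * w)
  xtx <- XtW %*% X
  if (rcond_safe(xtx) < 1e-12) abort("Singular weighted design matrix.")
  xtx_inv <- solve(xtx)
  beta <- drop(xtx_inv %*% (XtW %*% y))
  resid <- y - drop(X %*% beta)
  rss_w <- sum(w * resid^2)
  list(beta = beta, cov_unit = xtx_inv, rss_w = rss_w)
}

rcond_safe <- function(m) {
  out <- tryCatch(rcond(m), error = function(e) 0)
  if (!is.finite(out)) 0 else out
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an intercept,
#' weights `1/se_outcome^2`, after orienting every exposure beta to be
#' non-negative (outcome and mediator betas are flipped jointly, so the fit
#' is invariant to per-SNP sign conventions). The slope is the
#' pleiotropy-robust causal estimate under InSIDE; a non-zero intercept
#' indicates directional horizontal pleiotropy. Standard errors use
#' multiplicative random-effects scaling `max(1, sqrt(Q_egger / (k - 2)))`.
#'
#' @inheritParams wald_ratios
#' @return One-row `mr_estimate` tibble (method `"Egger"`) with the slope in
#'   `beta` and the intercept estimate, SE and p-value in the `intercept*`
#'   columns.
#' @export
mr_egger <- function(panel) {
  lab <- panel_labels(panel)
  k <- nrow(panel)
  if (k < 3L) abort("MR-Egger requires at least 3 SNPs.")
  panel <- orient_positive(panel)
  bx <- panel$beta_exposure; by <- panel$beta_outcome
  w <- 1 / panel$se_outcome^2
  if (stats::weighted.mean((bx - stats::weighted.mean(bx, w))^2, w) <
      1e-14 * mean(bx^2)) {
    abort("Singular Egger design: exposure betas are all equal.")
  }
  fit <- wls_fit(cbind(intercept = 1, slope = bx), by, w)
  phi <- max(1, sqrt(fit$rss_w / (k - 2L)))
  ses <- sqrt(diag(fit$cov_unit)) * phi
  out <- new_estimate_tbl(estimate_row(
    "Egger", lab$exposure, lab$stratum, fit$beta[["slope"]], ses[["slope"]],
    k, Q = fit$rss_w, Q_p = pchisq(fit$rss_w, k - 2L, lower.tail = FALSE),
    I2 = if (fit$rss_w > 0) max(0, (fit$rss_w - (k - 2L)) / fit$rss_w) * 100
         else 0,
    intercept = fit$beta[["intercept"]], intercept_se = ses[["intercept"]],
    intercept_p = norm_p(fit$beta[["intercept"]], ses[["intercept"]])
  ))
  out
}

wme_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- weight[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Consistent when SNPs carrying at least half the total weight are valid
#' instruments. The estimate interpolates the inverse-variance-weighted
#' empirical quantile function of the Wald ratios at probability 0.5; the
#' standard error comes from a parametric bootstrap that redraws the per-SNP
#' betas from normals with their stated SEs.
#'
#' @inheritParams wald_ratios
#' @param n_boot Bootstrap iterations (default 2000).
#' @param seed Integer seed for the bootstrap (required).
#' @return One-row `mr_estimate` tibble (method `"WME"`).
#' @export
weighted_median <- function(panel, n_boot = 2000, seed) {
  lab <- panel_labels(panel)
  if (nrow(panel) < 3L) abort("Weighted median requires at least 3 SNPs.")
  if (missing(seed)) abort("`seed` is required for the WME bootstrap.")
  r <- wald_ratios(panel)
  est <- wme_point(r$ratio, r$weight)
  k <- nrow(panel)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    bx <- rnorm(k, panel$beta_exposure, panel$se_exposure)
    by <- rnorm(k, panel$beta_outcome, panel$se_outcome)
    ok <- bx != 0
    wme_point(by[ok] / bx[ok], bx[ok]^2 / panel$se_outcome[ok]^2)
  }, numeric(1)))
  se <- stats::sd(boots)
  out <- new_estimate_tbl(estimate_row("WME", lab$exposure, lab$stratum,
                                       est, se, k))
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Leave-one-out IVW analysis
#'
#' @inheritParams wald_ratios
#' @return Tibble with one IVW estimate row per omitted SNP (column
#'   `omitted`).
#' @export
leave_one_out <- function(panel) {
  if (nrow(panel) < 2L) abort("Leave-one-out requires at least 2 SNPs.")
  purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    sub <- panel[-i, , drop = FALSE]
    for (a in c("exposure", "mediator", "outcome", "stratum")) {
      attr(sub, a) <- attr(panel, a)
    }
    mutate(as_tibble(ivw(sub)), omitted = panel$rsid[i], .before = 1)
  })
}

#' Single-SNP forest and funnel diagnostics table
#'
#' Per-SNP Wald ratio with its 95% CI (forest) and precision `1/se(ratio)`
#' (funnel); plotting is a convenience ([plot_forest()], [plot_funnel()]) —
#' the data are the deliverable.
#'
#' @inheritParams wald_ratios
#' @return Tibble with `rsid`, `ratio`, `se`, `lcl`, `ucl`, `precision`.
#' @export
single_snp_table <- function(panel) {
  r <- wald_ratios(panel)
  mutate(r,
         lcl = .data$ratio - CI_Z * .data$se,
         ucl = .data$ratio + CI_Z * .data$se,
         precision = 1 / .data$se)
}

#' Cook's distance influence diagnostics for the IVW regression
#'
#' Cook's distances from the weighted through-origin IVW regression of
#' outcome betas on exposure betas (weights `1/se_outcome^2`); SNPs with
#' `D > threshold` (default `4/k`) are flagged as high influence.
#'
#' @inheritParams wald_ratios
#' @param threshold Flagging threshold; default `4 / k`.
#' @return Tibble with `rsid`, `cooks_d`, `flagged`.
#' @export
cooks_influence <- function(panel, threshold = NULL) {
  k <- nrow(panel)
  if (k < 3L) abort("Cook's distance needs at least 3 SNPs.")
  threshold <- threshold %||% (4 / k)
  fit <- lm(beta_outcome ~ beta_exposure - 1,
            data = as_tibble(panel)[, c("beta_outcome", "beta_exposure")],
            weights = 1 / panel$se_outcome^2)
  d <- unname(cooks.distance(fit))
  tibble(rsid = panel$rsid, cooks_d = d, flagged = d > threshold)
}

#' Flag SNPs associated with potential confounders (Benjamini-Hochberg)
#'
#' Applies BH step-up across the pooled family of SNP x confounder tests
#' (the more conservative reading per SNP; `scope = "per_confounder"`
#' adjusts within each confounder separately). A SNP is flagged when any of
#' its tests is rejected at the given FDR; re-running MR without flagged
#' SNPs is the caller's step (see [sensitivity_rerun()]).
#'
#' @param assoc Long tibble with columns `rsid`, `confounder`, `pval`
#'   (p-values in (0, 1]).
#' @param fdr False-discovery rate (default 0.05).
#' @param scope `"pooled"` (default) or `"per_confounder"`.
#' @return Character vector of flagged rsids (empty for an empty table).
#' @export
bh_confounder_filter <- function(assoc, fdr = 0.05,
                                 scope = c("pooled", "per_confounder")) {
  scope <- match.arg(scope)
  assoc <- as_tibble(assoc)
  if (nrow(assoc) == 0L) return(character(0))
  if (any(assoc$pval <= 0 | assoc$pval > 1, na.rm = TRUE)) {
    abort("p-values must be in (0, 1].")
  }
  if (scope == "pooled") {
    assoc$p_adj <- p.adjust(assoc$pval, method = "BH")
  } else {
    assoc <- assoc |>
      group_by(.data$confounder) |>
      mutate(p_adj = p.adjust(.data$pval, method = "BH")) |>
      ungroup()
  }
  sort(unique(assoc$rsid[assoc$p_adj <= fdr]))
}
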