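panel_exposure_matrix <- function(panel) {
  if (!"beta_mediator" %in% names(panel)) {
    abort("Multivariable MR needs a panel with mediator columns.")
  }
  cbind(exposure = panel$beta_exposure, mediator = panel$beta_mediator)
}

# drop identically-zero columns (a nested univariable model), then require
# full rank among the remaining exposures
prune_zero_columns <- function(X) {
  zero <- apply(X, 2, function(col) all(col == 0))
  if (any(zero)) {
    inform(paste0("Exposure column(s) identically zero, dropped from the ",
                  "fit: ", paste(colnames(X)[zero], collapse = ", ")))
  }
  X[, !zero, drop = FALSE]
}

check_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[seq(q$rank + 1L, ncol(X))]]
    abort(paste0("Collinear exposure beta matrix; aliased column(s): ",
                 paste(bad, collapse = ", ")))
  }
}

mvmr_core <- function(panel, intercept = FALSE, min_k) {
  k <- nrow(panel)
  if (k < min_k) abort(sprintf("Need at least %d SNPs.", min_k))
  X0 <- prune_zero_columns(panel_exposure_matrix(panel))
  X <- if (intercept) cbind(intercept = 1, X0) else X0
  check_rank(X)
  w <- 1 / panel$se_outcome^2
  fit <- wls_fit(X, panel$beta_outcome, w)
  df <- k - ncol(X0) - if (intercept) 1L else 0L
  phi <- max(1, sqrt(fit$rss_w / df))
  ses <- sqrt(diag(fit$cov_unit)) * phi
  list(beta = fit$beta, se = ses, rss_w = fit$rss_w, df = df, k = k,
       terms = colnames(X), exposures = colnames(X0))
}

mvmr_rows <- function(fit, method, lab, intercept = FALSE) {
  rows <- purrr::map_dfr(fit$exposures, function(trm) {
    estimate_row(method, lab[[trm]] %||% trm, lab$stratum,
                 fit$beta[[trm]], fit$se[[trm]], fit$k,
                 Q = fit$rss_w,
                 Q_p = pchisq(fit$rss_w, fit$df, lower.tail = FALSE),
                 I2 = if (fit$rss_w > 0)
                   max(0, (fit$rss_w - fit$df) / fit$rss_w) * 100 else 0,
                 intercept = if (intercept) fit$beta[["intercept"]]
                             else NA_real_,
                 intercept_se = if (intercept) fit$se[["intercept"]]
                                else NA_real_,
                 intercept_p = if (intercept)
                   norm_p(fit$beta[["intercept"]], fit$se[["intercept"]])
                 else NA_real_)
  })
  rows$term <- fit$exposures
  new_estimate_tbl(dplyr::relocate(rows, "term", .after = "method"))
}

#' Multivariable MR by inverse-variance-weighted regression
#'
#' Weighted regression of the outcome betas on the exposure and mediator
#' betas without an intercept, weights `1/se_outcome^2`, giving each trait's
#' direct effect conditional on the other. Standard errors use
#' multiplicative random-effects scaling on `k - 2` degrees of freedom.
#' Conditional F-statistics and the generalised heterogeneity statistic
#' `Q_A` at the estimate (with zero phenotype correlation) are attached as
#' columns.
#'
#' @param panel An `mr_panel` with exposure, mediator and outcome columns.
#' @return An `mr_estimate` tibble with one row per exposure (column `term`
#'   is `"exposure"`/`"mediator"`), plus `cond_F` and `Q_A` columns.
#' @export
mvmr_ivw <- function(panel) {
  lab <- panel_labels(panel)
  fit <- mvmr_core(panel, intercept = FALSE, min_k = 3L)
  out <- mvmr_rows(fit, "MVMR-IVW", lab)
  if (setequal(fit$exposures, c("exposure", "mediator"))) {
    out$cond_F <- vapply(out$term, function(t) conditional_f(panel, t),
                         numeric(1), USE.NAMES = FALSE)
    th <- setNames(fit$beta[fit$exposures], fit$exposures)
    out$Q_A <- q_a(panel, th[["exposure"]], th[["mediator"]])
  } else {
    out$cond_F <- NA_real_
    out$Q_A <- NA_real_
  }
  out
}

#' Multivariable MR-Egger
#'
#' As [mvmr_ivw()] plus an intercept, fitted after orienting the exposure
#' betas to be non-negative with joint per-SNP sign flips. The intercept
#' p-value is the test for directional horizontal pleiotropy.
#'
#' @inheritParams mvmr_ivw
#' @return An `mr_estimate` tibble with one row per exposure; the
#'   `intercept*` columns are repeated on each row.
#' @export
mvmr_egger <- function(panel) {
  lab <- panel_labels(panel)
  if (nrow(panel) < 4L) abort("MVMR-Egger requires at least 4 SNPs.")
  fit <- mvmr_core(orient_positive(panel), intercept = TRUE, min_k = 4L)
  mvmr_rows(fit, "MVMR-Egger", lab, intercept = TRUE)
}

#' Conditional F-statistic for instrument strength in multivariable MR
#'
#' Two-sample Q-based formulation with the cross-trait sampling covariance
#' fixed at zero (non-overlapping estimation samples):
#' `F_cond = min_delta sum_j (b1_j - delta b2_j)^2 /
#' (se1_j^2 + delta^2 se2_j^2) / (k - 1)` where trait 1 is the exposure of
#' interest and trait 2 the conditioning trait. The minimisation is 1-D
#' numeric (golden-section over `interval`, refined against a coarse grid
#' fallback). When the conditioning betas are identically zero the profile
#' has no regression content and `delta = 0` is used, recovering the
#' univariable mean F.
#'
#' @inheritParams mvmr_ivw
#' @param exposure `"exposure"` (default) or `"mediator"`: whose conditional
#'   strength to compute.
#' @param interval Search interval for `delta` (default `c(-5, 5)`, widened
#'   automatically while the minimiser sits on the boundary).
#' @return The conditional F-statistic (single number).
#' @export
conditional_f <- function(panel, exposure = c("exposure", "mediator"),
                          interval = c(-5, 5)) {
  exposure <- match.arg(exposure)
  other <- setdiff(c("exposure", "mediator"), exposure)
  b1 <- panel[[paste0("beta_", exposure)]]
  s1 <- panel[[paste0("se_", exposure)]]
  b2 <- panel[[paste0("beta_", other)]]
  s2 <- panel[[paste0("se_", other)]]
  k <- length(b1)
  if (k < 3L) abort("Conditional F needs at least 3 SNPs.")
  qfun <- function(d) sum((b1 - d * b2)^2 / (s1^2 + d^2 * s2^2))
  if (all(b2 == 0)) return(qfun(0) / (k - 1L))
  lo <- interval[1]; hi <- interval[2]
  for (i in 1:20) {
    opt <- optimize(qfun, c(lo, hi), tol = 1e-10)
    span <- hi - lo
    on_edge <- min(opt$minimum - lo, hi - opt$minimum) < 1e-3 * span
    if (!on_edge) break
    lo <- lo - span; hi <- hi + span
  }
  # coarse grid fallback guards against local minima
  grid <- seq(lo, hi, length.out = 2001)
  gmin <- grid[which.min(vapply(grid, qfun, numeric(1)))]
  if (qfun(gmin) < opt$objective - 1e-12) {
    opt <- optimize(qfun, c(gmin - diff(range(grid)) / 2000,
                            gmin + diff(range(grid)) / 2000), tol = 1e-10)
  }
  opt$objective / (k - 1L)
}

#' Generalised Cochran's Q for multivariable MR
#'
#' Residual heterogeneity of the outcome betas about the fitted two-exposure
#' model, with per-SNP variances that account for uncertainty in the
#' exposure and mediator betas:
#' `Q_A = sum_j (by_j - tx bx_j - tm bm_j)^2 /
#' (sey_j^2 + tx^2 sex_j^2 + tm^2 sem_j^2 + 2 tx tm rho sex_j sem_j)`.
#' As a rule of thumb values above the number of SNPs indicate weak
#' instruments or pleiotropy.
#'
#' @inheritParams mvmr_ivw
#' @param theta_exposure,theta_mediator Effects at which to evaluate.
#' @param rho Phenotype correlation between exposure and mediator within the
#'   estimation sample: a number in `[-1, 1]` or a
#'   [phenotype_correlation()] object (0 when traits come from
#'   non-overlapping samples).
#' @return The Q_A value (single number).
#' @export
q_a <- function(panel, theta_exposure, theta_mediator, rho = 0) {
  rho <- resolve_rho(rho, panel)
  tx <- theta_exposure; tm <- theta_mediator
  if (!is.finite(tx) || !is.finite(tm)) abort("Thetas must be finite.")
  den <- panel$se_outcome^2 + tx^2 * panel$se_exposure^2 +
    tm^2 * panel$se_mediator^2 +
    2 * tx * tm * rho * panel$se_exposure * panel$se_mediator
  if (any(den <= 0)) {
    abort("Non-positive Q_A variance term; `rho` is not a valid correlation.")
  }
  num <- (panel$beta_outcome - tx * panel$beta_exposure -
            tm * panel$beta_mediator)^2
  sum(num / den)
}

#' Phenotype correlation matrix
#'
#' Small container for the (stratum-specific) phenotype correlation matrix
#' the Q-minimisation weights require; validated for symmetry, unit diagonal
#' and positive semi-definiteness.
#'
#' @param mat Square correlation matrix with trait dimnames.
#' @param stratum Stratum label.
#' @return Object of class `phenotype_correlation`.
#' @export
phenotype_correlation <- function(mat, stratum = "combined") {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) abort("Correlation matrix must be square.")
  if (is.null(rownames(mat))) abort("Correlation matrix needs trait names.")
  if (max(abs(mat - t(mat))) > 1e-8) abort("Correlation matrix must be symmetric.")
  if (max(abs(diag(mat) - 1)) > 1e-8) abort("Diagonal must be 1.")
  if (any(mat < -1 - 1e-8 | mat > 1 + 1e-8)) abort("Entries must be in [-1, 1].")
  if (min(eigen(mat, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("Correlation matrix must be positive semi-definite.")
  }
  structure(list(traits = rownames(mat), mat = mat, stratum = stratum),
            class = "phenotype_correlation")
}

resolve_rho <- function(rho, panel) {
  if (inherits(rho, "phenotype_correlation")) {
    lab <- panel_labels(panel)
    tr <- rho$traits
    i <- if (lab$exposure %in% tr) lab$exposure else "exposure"
    j <- if (lab$mediator %in% tr) lab$mediator else "mediator"
    if (!(i %in% tr && j %in% tr)) {
      abort("Correlation matrix does not cover the panel's traits.")
    }
    return(rho$mat[i, j])
  }
  check_number(rho, "rho")
  if (abs(rho) > 1) abort("`rho` must be in [-1, 1].")
  rho
}

qhet_minimise <- function(panel, rho, start, reltol = 1e-8) {
  obj <- function(th) q_a(panel, th[1], th[2], rho)
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = reltol, maxit = 2000))
  if (opt$convergence != 0) {
    # multi-start coarse grid fallback spanning +-5 start SEs
    sp <- pmax(abs(start), 0.2)
    grid <- expand.grid(tx = start[1] + seq(-5, 5, length.out = 11) * sp[1],
                        tm = start[2] + seq(-5, 5, length.out = 11) * sp[2])
    vals <- apply(grid, 1, function(g) obj(c(g[1], g[2])))
    best <- as.numeric(grid[which.min(vals), ])
    opt2 <- optim(best, obj, method = "Nelder-Mead",
                  control = list(reltol = reltol, maxit = 5000))
    if (opt2$value <= opt$value) opt <- opt2
  }
  opt
}

#' Q-minimisation (Q-het) multivariable MR estimation
#'
#' Robust direct-effect estimation under weak instruments and heterogeneity:
#' the effects are the argmin of the generalised Q statistic [q_a()]
#' (derivative-free simplex started at the MVMR-IVW solution, with a coarse
#' multi-start grid fallback), and confidence intervals are percentile
#' intervals from a parametric bootstrap that redraws every per-SNP beta
#' from a normal with its stated SE and re-minimises each replicate.
#'
#' @inheritParams mvmr_ivw
#' @param rho Phenotype correlation entering the Q_A weights (number or
#'   [phenotype_correlation()]).
#' @param n_boot Bootstrap iterations (default 2000; 0 skips the bootstrap
#'   and reports point estimates with `NA` intervals).
#' @param seed Integer seed (required; results are bit-reproducible).
#' @param reltol Simplex convergence tolerance (default 1e-8).
#' @param max_fail Maximum tolerated fraction of non-converged bootstrap
#'   replicates (default 0.01; more is an error).
#' @return An `mr_estimate` tibble, one row per exposure (method `"Q-het"`),
#'   with percentile `lcl`/`ucl`, bootstrap `se`, and columns `Q_A`
#'   (at the minimum), `n_boot`, `seed`.
#' @export
qhet_estimate <- function(panel, rho = 0, n_boot = 2000, seed,
                          reltol = 1e-8, max_fail = 0.01) {
  lab <- panel_labels(panel)
  if (nrow(panel) < 3L) abort("Q-het needs at least 3 SNPs.")
  if (missing(seed)) abort("`seed` is required for the Q-het bootstrap.")
  rho_v <- resolve_rho(rho, panel)
  ivw_fit <- mvmr_core(panel, intercept = FALSE, min_k = 3L)
  start <- unname(ivw_fit$beta[c("exposure", "mediator")])
  opt <- qhet_minimise(panel, rho_v, start, reltol)
  k <- nrow(panel)

  boot <- with_seed(seed, {
    fails <- 0L
    est <- matrix(NA_real_, max(n_boot, 0L), 2)
    for (b in seq_len(n_boot)) {
      bp <- panel
      bp$beta_exposure <- rnorm(k, panel$beta_exposure, panel$se_exposure)
      bp$beta_mediator <- rnorm(k, panel$beta_mediator, panel$se_mediator)
      bp$beta_outcome <- rnorm(k, panel$beta_outcome, panel$se_outcome)
      ob <- tryCatch(qhet_minimise(bp, rho_v, opt$par, reltol),
                     error = function(e) NULL)
      if (is.null(ob)) fails <- fails + 1L else est[b, ] <- ob$par
    }
    list(est = est, fails = fails)
  })
  if (boot$fails > max_fail * n_boot) {
    abort(sprintf("Q-het bootstrap failed to converge in %d/%d replicates.",
                  boot$fails, n_boot))
  }
  est <- boot$est[complete.cases(boot$est), , drop = FALSE]
  if (nrow(est) >= 2L) {
    ci <- apply(est, 2, stats::quantile, probs = c(0.025, 0.975))
    ses <- apply(est, 2, stats::sd)
  } else {
    ci <- matrix(NA_real_, 2, 2)
    ses <- rep(NA_real_, 2)
  }
  rows <- purrr::map_dfr(1:2, function(i) {
    trm <- c("exposure", "mediator")[i]
    estimate_row("Q-het", lab[[trm]], lab$stratum, opt$par[i], ses[i], k,
                 lcl = ci[1, i], ucl = ci[2, i],
                 pval = norm_p(opt$par[i], ses[i]))
  })
  rows$term <- c("exposure", "mediator")
  out <- new_estimate_tbl(dplyr::relocate(rows, "term", .after = "method"))
  out$Q_A <- opt$value
  out$n_boot <- n_boot
  out$seed <- as.integer(seed)
  attr(out, "rho") <- rho_v
  attr(out, "boot") <- est
  out
}
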