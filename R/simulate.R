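#' Simulation configuration for the exposure-mediator-outcome triangle
#'
#' Defines the generative model used throughout the test-bench: independent
#' Hardy-Weinberg genotypes, an exposure on a standardised (SD) scale, a
#' mediator on a natural-log scale, and an outcome in kg. Defaults mirror a
#' sex-stratified adiposity / C-reactive-protein / grip-strength analysis:
#' 76 exposure SNPs explaining ~2.1% of exposure variance, 88 mediator SNPs
#' explaining ~1.6% of mediator variance, GWAS sample sizes of ~322k
#' (exposure), ~204k (mediator) and ~170k (outcome stratum), an outcome SD of
#' 8.8 kg, and causal structure `theta_dir = 0.5` kg/SD,
#' `theta_xm = 0.4` ln-units/SD, `theta_my = -0.5` kg/ln-unit, implying a
#' total effect of 0.30 kg/SD and an indirect effect of -0.20 kg/SD.
#'
#' @param k_exposure,k_mediator Number of SNPs instrumenting the exposure and
#'   the mediator.
#' @param maf_range Minor-allele-frequency bounds (must lie in (0.01, 0.5)).
#' @param h2_exposure,h2_mediator Variance fractions explained by the SNP
#'   sets.
#' @param theta_xm Exposure -> mediator effect (ln-units per SD).
#' @param theta_dir Direct exposure -> outcome effect (kg per SD).
#' @param theta_my Mediator -> outcome effect (kg per ln-unit).
#' @param pleiotropy Direct SNP -> outcome paths: `"none"`, `"balanced"`
#'   (mean-zero) or `"directional"` (mean `alpha_mean`).
#' @param alpha_mean,alpha_sd Mean and SD of the pleiotropic effects (kg per
#'   allele) when enabled.
#' @param sd_exposure,sd_mediator,sd_outcome Total phenotype SDs.
#' @param n_exposure,n_mediator,n_outcome Estimation sample sizes per trait
#'   (two-sample; non-overlapping).
#' @param n_cohort Individuals per simulated cohort
#'   ([simulate_cohort()] only).
#' @param n_covariates Number of shared covariates (confounders when loaded
#'   on several phenotypes).
#' @param c_x,c_m,c_y Covariate loadings on exposure, mediator, outcome.
#' @param se_exposure,se_mediator,se_outcome Optional SE overrides for
#'   [simulate_sumstats()] (scalar or per-SNP; zero gives the noiseless
#'   limit, negative values error).
#' @param resid_sd_exposure,resid_sd_mediator,resid_sd_outcome Optional
#'   residual-SD overrides for [simulate_cohort()]; by default residual SDs
#'   are derived so each phenotype attains its configured total SD. Zero
#'   gives a noiseless cohort.
#' @param stratum Stratum label.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(k_exposure = 76, k_mediator = 88,
                       maf_range = c(0.05, 0.45),
                       h2_exposure = 0.021, h2_mediator = 0.016,
                       theta_xm = 0.4, theta_dir = 0.5, theta_my = -0.5,
                       pleiotropy = c("none", "balanced", "directional"),
                       alpha_mean = 0.02, alpha_sd = 0.02,
                       sd_exposure = 1, sd_mediator = 1, sd_outcome = 8.8,
                       n_exposure = 322000, n_mediator = 204000,
                       n_outcome = 170000, n_cohort = 20000,
                       n_covariates = 0, c_x = 0, c_m = 0, c_y = 0,
                       se_exposure = NULL, se_mediator = NULL,
                       se_outcome = NULL, resid_sd_exposure = NULL,
                       resid_sd_mediator = NULL, resid_sd_outcome = NULL,
                       stratum = "male") {
  pleiotropy <- match.arg(pleiotropy)
  if (k_exposure < 1 || k_mediator < 0) abort("SNP counts must be >= 1.")
  if (maf_range[1] <= 0.01 || maf_range[2] >= 0.5 ||
      maf_range[1] >= maf_range[2]) {
    abort("`maf_range` must be an increasing interval inside (0.01, 0.5).")
  }
  for (s in c("sd_exposure", "sd_mediator", "sd_outcome")) {
    check_number(get(s), s, min = 1e-12)
  }
  for (s in c("se_exposure", "se_mediator", "se_outcome")) {
    v <- get(s)
    if (!is.null(v) && any(v < 0)) abort(sprintf("`%s` must be >= 0.", s))
  }
  cfg <- list(
    k_exposure = as.integer(k_exposure), k_mediator = as.integer(k_mediator),
    maf_range = maf_range, h2_exposure = h2_exposure,
    h2_mediator = h2_mediator, theta_xm = theta_xm, theta_dir = theta_dir,
    theta_my = theta_my, pleiotropy = pleiotropy, alpha_mean = alpha_mean,
    alpha_sd = alpha_sd, sd_exposure = sd_exposure,
    sd_mediator = sd_mediator, sd_outcome = sd_outcome,
    n_exposure = n_exposure, n_mediator = n_mediator,
    n_outcome = n_outcome, n_cohort = as.integer(n_cohort),
    n_covariates = as.integer(n_covariates), c_x = c_x, c_m = c_m, c_y = c_y,
    se_exposure = se_exposure, se_mediator = se_mediator,
    se_outcome = se_outcome, resid_sd_exposure = resid_sd_exposure,
    resid_sd_mediator = resid_sd_mediator,
    resid_sd_outcome = resid_sd_outcome, stratum = stratum
  )
  structure(cfg, class = "sim_config")
}

sim_truth <- function(cfg, gamma, kappa, alpha) {
  theta_indirect <- cfg$theta_xm * cfg$theta_my
  list(
    gamma = gamma, kappa = kappa, alpha = alpha,
    theta_dir = cfg$theta_dir, theta_xm = cfg$theta_xm,
    theta_my = cfg$theta_my,
    theta_indirect = theta_indirect,
    theta_total = cfg$theta_dir + theta_indirect
  )
}

# draw positive per-allele effects scaled so sum(2 p (1-p) effect^2) = target
draw_effects <- function(k, maf, target_var) {
  if (k == 0L) return(numeric(0))
  raw <- abs(rnorm(k))
  raw <- raw + 0.1 * mean(raw)          # keep effects bounded away from zero
  scale <- sqrt(target_var / sum(2 * maf * (1 - maf) * raw^2))
  raw * scale
}

draw_alpha <- function(cfg, k) {
  switch(cfg$pleiotropy,
         none = rep(0, k),
         balanced = rnorm(k, 0, cfg$alpha_sd),
         directional = rnorm(k, cfg$alpha_mean, cfg$alpha_sd))
}

sim_structure <- function(cfg) {
  k <- cfg$k_exposure + cfg$k_mediator
  maf <- stats::runif(k, cfg$maf_range[1], cfg$maf_range[2])
  gamma <- c(draw_effects(cfg$k_exposure, maf[seq_len(cfg$k_exposure)],
                          cfg$h2_exposure * cfg$sd_exposure^2),
             rep(0, cfg$k_mediator))
  kappa <- c(rep(0, cfg$k_exposure),
             draw_effects(cfg$k_mediator,
                          maf[cfg$k_exposure + seq_len(cfg$k_mediator)],
                          cfg$h2_mediator * cfg$sd_mediator^2))
  alpha <- draw_alpha(cfg, k)
  list(maf = maf, gamma = gamma, kappa = kappa, alpha = alpha,
       rsid = paste0("rs", seq_len(k)),
       role = rep(c("exposure", "mediator"),
                  c(cfg$k_exposure, cfg$k_mediator)))
}

#' Simulate an individual-level cohort with known causal structure
#'
#' Genotypes are independent Binomial(2, maf) draws (Hardy-Weinberg, no LD);
#' phenotypes follow the linear structural model
#' `X = G gamma + C c_x + e_x`, `M = theta_xm X + G kappa + C c_m + e_m`,
#' `Y = theta_dir X + theta_my M + G alpha + C c_y + e_y`, with residual SDs
#' chosen so each phenotype attains its configured total SD. The returned
#' truth record satisfies `theta_total = theta_dir + theta_xm * theta_my`
#' exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the cohort bit for bit.
#' @return A list of class `mr_cohort`: `genotypes` (n x k matrix),
#'   `phenotypes` (tibble with `x`, `m`, `y` and covariates), `maf`, `rsid`,
#'   `snp_role`, `truth`.
#' @export
simulate_cohort <- function(config, seed) {
  cfg <- config
  k <- cfg$k_exposure + cfg$k_mediator
  n <- cfg$n_cohort
  if (n < k + 10) abort("`n_cohort` must be at least the SNP count + 10.")
  with_seed(seed, {
    st <- sim_structure(cfg)
    G <- matrix(rbinom(n * k, 2L, rep(st$maf, each = n)), nrow = n)
    colnames(G) <- st$rsid
    C <- if (cfg$n_covariates > 0) {
      matrix(rnorm(n * cfg$n_covariates), nrow = n)
    } else {
      matrix(0, n, 0)
    }
    cx <- rep_len(cfg$c_x, ncol(C)); cm <- rep_len(cfg$c_m, ncol(C))
    cy <- rep_len(cfg$c_y, ncol(C))
    var_gx <- sum(2 * st$maf * (1 - st$maf) * st$gamma^2)
    sd_ex <- cfg$resid_sd_exposure %||%
      sqrt(max(cfg$sd_exposure^2 - var_gx - sum(cx^2), 0))
    x <- as.vector(G %*% st$gamma) + as.vector(C %*% cx) + rnorm(n, 0, sd_ex)
    var_gm <- sum(2 * st$maf * (1 - st$maf) * st$kappa^2)
    sd_em <- cfg$resid_sd_mediator %||%
      sqrt(max(cfg$sd_mediator^2 - cfg$theta_xm^2 * cfg$sd_exposure^2 -
                 var_gm - sum(cm^2), 0))
    m <- cfg$theta_xm * x + as.vector(G %*% st$kappa) +
      as.vector(C %*% cm) + rnorm(n, 0, sd_em)
    var_sys <- stats::var(cfg$theta_dir * x + cfg$theta_my * m)
    sd_ey <- cfg$resid_sd_outcome %||%
      sqrt(max(cfg$sd_outcome^2 - var_sys - sum(cy^2), 0))
    y <- cfg$theta_dir * x + cfg$theta_my * m + as.vector(G %*% st$alpha) +
      as.vector(C %*% cy) + rnorm(n, 0, sd_ey)
    pheno <- tibble(x = x, m = m, y = y)
    if (ncol(C) > 0) {
      colnames(C) <- paste0("c", seq_len(ncol(C)))
      pheno <- dplyr::bind_cols(pheno, as_tibble(C))
    }
    structure(list(genotypes = G, phenotypes = pheno, maf = st$maf,
                   rsid = st$rsid, snp_role = st$role,
                   truth = sim_truth(cfg, st$gamma, st$kappa, st$alpha),
                   config = cfg, seed = as.integer(seed)),
              class = "mr_cohort")
  })
}

#' @export
print.mr_cohort <- function(x, ...) {
  cat("<mr_cohort> ", nrow(x$genotypes), " individuals x ",
      ncol(x$genotypes), " SNPs\n", sep = "")
  invisible(x)
}

# per-SNP covariate-adjusted regressions via Frisch-Waugh residualisation
per_snp_regression <- function(G, y, C = NULL) {
  n <- length(y)
  p_cov <- 0L
  if (!is.null(C) && ncol(C) > 0) {
    X <- cbind(1, C)
    qrX <- qr(X)
    y <- qr.resid(qrX, y)
    G <- qr.resid(qrX, G)
    p_cov <- ncol(C)
  } else {
    y <- y - mean(y)
    G <- sweep(G, 2, colMeans(G))
  }
  sxx <- colSums(G^2)
  sxy <- as.vector(crossprod(G, y))
  beta <- sxy / sxx
  rss <- sum(y^2) - beta * sxy
  df <- n - 2L - p_cov
  # noiseless fits give rss ~ 0; keep se strictly positive for validity
  se <- pmax(sqrt(pmax(rss / df, 0) / sxx), .Machine$double.xmin)
  pval <- 2 * stats::pt(-abs(beta / se), df)
  list(beta = beta, se = se, pval = pval)
}

#' Estimate per-SNP summary statistics from a simulated cohort
#'
#' Runs one covariate-adjusted simple linear regression per SNP and trait,
#' each within its own (by default disjoint) subsample — the two-sample
#' design that fixes cross-trait sampling covariance at zero.
#'
#' @param cohort An `mr_cohort`.
#' @param split Named list of row-index vectors, one per trait in
#'   `c("exposure", "mediator", "outcome")`; must be pairwise disjoint unless
#'   `allow_overlap = TRUE`.
#' @param covariates Character vector of cohort covariate columns to adjust
#'   for.
#' @param allow_overlap Permit overlapping subsamples (default `FALSE`).
#' @return Named list of summary-statistics tibbles (exposure, mediator,
#'   outcome).
#' @export
cohort_to_sumstats <- function(cohort, split, covariates = character(),
                               allow_overlap = FALSE) {
  trait_col <- c(exposure = "x", mediator = "m", outcome = "y")
  miss <- setdiff(names(trait_col), names(split))
  if (length(miss)) {
    abort(paste0("`split` must name index sets for: ",
                 paste(miss, collapse = ", ")))
  }
  if (!allow_overlap) {
    pairs <- utils::combn(names(trait_col), 2, simplify = FALSE)
    for (p in pairs) {
      if (length(intersect(split[[p[1]]], split[[p[2]]]))) {
        abort(sprintf("Subsamples for %s and %s overlap.", p[1], p[2]))
      }
    }
  }
  C_all <- if (length(covariates)) {
    as.matrix(cohort$phenotypes[, covariates, drop = FALSE])
  } else {
    NULL
  }
  out <- lapply(names(trait_col), function(nm) {
    idx <- split[[nm]]
    G <- cohort$genotypes[idx, , drop = FALSE]
    y <- cohort$phenotypes[[trait_col[[nm]]]][idx]
    C <- if (!is.null(C_all)) C_all[idx, , drop = FALSE] else NULL
    fit <- per_snp_regression(G, y, C)
    sumstats(tibble(
      rsid = cohort$rsid, chrom = "1",
      pos = seq_along(cohort$rsid) * 1e6,
      ea = "A", oa = "G", eaf = colMeans(G) / 2,
      beta = fit$beta, se = fit$se,
      pval = pmin(pmax(fit$pval, 1e-300), 1),
      n = length(idx)
    ), trait = nm, stratum = cohort$config$stratum)
  })
  setNames(out, names(trait_col))
}

#' Simulate two-sample summary statistics directly (fast path)
#'
#' Composes the true per-SNP associations implied by the structural model —
#' `beta_exposure = gamma`, `beta_mediator = theta_xm * gamma + kappa`,
#' `beta_outcome = theta_dir * gamma + theta_my * (theta_xm * gamma + kappa)
#' + alpha` — and draws the observed estimates independently per trait from
#' normals with the configured standard errors (by default the large-sample
#' GWAS values `sd_trait / sqrt(2 maf (1 - maf) n_trait)`). Setting an SE
#' override to zero yields the noiseless limit.
#'
#' @inheritParams simulate_cohort
#' @return List with `panel` (an `mr_panel` carrying `snp_role`) and `truth`.
#' @export
simulate_sumstats <- function(config, seed) {
  cfg <- config
  with_seed(seed, {
    st <- sim_structure(cfg)
    k <- length(st$maf)
    beta_x <- st$gamma
    beta_m <- cfg$theta_xm * st$gamma + st$kappa
    beta_y <- cfg$theta_dir * st$gamma + cfg$theta_my * beta_m + st$alpha
    denom <- sqrt(2 * st$maf * (1 - st$maf))
    se_x <- rep_len(cfg$se_exposure %||%
                      (cfg$sd_exposure / (denom * sqrt(cfg$n_exposure))), k)
    se_m <- rep_len(cfg$se_mediator %||%
                      (cfg$sd_mediator / (denom * sqrt(cfg$n_mediator))), k)
    se_y <- rep_len(cfg$se_outcome %||%
                      (cfg$sd_outcome / (denom * sqrt(cfg$n_outcome))), k)
    if (any(se_x < 0) || any(se_m < 0) || any(se_y < 0)) {
      abort("Standard errors must be non-negative.")
    }
    panel <- as_panel(tibble(
      rsid = st$rsid, ea = "A", oa = "G", eaf = st$maf,
      beta_exposure = beta_x + rnorm(k) * se_x, se_exposure = se_x,
      beta_mediator = beta_m + rnorm(k) * se_m, se_mediator = se_m,
      beta_outcome = beta_y + rnorm(k) * se_y, se_outcome = se_y,
      snp_role = st$role
    ), stratum = cfg$stratum)
    truth <- sim_truth(cfg, st$gamma, st$kappa, st$alpha)
    truth$beta_exposure <- beta_x
    truth$beta_mediator <- beta_m
    truth$beta_outcome <- beta_y
    list(panel = panel, truth = truth)
  })
}

#' Restrict a panel to the exposure's own instruments
#'
#' The univariable (total-effect) analysis uses only SNPs selected for the
#' exposure; the multivariable analysis uses the full union panel.
#'
#' @param panel An `mr_panel` with an `snp_role` column.
#' @param role Role to keep (default `"exposure"`).
#' @return The subset panel (attributes preserved).
#' @export
panel_subset_role <- function(panel, role = "exposure") {
  if (!"snp_role" %in% names(panel)) {
    abort("Panel has no `snp_role` column.")
  }
  out <- panel[panel$snp_role == role, , drop = FALSE]
  for (a in c("exposure", "mediator", "outcome", "stratum")) {
    attr(out, a) <- attr(panel, a)
  }
  out
}
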