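test_that("IVW matches the closed-form weighted mean and Q", {
  # oracle: beta = sum(bx*by/se^2)/sum(bx^2/se^2) = 390/1400, Q by hand
  p <- make_panel(bx = c(0.1, 0.2, 0.3), sx = 0.01,
                  by = c(0.02, 0.05, 0.09), sy = 0.01)
  est <- ivw(p)
  expect_equal(est$beta, 390 / 1400, tolerance = 1e-12)
  w <- c(0.1, 0.2, 0.3)^2 / 0.01^2
  r <- c(0.02, 0.05, 0.09) / c(0.1, 0.2, 0.3)
  q_oracle <- sum(w * (r - 390 / 1400)^2)
  expect_equal(est$Q, q_oracle, tolerance = 1e-10)
  expect_equal(est$Q, 1.357, tolerance = 1e-3)
  # multiplicative RE never shrinks below the fixed-effect SE
  expect_gte(est$se, 1 / sqrt(sum(w)))
})

test_that("homogeneous ratios give the common ratio with zero heterogeneity", {
  p <- make_panel(bx = c(0.1, 0.2), sx = 0.01, by = c(0.05, 0.10), sy = 0.01)
  est <- ivw(p)
  expect_equal(est$beta, 0.5, tolerance = 1e-12)
  expect_equal(est$Q, 0, tolerance = 1e-20)
  expect_equal(est$I2, 0)
})

test_that("a single SNP reduces IVW to its Wald ratio", {
  p <- make_panel(bx = 0.1, sx = 0.01, by = 0.03, sy = 0.02)
  est <- ivw(p)
  expect_equal(est$beta, 0.3, tolerance = 1e-12)
  expect_equal(est$se, 0.02 / 0.1, tolerance = 1e-12)
})

test_that("zero exposure betas are dropped with a warning", {
  p <- make_panel(bx = c(0, 0.2), sx = 0.01, by = c(0.05, 0.10), sy = 0.01)
  expect_warning(est <- ivw(p), "zero exposure beta")
  expect_equal(est$k, 1L)
})

test_that("Cochran's Q has the stated df, I2 and p behaviour", {
  p <- make_panel(bx = c(0.1, 0.2, 0.3), sx = 0.01,
                  by = c(0.02, 0.05, 0.09), sy = 0.01)
  r <- wald_ratios(p)
  pooled <- ivw(p)$beta
  q <- cochran_q(r, pooled)
  expect_equal(q$df, 2L)
  expect_equal(q$p, pchisq(q$Q, 2, lower.tail = FALSE))
  # homogeneous ratios: Q = 0, I2 = 0, p = 1
  ph <- make_panel(bx = c(0.1, 0.2), sx = 0.01, by = c(0.05, 0.1), sy = 0.01)
  qh <- cochran_q(wald_ratios(ph), 0.5)
  expect_equal(qh$Q, 0, tolerance = 1e-20)
  expect_equal(qh$I2, 0)
  expect_equal(qh$p, 1)
  # k < 2 is a defined null, not an error
  q1 <- cochran_q(wald_ratios(make_panel(0.1, 0.01, 0.05, 0.01)), 0.5)
  expect_true(is.na(q1$Q))
})

test_that("Cochran's Q is calibrated under the null", {
  # exact null: fixed exposure betas, outcome betas normal about theta*bx
  set.seed(42)
  k <- 20; reps <- 500
  bx <- seq(0.05, 0.24, length.out = k); sy <- 0.01; theta <- 0.3
  rej <- vapply(seq_len(reps), function(r) {
    by <- rnorm(k, theta * bx, sy)
    p <- make_panel(bx, 1e-8, by, sy)
    cochran_q(wald_ratios(p), ivw(p)$beta)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("MR-Egger recovers an exact line and matches the WLS oracle", {
  # collinear construction: by = 0.01 + 0.3 * bx exactly
  bx <- c(0.1, 0.15, 0.2, 0.3)
  p <- make_panel(bx, 0.01, 0.01 + 0.3 * bx, 0.01)
  est <- mr_egger(p)
  expect_equal(est$beta, 0.3, tolerance = 1e-10)
  expect_equal(est$intercept, 0.01, tolerance = 1e-10)

  # noisy 4-point weighted fit against the normal-equations oracle
  set.seed(7)
  by <- 0.01 + 0.3 * bx + rnorm(4, 0, 0.01)
  sy <- c(0.01, 0.02, 0.01, 0.03)
  p2 <- make_panel(bx, 0.01, by, sy)
  est2 <- mr_egger(p2)
  o <- wls_oracle(cbind(1, bx), by, 1 / sy^2)
  expect_equal(est2$beta, unname(o$beta[2]), tolerance = 1e-12)
  expect_equal(est2$intercept, unname(o$beta[1]), tolerance = 1e-12)
  phi <- max(1, sqrt(o$rss_w / 2))
  expect_equal(est2$se, sqrt(o$cov_unit[2, 2]) * phi, tolerance = 1e-12)
})

test_that("jointly negating a SNP leaves the Egger fit unchanged", {
  set.seed(8)
  bx <- abs(rnorm(6, 0.15, 0.05))
  by <- 0.02 + 0.4 * bx + rnorm(6, 0, 0.01)
  p <- make_panel(bx, 0.01, by, 0.01)
  base <- mr_egger(p)
  p2 <- p
  p2$beta_exposure[3] <- -p2$beta_exposure[3]
  p2$beta_outcome[3] <- -p2$beta_outcome[3]
  flipped <- mr_egger(p2)
  expect_equal(flipped$beta, base$beta, tolerance = 1e-12)
  expect_equal(flipped$intercept, base$intercept, tolerance = 1e-12)
})

test_that("Egger guards on k and on a degenerate design", {
  expect_error(mr_egger(make_panel(c(0.1, 0.2), 0.01, c(0.1, 0.2), 0.01)),
               "at least 3")
  expect_error(mr_egger(make_panel(rep(0.1, 4), 0.01,
                                   c(0.02, 0.03, 0.04, 0.05), 0.01)),
               "Singular")
})

test_that("weighted median interpolates the weighted ratio quantile", {
  # equal weights: the middle ratio
  p <- make_panel(bx = c(1, 1, 1), sx = 0.01, by = c(0.1, 0.2, 0.9),
                  sy = 0.1)
  est <- weighted_median(p, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.2, tolerance = 1e-12)
  # >= 50% of weight at a common ratio pins the estimate there
  p2 <- make_panel(bx = c(2, 2, 2, 0.5, 0.5), sx = 0.01,
                   by = c(0.6, 0.6, 0.6, 0.45, 0.05), sy = 0.1)
  est2 <- weighted_median(p2, n_boot = 50, seed = 1)
  expect_equal(est2$beta, 0.3, tolerance = 1e-12)
})

test_that("weighted median matches a brute-force interpolation oracle", {
  set.seed(9)
  bx <- abs(rnorm(7, 0.2, 0.05)); by <- rnorm(7, 0.3 * bx, 0.02)
  sy <- runif(7, 0.01, 0.05)
  p <- make_panel(bx, 0.01, by, sy)
  est <- weighted_median(p, n_boot = 50, seed = 2)
  ratio <- by / bx; w <- bx^2 / sy^2
  ord <- order(ratio); r <- ratio[ord]; ws <- w[ord]
  s <- (cumsum(ws) - ws / 2) / sum(ws)
  below <- max(which(s < 0.5)); above <- min(which(s >= 0.5))
  oracle <- r[below] + (r[above] - r[below]) * (0.5 - s[below]) /
    (s[above] - s[below])
  expect_equal(est$beta, oracle, tolerance = 1e-12)
})

test_that("the WME bootstrap is seed-reproducible and requires a seed", {
  p <- make_panel(bx = c(0.1, 0.15, 0.2, 0.25), sx = 0.01,
                  by = c(0.03, 0.05, 0.06, 0.07), sy = 0.01)
  e1 <- weighted_median(p, n_boot = 100, seed = 5)
  e2 <- weighted_median(p, n_boot = 100, seed = 5)
  expect_identical(e1$se, e2$se)
  expect_error(weighted_median(p, n_boot = 10), "seed")
})

test_that("leave-one-out equals IVW on the explicit subsets", {
  set.seed(10)
  bx <- abs(rnorm(5, 0.2, 0.05)); by <- rnorm(5, 0.3 * bx, 0.02)
  p <- make_panel(bx, 0.01, by, 0.01)
  loo <- leave_one_out(p)
  expect_equal(nrow(loo), 5L)
  for (i in 1:5) {
    sub <- make_panel(bx[-i], 0.01, by[-i], 0.01,
                      rsid = paste0("rs", seq_len(5))[-i])
    expect_equal(loo$beta[loo$omitted == paste0("rs", i)], ivw(sub)$beta,
                 tolerance = 1e-12)
  }
  # k = 2: each row is the other SNP's Wald ratio
  p2 <- make_panel(c(0.1, 0.2), 0.01, c(0.05, 0.08), 0.01)
  loo2 <- leave_one_out(p2)
  expect_equal(loo2$beta, c(0.08 / 0.2, 0.05 / 0.1), tolerance = 1e-12)
})

test_that("the single-SNP table carries forest and funnel columns", {
  p <- make_panel(bx = c(0.1, 0.2, 0.4), sx = 0.01,
                  by = c(0.03, 0.05, 0.1), sy = 0.02)
  tab <- single_snp_table(p)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$precision, abs(c(0.1, 0.2, 0.4)) / 0.02,
               tolerance = 1e-12)
  expect_equal(tab$ucl - tab$ratio, 1.96 * tab$se, tolerance = 1e-12)
})

test_that("funnel asymmetry is absent under balanced pleiotropy", {
  set.seed(12)
  reps <- 300
  slopes <- vapply(seq_len(reps), function(r) {
    k <- 30
    bx <- abs(rnorm(k, 0.2, 0.05))
    alpha <- rnorm(k, 0, 0.01)          # balanced: mean zero
    by <- 0.3 * bx + alpha + rnorm(k, 0, 0.01)
    tab <- single_snp_table(make_panel(bx, 1e-6, by, 0.01))
    coef(lm(ratio ~ precision, data = tab))[["precision"]]
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 3 * mcse(slopes))
})

test_that("Cook's distances match the textbook oracle and flag outliers", {
  set.seed(13)
  bx <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  by <- 0.3 * bx + rnorm(5, 0, 0.005)
  sy <- c(0.01, 0.02, 0.01, 0.015, 0.01)
  p <- make_panel(bx, 0.01, by, sy)
  d <- cooks_influence(p)
  # textbook oracle for weighted through-origin regression
  w <- 1 / sy^2
  bhat <- sum(w * bx * by) / sum(w * bx^2)
  h <- w * bx^2 / sum(w * bx^2)
  e <- by - bhat * bx
  s2 <- sum(w * e^2) / (5 - 1)
  oracle <- (w * e^2 / (1 * s2)) * h / (1 - h)^2
  expect_equal(d$cooks_d, oracle, tolerance = 1e-10)

  # a gross outlier at the high-leverage point attains the maximum distance
  by2 <- by; by2[5] <- by2[5] + 0.5
  d2 <- cooks_influence(make_panel(bx, 0.01, by2, sy))
  expect_equal(which.max(d2$cooks_d), 5L)
  expect_true(d2$flagged[5])
})

test_that("balanced duplicated points share one Cook's distance", {
  # equal leverage, residuals equal in magnitude: all D identical
  p <- make_panel(bx = rep(0.2, 4), sx = 0.01,
                  by = c(0.07, 0.07, 0.05, 0.05), sy = 0.01)
  d <- cooks_influence(p)
  expect_equal(d$cooks_d, rep(d$cooks_d[1], 4), tolerance = 1e-10)
})

test_that("BH confounder filtering follows the step-up oracle", {
  # explicit BH step-up on p = (0.001, 0.01, 0.02, 0.04, 0.9), m = 5:
  # thresholds i/m * 0.05; largest i with p_(i) <= thr is 4 => reject 4
  assoc <- tibble::tibble(
    rsid = paste0("rs", 1:5), confounder = "smoking",
    pval = c(0.001, 0.01, 0.02, 0.04, 0.9)
  )
  flagged <- bh_confounder_filter(assoc)
  expect_setequal(flagged, paste0("rs", 1:4))
  # all p = 1: nothing; all p -> 0: everything
  expect_length(bh_confounder_filter(dplyr::mutate(assoc, pval = 1)), 0L)
  expect_setequal(bh_confounder_filter(dplyr::mutate(assoc, pval = 1e-12)),
                  assoc$rsid)
  # empty table: empty flag list
  expect_length(bh_confounder_filter(assoc[0, ]), 0L)
  # a SNP is flagged if any of its confounder tests rejects
  assoc2 <- dplyr::bind_rows(assoc,
                             tibble::tibble(rsid = "rs5",
                                            confounder = "alcohol",
                                            pval = 1e-10))
  expect_true("rs5" %in% bh_confounder_filter(assoc2))
})

test_that("negating all outcome betas negates every estimator", {
  set.seed(14)
  bx <- abs(rnorm(6, 0.2, 0.05)); by <- rnorm(6, 0.3 * bx, 0.02)
  p <- make_panel(bx, 0.01, by, 0.01)
  pn <- p; pn$beta_outcome <- -pn$beta_outcome
  expect_equal(ivw(pn)$beta, -ivw(p)$beta, tolerance = 1e-12)
  expect_equal(ivw(pn)$se, ivw(p)$se, tolerance = 1e-12)
  expect_equal(mr_egger(pn)$beta, -mr_egger(p)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(pn)$se, mr_egger(p)$se, tolerance = 1e-12)
  w1 <- weighted_median(p, n_boot = 50, seed = 3)
  w2 <- weighted_median(pn, n_boot = 50, seed = 3)
  expect_equal(w2$beta, -w1$beta, tolerance = 1e-12)
})

test_that("IVW recovers the total effect on pleiotropy-free panels", {
  cfg <- sim_config()                    # 76 exposure instruments
  reps <- 300
  est <- vapply(seq_len(reps), function(r) {
    sim <- simulate_sumstats(cfg, seed = 20000 + r)
    ivw(panel_subset_role(sim$panel))$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.30), 3 * mcse(est))
})

test_that("the Egger intercept recovers directional pleiotropy under InSIDE", {
  cfg <- sim_config(k_mediator = 0, pleiotropy = "directional",
                    alpha_mean = 0.02, alpha_sd = 0.01)
  reps <- 300
  ic <- vapply(seq_len(reps), function(r) {
    sim <- simulate_sumstats(cfg, seed = 30000 + r)
    mr_egger(sim$panel)$intercept
  }, numeric(1))
  expect_lt(abs(mean(ic) - 0.02), 3 * mcse(ic))
})

test_that("WME resists 40% invalid weight where IVW does not", {
  # 40% of the weight carries a +0.5 directional ratio shift; the weighted
  # median stays near the valid ratio (its residual bias scales with the
  # per-ratio SE) while IVW absorbs the full weight-fraction of the shift
  set.seed(15)
  theta <- 0.3; shift <- 0.5
  reps <- 100; k <- 50
  est <- vapply(seq_len(reps), function(r) {
    bx <- rep(0.2, k)
    by <- rnorm(k, theta * bx, 0.005)
    by[1:20] <- by[1:20] + shift * bx[1:20]     # 20/50 = 40% of equal weight
    p <- make_panel(bx, 1e-6, by, 0.005)
    c(wme = wme_point_export(p), ivw = ivw(p)$beta)
  }, numeric(2))
  wme_bias <- mean(est["wme", ]) - theta
  ivw_bias <- mean(est["ivw", ]) - theta
  expect_lt(abs(wme_bias), 0.1 * shift)
  expect_gt(abs(ivw_bias), 0.3 * shift)          # ~ 0.4 * shift in truth
  expect_gt(abs(ivw_bias), 5 * abs(wme_bias))
})
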