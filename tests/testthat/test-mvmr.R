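test_that("MVMR-IVW matches the two-exposure normal-equations oracle", {
  set.seed(20)
  bx <- c(0.10, 0.20, 0.05, 0.15)
  bm <- c(0.02, 0.01, 0.12, 0.08)
  by <- 0.5 * bx - 0.3 * bm + rnorm(4, 0, 0.005)
  sy <- c(0.01, 0.02, 0.01, 0.015)
  p <- make_panel(bx, 0.005, by, sy, bm = bm, sm = 0.005)
  est <- mvmr_ivw(p)
  o <- wls_oracle(cbind(bx, bm), by, 1 / sy^2)
  expect_equal(est$beta[est$term == "exposure"], unname(o$beta[1]),
               tolerance = 1e-12)
  expect_equal(est$beta[est$term == "mediator"], unname(o$beta[2]),
               tolerance = 1e-12)
  phi <- max(1, sqrt(o$rss_w / 2))
  expect_equal(est$se[est$term == "exposure"],
               sqrt(o$cov_unit[1, 1]) * phi, tolerance = 1e-12)
})

test_that("a zero mediator column reduces MVMR-IVW to regression-form IVW", {
  set.seed(21)
  bx <- abs(rnorm(6, 0.2, 0.05))
  by <- rnorm(6, 0.4 * bx, 0.01)
  sy <- runif(6, 0.01, 0.03)
  p <- make_panel(bx, 0.005, by, sy, bm = rep(0, 6), sm = 0.005)
  expect_message(est <- mvmr_ivw(p), "identically zero")
  # univariable IVW in regression (through-origin WLS) form
  o <- wls_oracle(matrix(bx, ncol = 1), by, 1 / sy^2)
  expect_equal(est$beta[est$term == "exposure"], unname(o$beta[1]),
               tolerance = 1e-12)
  # which is algebraically the ratio-form IVW point estimate
  expect_equal(est$beta[est$term == "exposure"], ivw(p)$beta,
               tolerance = 1e-12)
})

test_that("collinear exposure betas are a hard error naming the columns", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  p <- make_panel(bx, 0.005, rnorm(4, 0.1, 0.01), 0.01,
                  bm = 2 * bx, sm = 0.005)
  expect_error(mvmr_ivw(p), "[Cc]ollinear")
})

test_that("MVMR-IVW recovers direct effects on simulated union panels", {
  # instrument arms made precise (large GWAS n) so this checks estimator
  # correctness in the consistency limit; finite-sample attenuation at
  # realistic instrument precision is exercised separately
  cfg <- sim_config(n_exposure = 5e6, n_mediator = 5e6)   # k = 164
  reps <- 200
  est <- vapply(seq_len(reps), function(r) {
    sim <- simulate_sumstats(cfg, seed = 50000 + r)
    e <- mvmr_ivw(sim$panel)
    c(e$beta[e$term == "exposure"], e$beta[e$term == "mediator"])
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 0.5), 3 * mcse(est[1, ]))
  expect_lt(abs(mean(est[2, ]) - (-0.5)), 3 * mcse(est[2, ]))
})

test_that("MVMR-Egger recovers an exact construction with intercept", {
  bx <- c(0.10, 0.20, 0.05, 0.15, 0.25)
  bm <- c(0.02, 0.01, 0.12, 0.08, 0.05)
  by <- 0.05 + 0.5 * bx - 0.3 * bm        # exact plane with intercept
  p <- make_panel(bx, 0.005, by, 0.01, bm = bm, sm = 0.005)
  est <- mvmr_egger(p)
  expect_equal(est$intercept[1], 0.05, tolerance = 1e-10)
  expect_equal(est$beta[est$term == "exposure"], 0.5, tolerance = 1e-10)
  expect_equal(est$beta[est$term == "mediator"], -0.3, tolerance = 1e-10)
})

test_that("MVMR-Egger is invariant to joint per-SNP sign flips", {
  set.seed(22)
  bx <- abs(rnorm(6, 0.2, 0.05))
  bm <- rnorm(6, 0.1, 0.05)
  by <- 0.02 + 0.5 * bx - 0.3 * bm + rnorm(6, 0, 0.005)
  p <- make_panel(bx, 0.005, by, 0.01, bm = bm, sm = 0.005)
  base <- mvmr_egger(p)
  p2 <- p
  for (col in c("beta_exposure", "beta_mediator", "beta_outcome")) {
    p2[[col]][2] <- -p2[[col]][2]
  }
  flipped <- mvmr_egger(p2)
  expect_equal(flipped$beta, base$beta, tolerance = 1e-12)
  expect_equal(flipped$intercept, base$intercept, tolerance = 1e-12)
})

test_that("the MVMR-Egger intercept is calibrated under no pleiotropy", {
  cfg <- sim_config(k_exposure = 30, k_mediator = 30)
  reps <- 200
  z <- vapply(seq_len(reps), function(r) {
    sim <- simulate_sumstats(cfg, seed = 60000 + r)
    e <- mvmr_egger(sim$panel)
    e$intercept[1] / e$intercept_se[1]
  }, numeric(1))
  expect_gt(mean(abs(z) < 3), 0.95)
})

test_that("conditional F matches a dense grid-search oracle", {
  set.seed(23)
  bx <- c(0.10, 0.18, 0.05, 0.15, 0.22)
  bm <- c(0.04, 0.02, 0.10, 0.07, 0.06)
  p <- make_panel(bx, sx = 0.02, by = rnorm(5, 0.1, 0.02), sy = 0.01,
                  bm = bm, sm = 0.03)
  f <- conditional_f(p, "exposure")
  qfun <- function(d) sum((bx - d * bm)^2 / (0.02^2 + d^2 * 0.03^2))
  grid <- seq(-5, 5, by = 1e-4)
  oracle <- min(vapply(grid, qfun, numeric(1))) / 4
  expect_equal(f, oracle, tolerance = 1e-6)
  expect_lte(f, oracle + 1e-10)   # the optimiser can only do better
})

test_that("conditional F reduces to the univariable mean F without a mediator path", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  p <- make_panel(bx, sx = 0.02, by = rep(0.1, 4), sy = 0.01,
                  bm = rep(0, 4), sm = 0.03)
  expect_equal(conditional_f(p, "exposure"),
               sum((bx / 0.02)^2) / 3, tolerance = 1e-12)
})

test_that("conditional F is invariant to joint rescaling of the exposure", {
  set.seed(24)
  bx <- abs(rnorm(5, 0.2, 0.05)); bm <- rnorm(5, 0.1, 0.04)
  p1 <- make_panel(bx, 0.02, rnorm(5, 0.1, 0.02), 0.01, bm = bm, sm = 0.03)
  p2 <- p1
  p2$beta_exposure <- 10 * p2$beta_exposure
  p2$se_exposure <- 10 * p2$se_exposure
  expect_equal(conditional_f(p1, "exposure"), conditional_f(p2, "exposure"),
               tolerance = 1e-6)
})

test_that("Q_A follows the hand-computed two-SNP oracle", {
  p <- make_panel(bx = c(0.1, 0.2), sx = 0.02, by = c(0.08, 0.05),
                  sy = 0.01, bm = c(0.05, 0.03), sm = 0.03)
  tx <- 0.4; tm <- -0.2; rho <- 0.25
  oracle <- sum((c(0.08, 0.05) - tx * c(0.1, 0.2) - tm * c(0.05, 0.03))^2 /
                  (0.01^2 + tx^2 * 0.02^2 + tm^2 * 0.03^2 +
                     2 * tx * tm * rho * 0.02 * 0.03))
  expect_equal(q_a(p, tx, tm, rho = rho), oracle, tolerance = 1e-12)
})

test_that("Q_A vanishes at the generative thetas on noiseless panels", {
  cfg <- sim_config(k_exposure = 6, k_mediator = 5, se_exposure = 0,
                    se_mediator = 0, se_outcome = 0)
  sim <- simulate_sumstats(cfg, seed = 25)
  p <- sim$panel
  p$se_outcome <- rep(0.01, nrow(p))      # positive variance, exact betas
  expect_equal(q_a(p, cfg$theta_dir, cfg$theta_my), 0, tolerance = 1e-18)
})

test_that("mean Q_A on correctly specified noisy panels is about k - 2", {
  cfg <- sim_config(k_exposure = 20, k_mediator = 20)
  reps <- 200
  qa <- vapply(seq_len(reps), function(r) {
    sim <- simulate_sumstats(cfg, seed = 70000 + r)
    qhet_estimate(sim$panel, n_boot = 0, seed = 1)$Q_A[1]
  }, numeric(1))
  expect_lt(abs(mean(qa) - 38), 3 * mcse(qa))
})

test_that("degenerate Q_A variance terms and invalid rho are hard errors", {
  p <- make_panel(bx = c(1, 1, 1), sx = 1, by = c(0.1, 0.2, 0.3),
                  sy = 1e-4, bm = c(1, 1, 1), sm = 1)
  expect_error(q_a(p, 1, 1, rho = 2), "\\[-1, 1\\]")
  p0 <- p
  p0$se_outcome <- rep(0, 3)
  expect_error(q_a(p0, 0, 0), "Non-positive")
})

test_that("the Q-het argmin beats random theta pairs", {
  cfg <- sim_config(k_exposure = 15, k_mediator = 15)
  sim <- simulate_sumstats(cfg, seed = 26)
  qh <- qhet_estimate(sim$panel, n_boot = 20, seed = 27)
  qmin <- qh$Q_A[1]
  set.seed(28)
  for (i in 1:100) {
    expect_gte(q_a(sim$panel, rnorm(1, 0.5, 0.5), rnorm(1, -0.5, 0.5)),
               qmin - 1e-9)
  }
})

test_that("Q-het collapses to MVMR-IVW when exposure-side SEs vanish", {
  cfg <- sim_config(k_exposure = 15, k_mediator = 15)
  sim <- simulate_sumstats(cfg, seed = 29)
  p <- sim$panel
  p$se_exposure <- rep(1e-10, nrow(p))
  p$se_mediator <- rep(1e-10, nrow(p))
  qh <- qhet_estimate(p, n_boot = 20, seed = 30)
  mv <- mvmr_ivw(p)
  expect_equal(qh$beta[qh$term == "exposure"],
               mv$beta[mv$term == "exposure"], tolerance = 1e-6)
  expect_equal(qh$beta[qh$term == "mediator"],
               mv$beta[mv$term == "mediator"], tolerance = 1e-6)
})

test_that("Q-het is bit-reproducible for a fixed seed", {
  cfg <- sim_config(k_exposure = 10, k_mediator = 10)
  sim <- simulate_sumstats(cfg, seed = 31)
  q1 <- qhet_estimate(sim$panel, n_boot = 40, seed = 32)
  q2 <- qhet_estimate(sim$panel, n_boot = 40, seed = 32)
  expect_identical(q1$beta, q2$beta)
  expect_identical(q1$lcl, q2$lcl)
  expect_identical(q1$ucl, q2$ucl)
  expect_error(qhet_estimate(sim$panel, n_boot = 10), "seed")
})

test_that("Q-het is less biased than MVMR-IVW under weak instruments", {
  # conditional F ~ 6: exposure instruments barely separable from the
  # mediator's, mimicking a weak-instrument stratum
  cfg <- sim_config(k_exposure = 28, k_mediator = 28, h2_exposure = 0.015,
                    n_exposure = 20000)
  reps <- 150
  est <- vapply(seq_len(reps), function(r) {
    sim <- simulate_sumstats(cfg, seed = 80000 + r)
    mv <- mvmr_ivw(sim$panel)
    qh <- qhet_estimate(sim$panel, n_boot = 0, seed = 1)
    c(ivw = mv$beta[mv$term == "exposure"],
      qhet = qh$beta[qh$term == "exposure"],
      condf = mv$cond_F[mv$term == "exposure"])
  }, numeric(3))
  expect_lt(mean(est["condf", ]), 15)     # genuinely weak regime
  bias_ivw <- abs(mean(est["ivw", ]) - 0.5)
  bias_qhet <- abs(mean(est["qhet", ]) - 0.5)
  expect_lt(bias_qhet, bias_ivw)
})
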