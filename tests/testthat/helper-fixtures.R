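# fixture builders shared across the suite; everything is generated in code

make_ss <- function(rsid, beta, se, pval = NULL, ea = "A", oa = "G",
                    eaf = 0.3, chrom = "1", pos = NULL, n = 1e5,
                    trait = "trait", stratum = "combined") {
  k <- length(rsid)
  pval <- pval %||% pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  sumstats(tibble::tibble(
    rsid = rsid, chrom = rep_len(chrom, k),
    pos = pos %||% (seq_len(k) * 1e6),
    ea = rep_len(ea, k), oa = rep_len(oa, k), eaf = rep_len(eaf, k),
    beta = beta, se = rep_len(se, k), pval = pval, n = rep_len(n, k)
  ), trait = trait, stratum = stratum)
}

make_panel <- function(bx, sx, by, sy, bm = NULL, sm = NULL,
                       rsid = NULL, stratum = "combined", eaf = 0.3) {
  k <- length(bx)
  df <- tibble::tibble(
    rsid = rsid %||% paste0("rs", seq_len(k)),
    ea = "A", oa = "G", eaf = rep_len(eaf, k),
    beta_exposure = bx, se_exposure = rep_len(sx, k),
    beta_outcome = by, se_outcome = rep_len(sy, k)
  )
  if (!is.null(bm)) {
    df$beta_mediator <- bm
    df$se_mediator <- rep_len(sm, k)
  }
  as_panel(df, stratum = stratum)
}

`%||%` <- rlang::`%||%`

# independent weighted-least-squares oracle via explicit normal equations
wls_oracle <- function(X, y, w) {
  A <- t(X * w) %*% X
  b <- t(X * w) %*% y
  beta <- solve(A, b)
  resid <- y - X %*% beta
  rss_w <- sum(w * resid^2)
  list(beta = drop(beta), cov_unit = solve(A), rss_w = rss_w)
}

# identity-LD matrix over the given rsids with far-apart positions
identity_ld <- function(rsid, pos = NULL) {
  m <- diag(length(rsid))
  dimnames(m) <- list(rsid, rsid)
  ld_matrix(m, pos = setNames(pos %||% (seq_along(rsid) * 1e7), rsid))
}

mcse <- function(x) sd(x) / sqrt(length(x))

# WME point estimate without the bootstrap (for recovery loops)
wme_point_export <- function(panel) {
  r <- wald_ratios(panel)
  mrmediate:::wme_point(r$ratio, r$weight)
}
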