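#' Assemble the multivariable MR instrument panel
#'
#' Implements the joint instrument-selection rule for an exposure-mediator
#' pair: take the union of SNPs reaching genome-wide significance for either
#' trait, clump the union across traits so all retained SNPs are mutually
#' independent, look every retained SNP up in all three summary sets with
#' proxy fallback (r^2 strictly above `proxy_r2_min`, proxy must be present
#' in every trait), drop SNPs unavailable anywhere after the proxy search,
#' and harmonize the result to the exposure's effect-increasing allele.
#'
#' @param exposure,mediator,outcome Full summary-statistics tibbles (the
#'   exposure/mediator sets are also the significance-selection sources; the
#'   outcome set is lookup-only).
#' @param ld `ld_matrix` covering the candidate SNPs.
#' @param p_thr,r2_thr,window_kb Clumping parameters, see [clump()].
#' @param proxy_r2_min Minimum proxy r^2 (strict), see [find_proxies()].
#' @param ambiguity_band Palindromic ambiguity band, see [harmonize()].
#' @return An `mr_panel` with `snp_role` (`"exposure"`/`"mediator"`, by which
#'   trait selected the SNP; union-selected SNPs are labelled `"exposure"`)
#'   and `proxy_for` columns; attribute `assembly_report` is a named list of
#'   per-stage counts satisfying
#'   `n_panel == n_union - n_clumped - n_unavailable - n_dropped_harmonize`.
#' @export
assemble_mvmr_instruments <- function(exposure, mediator, outcome, ld,
                                      p_thr = 5e-8, r2_thr = 0.001,
                                      window_kb = 250, proxy_r2_min = 0.8,
                                      ambiguity_band = c(0.42, 0.58)) {
  exposure <- as_tibble(exposure); mediator <- as_tibble(mediator)
  outcome <- as_tibble(outcome)
  sel_exp <- exposure[exposure$pval < p_thr, ]
  sel_med <- mediator[mediator$pval < p_thr, ]

  # union with the smaller p across source traits driving clump order
  union_df <- bind_rows(
    mutate(sel_exp, snp_role = "exposure"),
    mutate(sel_med, snp_role = "mediator")
  )
  union_df <- union_df[order(union_df$pval), ]
  union_df <- union_df[!duplicated(union_df$rsid), ]
  n_union <- nrow(union_df)

  clumped <- clump(union_df, ld, p_thr = p_thr, r2_thr = r2_thr,
                   window_kb = window_kb)
  n_clumped <- n_union - nrow(clumped)

  traits <- list(exposure = exposure, mediator = mediator, outcome = outcome)
  in_all <- Reduce(intersect, lapply(traits, function(t) t$rsid))
  # proxies must themselves be present in every trait and not already chosen
  proxy_pool_ok <- function(pool) {
    traits$exposure[traits$exposure$rsid %in% pool, ]
  }
  rsid_final <- clumped$rsid
  proxy_for <- setNames(rep(NA_character_, length(rsid_final)), rsid_final)
  missing <- setdiff(rsid_final, in_all)
  n_proxied <- 0L
  if (length(missing)) {
    pool <- setdiff(in_all, rsid_final)
    px <- find_proxies(missing, ld, proxy_pool_ok(pool),
                       r2_min = proxy_r2_min)
    for (i in seq_len(nrow(px))) {
      rs <- px$rsid[i]
      if (!is.na(px$proxy_rsid[i])) {
        j <- match(rs, rsid_final)
        rsid_final[j] <- px$proxy_rsid[i]
        names(proxy_for)[j] <- px$proxy_rsid[i]
        proxy_for[j] <- rs
        n_proxied <- n_proxied + 1L
      }
    }
    unavailable <- setdiff(rsid_final, in_all)
    keep <- !(rsid_final %in% unavailable)
  } else {
    unavailable <- character(0)
    keep <- rep(TRUE, length(rsid_final))
  }
  n_unavailable <- sum(!keep)
  rsid_final <- rsid_final[keep]
  proxy_for <- proxy_for[keep]
  role <- clumped$snp_role[keep]
  if (length(rsid_final) == 0L) {
    abort("Instrument assembly produced an empty panel.")
  }

  sub <- lapply(traits, function(t) {
    s <- t[match(rsid_final, t$rsid), ]
    for (a in c("trait", "stratum")) attr(s, a) <- attr(t, a)
    s
  })
  panel <- harmonize(sub$exposure, sub$outcome, sub$mediator,
                     ambiguity_band = ambiguity_band)
  panel$snp_role <- role[match(panel$rsid, rsid_final)]
  panel$proxy_for <- unname(proxy_for[match(panel$rsid, rsid_final)])
  n_dropped_harmonize <- length(rsid_final) - nrow(panel)

  attr(panel, "assembly_report") <- list(
    n_exposure_selected = nrow(sel_exp),
    n_mediator_selected = nrow(sel_med),
    n_union = n_union,
    n_clumped = n_clumped,
    n_proxied = n_proxied,
    n_unavailable = n_unavailable,
    n_dropped_harmonize = n_dropped_harmonize,
    n_panel = nrow(panel),
    unavailable_rsids = unavailable,
    dropped_harmonize = attr(panel, "dropped")
  )
  panel
}
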