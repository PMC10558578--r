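#' Greedy LD clumping of summary statistics
#'
#' Retains approximately independent genome-wide-significant SNPs: after the
#' p-value filter, SNPs are visited in order of ascending p (ties broken by
#' rsid) and accepted when their r^2 with every already-accepted SNP within
#' the window is below `r2_thr`. Pairs further apart than the window, or on
#' different chromosomes, never clump; when positions are unavailable the r^2
#' check is applied to every pair (conservative).
#'
#' @param ss Summary-statistics tibble.
#' @param ld `ld_matrix` covering the retained rsids.
#' @param p_thr Significance threshold (default genome-wide, 5e-8; strict <).
#' @param r2_thr Independence threshold (default 0.001; accepted iff r^2 <).
#' @param window_kb Window in kilobases within which r^2 is checked
#'   (default 250).
#' @param missing_ld What to do with candidate SNPs absent from `ld`:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @return The retained rows, sorted by ascending p-value, with the input's
#'   attributes; attribute `clump_report` counts drops by reason.
#' @export
clump <- function(ss, ld, p_thr = 5e-8, r2_thr = 0.001, window_kb = 250,
                  missing_ld = c("drop", "error")) {
  missing_ld <- match.arg(missing_ld)
  df <- as_tibble(ss)
  sig <- df[df$pval < p_thr, , drop = FALSE]
  n_failed_p <- nrow(df) - nrow(sig)
  absent <- !(sig$rsid %in% ld$rsids)
  if (any(absent)) {
    if (missing_ld == "error") {
      abort(paste0("SNP(s) absent from LD matrix: ",
                   paste(head(sig$rsid[absent], 5), collapse = ", ")))
    }
    warn(sprintf("%d SNP(s) absent from the LD matrix were dropped.",
                 sum(absent)))
    sig <- sig[!absent, , drop = FALSE]
  }
  sig <- sig[order(sig$pval, sig$rsid), , drop = FALSE]

  pos <- if (all(is.na(sig$pos)) && !is.null(ld$pos)) ld$pos[sig$rsid]
         else sig$pos
  chrom <- sig$chrom
  keep <- logical(nrow(sig))
  kept_idx <- integer(0)
  for (i in seq_len(nrow(sig))) {
    ok <- TRUE
    for (j in kept_idx) {
      in_window <- TRUE
      if (!is.na(pos[i]) && !is.na(pos[j])) {
        same_chr <- is.na(chrom[i]) || is.na(chrom[j]) ||
          chrom[i] == chrom[j]
        in_window <- same_chr && abs(pos[i] - pos[j]) <= window_kb * 1000
      }
      if (in_window &&
          ld$r2[sig$rsid[i], sig$rsid[j]] >= r2_thr) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  out <- sig[keep, , drop = FALSE]
  for (a in c("trait", "stratum")) attr(out, a) <- attr(ss, a)
  attr(out, "clump_report") <- tibble(
    reason = c("failed_p_filter", "absent_from_ld", "clumped"),
    n = c(n_failed_p, sum(absent), sum(!keep))
  )
  out
}

#' Find proxy SNPs for instruments missing from a summary set
#'
#' For each missing rsid, returns the donor SNP with the highest r^2 strictly
#' above `r2_min`; ties are broken by smaller p-value, then lexicographic
#' rsid. Absence of a proxy is a valid outcome (`NA` row), never an error.
#'
#' @param missing Character vector of rsids needing substitutes.
#' @param ld `ld_matrix`.
#' @param donor Summary-statistics tibble in which candidate proxies must be
#'   present.
#' @param r2_min Minimum r^2, strict (default 0.8).
#' @return Tibble with columns `rsid`, `proxy_rsid` (`NA` when none), `r2`.
#' @export
find_proxies <- function(missing, ld, donor, r2_min = 0.8) {
  donor <- as_tibble(donor)
  purrr::map_dfr(missing, function(rs) {
    cand <- setdiff(intersect(donor$rsid, ld$rsids), rs)
    if (!(rs %in% ld$rsids) || length(cand) == 0L) {
      return(tibble(rsid = rs, proxy_rsid = NA_character_, r2 = NA_real_))
    }
    r2 <- ld$r2[rs, cand]
    cand <- cand[r2 > r2_min]
    r2 <- r2[r2 > r2_min]
    if (length(cand) == 0L) {
      return(tibble(rsid = rs, proxy_rsid = NA_character_, r2 = NA_real_))
    }
    p <- donor$pval[match(cand, donor$rsid)]
    ord <- order(-r2, p, cand)
    tibble(rsid = rs, proxy_rsid = cand[ord[1]], r2 = unname(r2[ord[1]]))
  })
}
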