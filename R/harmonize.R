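COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

# classify one trait's allele pair against the reference orientation:
# "keep", "flip", "drop_palindromic", "drop_irreconcilable"
align_action <- function(ref_ea, ref_oa, ea, oa, ref_eaf, eaf, band) {
  pal <- is_palindromic(ref_ea, ref_oa)
  if (pal) {
    same_set <- setequal(c(ea, oa), c(ref_ea, ref_oa)) ||
      setequal(unname(COMPLEMENT[c(ea, oa)]), c(ref_ea, ref_oa))
    if (!same_set) return("drop_irreconcilable")
    # strand is unknowable from the letters; use frequency concordance
    if (is.na(ref_eaf) || is.na(eaf)) return("drop_palindromic")
    if ((ref_eaf >= band[1] && ref_eaf <= band[2]) ||
        (eaf >= band[1] && eaf <= band[2])) {
      return("drop_palindromic")
    }
    if ((ref_eaf < 0.5) == (eaf < 0.5)) return("keep") else return("flip")
  }
  cea <- unname(COMPLEMENT[ea]); coa <- unname(COMPLEMENT[oa])
  if (ea == ref_ea && oa == ref_oa) return("keep")
  if (ea == ref_oa && oa == ref_ea) return("flip")
  if (cea == ref_ea && coa == ref_oa) return("keep")
  if (cea == ref_oa && coa == ref_ea) return("flip")
  "drop_irreconcilable"
}

#' Construct a harmonized panel directly
#'
#' Low-level constructor used by the simulator and tests; [harmonize()] is
#' the entry point for real summary statistics. All trait vectors must share
#' the rsid index and contain no missing values.
#'
#' @param df Data frame with columns `rsid`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, optionally `beta_mediator`, `se_mediator`,
#'   `ea`, `oa`, `eaf`, `snp_role`, `flipped`, `palindromic`, `proxy_for`.
#' @param exposure,mediator,outcome,stratum Labels stored as attributes.
#' @return Tibble of class `mr_panel`.
#' @export
as_panel <- function(df, exposure = "exposure", mediator = "mediator",
                     outcome = "outcome", stratum = "combined") {
  df <- as_tibble(df)
  need <- c("rsid", "beta_exposure", "se_exposure", "beta_outcome",
            "se_outcome")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("Panel is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$rsid)) abort("Panel rsids must be unique.")
  core <- intersect(c(need, "beta_mediator", "se_mediator"), names(df))
  if (any(!complete.cases(df[, core]))) {
    abort("Panel beta/se entries must not be missing.")
  }
  for (col in c("ea", "oa")) if (!col %in% names(df)) df[[col]] <- NA_character_
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"flipped" %in% names(df)) df$flipped <- FALSE
  if (!"palindromic" %in% names(df)) {
    df$palindromic <- !is.na(df$ea) & !is.na(df$oa) &
      unname(COMPLEMENT[df$ea] == df$oa)
  }
  if (!"proxy_for" %in% names(df)) df$proxy_for <- NA_character_
  structure(df, class = unique(c("mr_panel", class(df))),
            exposure = exposure, mediator = mediator, outcome = outcome,
            stratum = stratum)
}

#' Harmonize summary statistics across traits into an analysis panel
#'
#' Aligns every trait to the exposure's allele orientation: swapped alleles
#' flip the beta sign and complement the frequency; strand-complement pairs
#' are matched by complementing; palindromic (A/T, C/G) SNPs are resolved by
#' allele-frequency concordance when both frequencies fall outside the
#' ambiguity band, and dropped otherwise; irreconcilable allele pairs are
#' dropped with a logged reason. Finally all traits are jointly oriented so
#' the exposure beta is non-negative (the convention Egger-family fits
#' require).
#'
#' @param exposure,outcome,mediator Summary-statistics tibbles sharing rsids
#'   (`mediator` optional). The exposure is the allele reference.
#' @param ambiguity_band Effect-allele-frequency interval within which a
#'   palindromic SNP is considered unresolvable (default `c(0.42, 0.58)`).
#' @param orient_exposure Orient all traits so `beta_exposure >= 0`
#'   (default `TRUE`).
#' @return An `mr_panel` tibble; attribute `harmonize_report` counts drops by
#'   reason, attribute `dropped` lists the dropped rsids with reasons.
#' @export
harmonize <- function(exposure, outcome, mediator = NULL,
                      ambiguity_band = c(0.42, 0.58),
                      orient_exposure = TRUE) {
  traits <- list(exposure = as_tibble(exposure), outcome = as_tibble(outcome))
  if (!is.null(mediator)) traits$mediator <- as_tibble(mediator)
  shared <- Reduce(intersect, lapply(traits, function(t) t$rsid))
  ref <- traits$exposure[match(shared, traits$exposure$rsid), ]

  out <- tibble(
    rsid = shared, ea = ref$ea, oa = ref$oa, eaf = ref$eaf,
    chrom = ref$chrom %||% NA_character_, pos = ref$pos %||% NA_real_,
    beta_exposure = ref$beta, se_exposure = ref$se,
    pval_exposure = ref$pval
  )
  drop_reason <- rep(NA_character_, length(shared))
  for (nm in setdiff(names(traits), "exposure")) {
    tt <- traits[[nm]][match(shared, traits[[nm]]$rsid), ]
    beta <- tt$beta; se <- tt$se
    for (i in seq_along(shared)) {
      act <- align_action(ref$ea[i], ref$oa[i], tt$ea[i], tt$oa[i],
                          ref$eaf[i], tt$eaf[i], ambiguity_band)
      if (act == "flip") {
        beta[i] <- -beta[i]
      } else if (act != "keep" && is.na(drop_reason[i])) {
        drop_reason[i] <- act
      }
    }
    out[[paste0("beta_", nm)]] <- beta
    out[[paste0("se_", nm)]] <- se
  }
  dropped <- tibble(rsid = shared, reason = drop_reason)
  dropped <- dropped[!is.na(dropped$reason), ]
  out <- out[is.na(drop_reason), , drop = FALSE]
  out$palindromic <- is_palindromic(out$ea, out$oa)
  out$flipped <- FALSE
  if (orient_exposure) {
    neg <- out$beta_exposure < 0
    for (col in grep("^beta_", names(out), value = TRUE)) {
      out[[col]][neg] <- -out[[col]][neg]
    }
    tmp <- out$ea[neg]; out$ea[neg] <- out$oa[neg]; out$oa[neg] <- tmp
    out$eaf[neg] <- 1 - out$eaf[neg]
    out$flipped <- neg
  }
  panel <- as_panel(out,
                    exposure = attr(exposure, "trait") %||% "exposure",
                    mediator = if (is.null(mediator)) "mediator" else
                      attr(mediator, "trait") %||% "mediator",
                    outcome = attr(outcome, "trait") %||% "outcome",
                    stratum = attr(exposure, "stratum") %||% "combined")
  attr(panel, "dropped") <- dropped
  attr(panel, "harmonize_report") <- dplyr::count(dropped, .data$reason)
  panel
}

#' Split a panel back into per-trait summary statistics
#'
#' Inverse of [harmonize()] up to the dropped rows; used for re-harmonization
#' checks and for writing panels in the sumstats dialect.
#'
#' @param panel An `mr_panel`.
#' @return Named list of summary-statistics tibbles.
#' @export
panel_to_sumstats <- function(panel) {
  lab <- panel_labels(panel)
  trts <- c("exposure",
            if ("beta_mediator" %in% names(panel)) "mediator", "outcome")
  chrom <- if ("chrom" %in% names(panel)) panel$chrom else NA_character_
  pos <- if ("pos" %in% names(panel)) panel$pos else NA_real_
  out <- lapply(trts, function(nm) {
    beta <- panel[[paste0("beta_", nm)]]
    se <- panel[[paste0("se_", nm)]]
    sumstats(tibble(
      rsid = panel$rsid, chrom = chrom,
      pos = pos, ea = panel$ea, oa = panel$oa,
      eaf = panel$eaf, beta = beta, se = se,
      pval = pmax(norm_p(beta, se), 1e-300), n = NA_real_
    ), trait = lab[[nm]], stratum = lab$stratum)
  })
  setNames(out, trts)
}
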