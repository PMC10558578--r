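#' Canonical GWAS summary-statistic columns
#'
#' A summary-statistics table holds one row per SNP with the per-allele
#' association estimate for a single trait in a single stratum. The canonical
#' columns are `rsid`, `chrom`, `pos` (1-based), `ea` (effect allele), `oa`
#' (other allele), `eaf` (effect-allele frequency), `beta`, `se`, `pval` and
#' `n`. Only `rsid`, `ea`, `oa`, `beta`, `se` and `pval` are mandatory;
#' `chrom`/`pos` are needed for windowed clumping and `eaf` for palindromic
#' resolution and R^2 summaries.
#'
#' @name sumstats-format
#' @keywords internal
NULL

SUMSTATS_REQUIRED <- c("rsid", "ea", "oa", "beta", "se", "pval")
SUMSTATS_OPTIONAL <- c("chrom", "pos", "eaf", "n")

#' Build a validated summary-statistics tibble
#'
#' Normalises alleles to upper case, enforces the row invariants
#' (`se > 0`, `pval` in (0,1], `eaf` in (0,1) when present, distinct
#' single-base alleles) and drops offending rows, recording the counts in a
#' `drop_report` attribute.
#'
#' @param df Data frame with at least the mandatory canonical columns.
#' @param trait Trait label stored as an attribute.
#' @param stratum One of `"male"`, `"female"`, `"combined"`.
#' @return A tibble of valid rows with unique `rsid`s, attributes `trait`,
#'   `stratum` and `drop_report` (tibble of reason/n).
#' @export
sumstats <- function(df, trait = "trait", stratum = "combined") {
  df <- as_tibble(df)
  missing_cols <- setdiff(SUMSTATS_REQUIRED, names(df))
  if (length(missing_cols)) {
    abort(paste0("Missing mandatory summary-statistic column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(SUMSTATS_OPTIONAL, names(df))) df[[col]] <- NA
  df <- df[, c(SUMSTATS_REQUIRED, SUMSTATS_OPTIONAL)]
  df$rsid <- as.character(df$rsid)
  df$chrom <- as.character(df$chrom)
  df$ea <- toupper(as.character(df$ea))
  df$oa <- toupper(as.character(df$oa))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  bad <- list(
    missing_core = is.na(df$rsid) | is.na(df$beta) | is.na(df$se) |
      is.na(df$pval),
    invalid_allele = !(df$ea %in% c("A", "C", "G", "T")) |
      !(df$oa %in% c("A", "C", "G", "T")),
    identical_alleles = !is.na(df$ea) & !is.na(df$oa) & df$ea == df$oa,
    nonpositive_se = !is.na(df$se) & df$se <= 0,
    invalid_pval = !is.na(df$pval) & (df$pval <= 0 | df$pval > 1),
    invalid_eaf = !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1),
    duplicate_rsid = duplicated(df$rsid)
  )
  drop <- Reduce(`|`, lapply(bad, function(x) x & !is.na(x)))
  reason_first <- rep(NA_character_, nrow(df))
  for (r in rev(names(bad))) reason_first[bad[[r]] %in% TRUE] <- r
  report <- tibble(reason = names(bad),
                   n = vapply(names(bad), function(r) {
                     sum(reason_first == r, na.rm = TRUE)
                   }, integer(1), USE.NAMES = FALSE))
  out <- df[!drop, , drop = FALSE]
  if (nrow(out) == 0L) abort("No valid summary-statistic rows remain.")
  structure(out, trait = trait, stratum = stratum,
            drop_report = report[report$n > 0L, ])
}

#' Read GWAS summary statistics from a delimited text file
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Optional named character vector mapping canonical column
#'   names (see [sumstats-format]) to the file's column names, e.g.
#'   `c(rsid = "SNP", ea = "A1", ...)`. Canonical names present in the file
#'   need not be mapped.
#' @param delim Field delimiter (default tab).
#' @inheritParams sumstats
#' @return A validated summary-statistics tibble (see [sumstats()]).
#' @export
read_sumstats <- function(path, dialect = NULL, trait = "trait",
                          stratum = "combined", delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(dialect)) {
    dialect <- dialect[dialect %in% names(raw)]
    for (canon in names(dialect)) {
      raw[[canon]] <- raw[[dialect[[canon]]]]
    }
  }
  sumstats(raw, trait = trait, stratum = stratum)
}

#' Write summary statistics in the canonical TSV dialect
#'
#' @param ss Summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  readr::write_tsv(as_tibble(ss), path, progress = FALSE)
  invisible(path)
}

#' Summary-based instrument strength
#'
#' Per-SNP F-statistics `(beta/se)^2`, their mean as the summary-level
#' instrument-strength proxy, and the approximate variance explained
#' `sum(beta^2 * 2 * eaf * (1 - eaf))` on a standardised trait scale (reported
#' as `NA` when any effect-allele frequency is missing).
#'
#' @param ss Summary-statistics tibble, or a harmonized panel together with
#'   `trait`.
#' @param trait For panels: `"exposure"` or `"mediator"`, selecting which
#'   trait's beta/se columns to use.
#' @return One-row tibble with `trait`, `stratum`, `k`, `f_mean`, `f_min` and
#'   `r2`; the per-SNP F vector is attached as attribute `f_per_snp`.
#' @export
instrument_strength <- function(ss, trait = NULL) {
  if (inherits(ss, "mr_panel")) {
    trait <- trait %||% "exposure"
    lab <- panel_labels(ss)
    df <- tibble(rsid = ss$rsid, beta = ss[[paste0("beta_", trait)]],
                 se = ss[[paste0("se_", trait)]],
                 eaf = if ("eaf" %in% names(ss)) ss$eaf else NA_real_)
    trait_label <- lab[[trait]]
    stratum <- lab$stratum
  } else {
    df <- as_tibble(ss)
    trait_label <- trait %||% attr(ss, "trait") %||% "trait"
    stratum <- attr(ss, "stratum") %||% "combined"
    if (!("eaf" %in% names(df))) df$eaf <- NA_real_
  }
  if (nrow(df) == 0L) abort("Cannot summarise an empty panel.")
  f <- (df$beta / df$se)^2
  r2 <- if (anyNA(df$eaf)) NA_real_ else
    sum(df$beta^2 * 2 * df$eaf * (1 - df$eaf))
  out <- tibble(trait = trait_label, stratum = stratum, k = nrow(df),
                f_mean = mean(f), f_min = min(f), r2 = r2)
  attr(out, "f_per_snp") <- setNames(f, df$rsid)
  out
}
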