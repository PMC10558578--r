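#' Analysis configuration
#'
#' Bundles file paths (or in-memory tables), thresholds and seeds for a full
#' stratified run. Each element of `strata` is a named list with summary
#' statistics for `exposure`, `mediator` and `outcome` (paths to TSVs in the
#' canonical dialect, or tibbles), an `ld` matrix (path or `ld_matrix`), and
#' optionally `phenotypes` (individual-level tibble/path for the
#' observational arm), `confounder_pvals` (long SNP x confounder p-value
#' table), `rho` (phenotype correlation) and `dialect` column mappings.
#'
#' @param strata Named list of stratum input lists (see above).
#' @param exposure,mediator,outcome Trait labels.
#' @param covariates Covariate columns for the observational arm.
#' @param p_thr,r2_thr,window_kb,proxy_r2_min,fdr,cooks_multiplier
#'   Thresholds; defaults are genome-wide significance 5e-8, clumping r^2
#'   0.001 within 250 kb, proxy r^2 0.8, FDR 0.05 and Cook's cut-off
#'   `cooks_multiplier / k`.
#' @param n_boot Bootstrap iterations for WME and Q-het (default 2000).
#' @param seed Master seed; stage seeds are derived deterministically from
#'   it (see [stage_seed()]).
#' @param outdir Optional output directory for the report bundle.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(strata, exposure = "exposure",
                            mediator = "mediator", outcome = "outcome",
                            covariates = character(), p_thr = 5e-8,
                            r2_thr = 0.001, window_kb = 250,
                            proxy_r2_min = 0.8, fdr = 0.05,
                            cooks_multiplier = 4, n_boot = 2000, seed = 1,
                            outdir = NULL) {
  if (is.null(names(strata)) || any(!nzchar(names(strata)))) {
    abort("`strata` must be a named list.")
  }
  structure(as.list(environment()), class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' The YAML mirrors the arguments of [analysis_config()]; file paths inside
#' `strata` are resolved relative to the YAML file's directory.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  y$strata <- lapply(y$strata, function(s) {
    lapply(s, function(v) {
      if (is.character(v) && length(v) == 1L && file.exists(file.path(base, v)))
        file.path(base, v)
      else v
    })
  })
  do.call(analysis_config, y)
}

#' Derive a stage seed from the master seed
#'
#' Stage seeds are `(seed * 1009 + 97 * stage_index) mod (2^31 - 1)` with
#' stage indices fixed by position in the analysis graph, so any single
#' stage can be reproduced without re-running the rest.
#'
#' @param seed Master seed.
#' @param stage Stage index (integer).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(stage)) %%
               (2^31 - 1))
}

load_table <- function(x, loader) {
  if (is.character(x) && length(x) == 1L) loader(x) else x
}

run_stratum <- function(sin, cfg, stratum_name) {
  exposure <- load_table(sin$exposure, function(p)
    read_sumstats(p, dialect = sin$dialect, trait = cfg$exposure,
                  stratum = stratum_name))
  mediator <- load_table(sin$mediator, function(p)
    read_sumstats(p, dialect = sin$dialect, trait = cfg$mediator,
                  stratum = stratum_name))
  outcome <- load_table(sin$outcome, function(p)
    read_sumstats(p, dialect = sin$dialect, trait = cfg$outcome,
                  stratum = stratum_name))
  ld <- load_table(sin$ld, read_ld_matrix)
  rho <- sin$rho %||% 0

  panel <- assemble_mvmr_instruments(
    exposure, mediator, outcome, ld, p_thr = cfg$p_thr,
    r2_thr = cfg$r2_thr, window_kb = cfg$window_kb,
    proxy_r2_min = cfg$proxy_r2_min)
  uni_panel <- panel_subset_role(panel, "exposure")

  wme_seed <- stage_seed(cfg$seed, 1L)
  qhet_seed <- stage_seed(cfg$seed, 2L)
  est_ivw <- ivw(uni_panel)
  univariable <- bind_rows(
    as_tibble(est_ivw),
    as_tibble(mr_egger(uni_panel)),
    as_tibble(weighted_median(uni_panel, n_boot = cfg$n_boot,
                              seed = wme_seed))
  )
  diagnostics <- list(
    single_snp = single_snp_table(uni_panel),
    leave_one_out = leave_one_out(uni_panel),
    cooks = cooks_influence(uni_panel,
                            threshold = cfg$cooks_multiplier /
                              nrow(uni_panel)),
    instrument_strength = bind_rows(
      instrument_strength(panel, "exposure"),
      instrument_strength(panel, "mediator")
    )
  )
  flagged_confounder <- if (!is.null(sin$confounder_pvals)) {
    bh_confounder_filter(load_table(sin$confounder_pvals, function(p)
      readr::read_tsv(p, show_col_types = FALSE)), fdr = cfg$fdr)
  } else {
    character(0)
  }
  diagnostics$flagged_confounder <- flagged_confounder
  diagnostics$flagged_influence <-
    diagnostics$cooks$rsid[diagnostics$cooks$flagged]

  mvmr <- mvmr_ivw(panel)
  mvmr_eg <- mvmr_egger(panel)
  qhet <- qhet_estimate(panel, rho = rho, n_boot = cfg$n_boot,
                        seed = qhet_seed)
  exp_row <- function(est) est[est$term == "exposure", , drop = FALSE]
  cond_f_exp <- exp_row(mvmr)$cond_F
  qa <- exp_row(mvmr)$Q_A
  # weak instruments or heterogeneity promote the Q-minimisation estimate
  primary_direct <- if (cond_f_exp < 10 || qa > nrow(panel)) "Q-het"
                    else "MVMR-IVW"
  direct_est <- if (primary_direct == "Q-het") exp_row(qhet) else
    exp_row(mvmr)
  direct_est$exposure <- est_ivw$exposure
  mediation_mr <- difference_method(est_ivw, select(direct_est, -"term",
                                                    -dplyr::any_of(c(
                                                      "cond_F", "Q_A",
                                                      "n_boot", "seed"))))
  mediation_obs <- if (!is.null(sin$phenotypes)) {
    pheno <- load_table(sin$phenotypes, function(p)
      readr::read_tsv(p, show_col_types = FALSE))
    prep <- prepare_phenotypes(pheno, exposure = cfg$exposure,
                               covariates = cfg$covariates)
    observational_mediation(prep, exposure = cfg$exposure,
                            mediator = "log_crp", outcome = "grip",
                            covariates = cfg$covariates,
                            stratum = stratum_name)
  }

  list(
    stratum = stratum_name,
    assembly_report = attr(panel, "assembly_report"),
    panel = panel,
    univariable = univariable,
    diagnostics = diagnostics,
    mvmr = bind_rows(as_tibble(mvmr), as_tibble(mvmr_eg)),
    qhet = as_tibble(qhet),
    primary_direct_method = primary_direct,
    mediation_mr = as_tibble(mediation_mr),
    mediation_obs = if (!is.null(mediation_obs)) as_tibble(mediation_obs),
    seeds = list(wme = wme_seed, qhet = qhet_seed)
  )
}

#' Run the full stratified mediation analysis
#'
#' Per stratum: instrument assembly with accounting, univariable IVW, Egger
#' and WME total effects with the single-SNP, leave-one-out, Cook's-distance
#' and confounder-association diagnostics, multivariable IVW and Egger
#' direct effects with conditional F and Q_A, the Q-minimisation estimate
#' (always computed; labelled primary when the conditional F is below 10 or
#' Q_A exceeds the SNP count), and difference-method mediation for the MR
#' arm plus the observational two-regression arm when individual-level
#' phenotypes are supplied. A hard error in one stratum is captured as a
#' structured error record; other strata continue.
#'
#' @param config An [analysis_config()] (or path to a YAML accepted by
#'   [read_analysis_config()]).
#' @return List of class `mr_report`: `strata` (named result lists),
#'   `errors`, `provenance` (thresholds, seeds, package version). Written to
#'   `config$outdir` as JSON + TSVs when set.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  results <- list(); errors <- list()
  for (nm in names(config$strata)) {
    res <- tryCatch(run_stratum(config$strata[[nm]], config, nm),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm]] <- list(stratum = nm, message = conditionMessage(res))
    } else {
      results[[nm]] <- res
    }
  }
  bundle <- structure(list(
    strata = results,
    errors = errors,
    provenance = list(
      thresholds = config[c("p_thr", "r2_thr", "window_kb", "proxy_r2_min",
                            "fdr", "cooks_multiplier")],
      n_boot = config$n_boot, seed = config$seed,
      package = as.character(utils::packageVersion("mrmediate"))
    )
  ), class = "mr_report")
  if (!is.null(config$outdir)) write_report_bundle(bundle, config$outdir)
  bundle
}

#' Write a report bundle to disk
#'
#' One JSON file with full provenance plus tidy TSVs of every estimate
#' table.
#'
#' @param bundle An `mr_report` from [run_full_analysis()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tables <- list()
  for (nm in names(bundle$strata)) {
    s <- bundle$strata[[nm]]
    for (tb in c("univariable", "mvmr", "qhet", "mediation_mr",
                 "mediation_obs")) {
      if (!is.null(s[[tb]])) {
        tables[[tb]] <- bind_rows(tables[[tb]],
                                  mutate(s[[tb]], stratum = nm))
      }
    }
  }
  for (tb in names(tables)) {
    readr::write_tsv(tables[[tb]], file.path(outdir, paste0(tb, ".tsv")),
                     progress = FALSE)
  }
  json <- list(
    provenance = bundle$provenance,
    errors = bundle$errors,
    strata = lapply(bundle$strata, function(s) {
      list(assembly_report = s$assembly_report[
        setdiff(names(s$assembly_report), "dropped_harmonize")],
        primary_direct_method = s$primary_direct_method,
        seeds = s$seeds,
        univariable = s$univariable, mvmr = s$mvmr, qhet = s$qhet,
        mediation_mr = s$mediation_mr, mediation_obs = s$mediation_obs,
        instrument_strength = s$diagnostics$instrument_strength,
        flagged_confounder = s$diagnostics$flagged_confounder,
        flagged_influence = s$diagnostics$flagged_influence)
    })
  )
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(outdir)
}

#' Re-run univariable estimators after excluding flagged SNPs
#'
#' Pairs each estimator's estimate before and after removing the flagged
#' SNPs (confounder-associated or high-influence). Estimators whose minimum
#' SNP count is no longer met are reported as not estimable rather than
#' erroring.
#'
#' @param panel An `mr_panel`.
#' @param flagged Character vector of rsids to exclude (must be a subset of
#'   the panel).
#' @param which Label recorded in the output: `"confounder-associated"` or
#'   `"high-influence"`.
#' @param n_boot,seed WME bootstrap settings.
#' @return Tibble with columns `method`, `phase` (`before`/`after`),
#'   estimate columns, `excluded` (count) and `note`.
#' @export
sensitivity_rerun <- function(panel, flagged,
                              which = c("confounder-associated",
                                        "high-influence"),
                              n_boot = 2000, seed = 1) {
  which <- match.arg(which)
  if (length(setdiff(flagged, panel$rsid))) {
    abort("`flagged` contains rsids not present in the panel.")
  }
  sub <- panel[!(panel$rsid %in% flagged), , drop = FALSE]
  for (a in c("exposure", "mediator", "outcome", "stratum")) {
    attr(sub, a) <- attr(panel, a)
  }
  run_all <- function(p, phase) {
    est <- function(fn, min_k, ...) {
      if (nrow(p) < min_k) {
        return(tibble(method = NA_character_, beta = NA_real_,
                      se = NA_real_, k = nrow(p),
                      note = "not estimable"))
      }
      mutate(as_tibble(fn(p, ...)), note = NA_character_)
    }
    out <- bind_rows(
      mutate(est(ivw, 1L), method = "IVW"),
      mutate(est(mr_egger, 3L), method = "Egger"),
      mutate(est(weighted_median, 3L, n_boot = n_boot, seed = seed),
             method = "WME")
    )
    mutate(out, phase = phase, excluded = nrow(panel) - nrow(p),
           flag_type = which, .before = 1)
  }
  bind_rows(run_all(panel, "before"), run_all(sub, "after"))
}
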