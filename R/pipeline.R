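# End-to-end orchestration: simulate -> QC -> transform -> heritability ->
# correlations -> expression association -> GWAM -> report, with every
# artifact written as delimited text plus a JSON run manifest.

#' Run the full twin-lipidome analysis pipeline on synthetic data
#'
#' Chains every stage of the analysis on a synthetic cohort with known
#' ground truth: raw-peak QC (filtering and duplicate resolution),
#' covariate residualization with inverse normal transformation,
#' lipidome-wide heritability screening, genetic correlations for a subset
#' of trait pairs, pair-clustered lipid-expression association with lasso
#' probe selection and variance explained, GWAM association, and the
#' summary reports. All tables are written to `out_dir` as CSV plus a run
#' manifest JSON; the function also returns every result invisibly.
#'
#' @param config A [twin_sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param alpha Family-wise error rate for the association screen.
#' @param n_assoc_lipids,n_assoc_probes Size of the (lipid x probe)
#'   association screen; the mixed-model stage scales with their product.
#' @param n_corr_traits Number of leading lipids whose pairwise genetic
#'   correlations are fitted.
#' @param ci Profile CIs in the heritability screen (slower).
#' @return (invisibly) A list with all intermediate and final tables.
#' @export
run_twin_lipidome_pipeline <- function(config = twin_sim_config(),
                                       out_dir = tempfile("twinlipids_run_"),
                                       alpha = 0.05,
                                       n_assoc_lipids = 4,
                                       n_assoc_probes = 100,
                                       n_corr_traits = 4,
                                       ci = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  save_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p)
    outputs <<- c(outputs, p)
  }

  # synthetic inputs
  cohort <- simulate_twin_cohort(config)
  expr <- simulate_expression(cohort, config)
  meth <- simulate_methylation(cohort, config)
  raw <- simulate_raw_peak_table()
  save_csv(cohort$pairs, "pairs.csv")
  save_csv(cohort$lipids, "lipids.csv")

  # peak-table QC
  norm <- normalize_by_class_standard(raw)
  filt <- filter_lipids(norm)
  dedup <- resolve_duplicates(filt$kept)
  save_csv(dedup$kept, "peaks_filtered.csv")
  save_csv(filt$audit, "qc_audit.csv")

  # transforms
  covars <- dplyr::select(cohort$pairs, "age", "sex", "education", "bmi",
                          "smoking", "lipid_med", "apoe_e4", "batch")
  resid <- residualize_matrix(cohort$lipids, covars)
  expr_resid <- residualize_matrix(
    expr, dplyr::select(cohort$pairs, "age", "sex", "batch"), int = FALSE)
  save_csv(resid, "lipid_residuals.csv")

  # heritability screen + summary
  herit <- fit_lipidome_heritability(cohort$pairs, resid, ci = ci)
  save_csv(herit, "heritability.csv")
  ace <- dplyr::filter(herit, .data$model == "ACE")
  hsum <- heritability_summary(ace, alpha = alpha)
  save_csv(hsum$by_class, "heritability_by_class.csv")

  # genetic correlations for the leading traits
  traits <- head(setdiff(names(resid), "sample_id"), n_corr_traits)
  corr <- if (length(traits) >= 2) {
    cmb <- utils::combn(traits, 2)
    twin_correlations_table(cohort$pairs, resid,
                            tibble::tibble(trait1 = cmb[1, ],
                                           trait2 = cmb[2, ]))
  } else NULL
  if (!is.null(corr)) save_csv(corr, "correlations.csv")

  # expression association on a subset, lasso selection, variance explained
  assoc_lipids <- head(setdiff(names(resid), "sample_id"), n_assoc_lipids)
  assoc_probes <- head(setdiff(names(expr_resid), "sample_id"), n_assoc_probes)
  assoc <- mixed_model_association(resid, expr_resid, cohort$pairs,
                                   lipid_cols = assoc_lipids,
                                   probe_cols = assoc_probes, alpha = alpha)
  save_csv(assoc, "associations.csv")

  dat <- dplyr::inner_join(resid, expr_resid, by = "sample_id") |>
    dplyr::inner_join(dplyr::select(cohort$pairs, "sample_id", "pair_id"),
                      by = "sample_id")
  varexp <- purrr::map_dfr(assoc_lipids, function(l) {
    cand <- assoc$probe[assoc$lipid == l & assoc$significant]
    sel <- if (length(cand)) {
      select_probes_penalized(dat[[l]], dat[, cand, drop = FALSE],
                              seed = config$seed)
    } else character(0)
    ve <- variance_explained(dat[[l]], dat[, sel, drop = FALSE], dat$pair_id)
    dplyr::bind_cols(tibble::tibble(lipid = l), ve)
  })
  save_csv(varexp, "variance_explained.csv")

  # GWAM
  gwam <- compute_gwam(meth)
  gw_assoc <- gwam_association(resid, gwam, lipid_cols = assoc_lipids)
  save_csv(gwam, "gwam.csv")
  save_csv(gw_assoc, "gwam_assoc.csv")

  # cohort characteristics
  ctab <- cohort_table(cohort$pairs)
  save_csv(ctab, "cohort_table.csv")

  manifest_path <- file.path(out_dir, "run_manifest.json")
  write_run_manifest(
    manifest_path,
    config = list(
      seed = config$seed, n_mz_pairs = config$n_mz_pairs,
      n_dz_pairs = config$n_dz_pairs, n_lipids = config$n_lipids,
      n_probes = config$n_probes, n_cpg = config$n_cpg, alpha = alpha,
      n_assoc_lipids = n_assoc_lipids, n_assoc_probes = n_assoc_probes),
    outputs = basename(outputs))

  invisible(list(
    cohort = cohort, expression = expr, methylation = meth,
    peaks_filtered = dedup$kept, qc_audit = filt$audit,
    residuals = resid, heritability = herit, heritability_summary = hsum,
    correlations = corr, associations = assoc, variance_explained = varexp,
    gwam = gwam, gwam_assoc = gw_assoc, cohort_table = ctab,
    manifest = manifest_path, out_dir = out_dir))
}
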