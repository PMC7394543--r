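# Genome-wide average methylation (GWAM) and methylation association stages.

#' Genome-wide average methylation per sample
#'
#' Unweighted per-sample mean of CpG beta values over the retained probes
#' (after masking sex-chromosome, SNP-containing, cross-reactive or
#' undetected probes upstream).
#'
#' @param methylation Tibble `sample_id` + CpG beta columns (values in
#'   `[0, 1]`).
#' @param probe_mask Optional character vector of CpG column names to retain;
#'   default all. An empty mask is an error.
#' @return Tibble `sample_id`, `gwam`.
#' @export
compute_gwam <- function(methylation, probe_mask = NULL) {
  cpgs <- setdiff(names(methylation), "sample_id")
  probe_mask <- probe_mask %||% cpgs
  probe_mask <- intersect(probe_mask, cpgs)
  if (length(probe_mask) == 0) abort("Empty probe mask: no CpGs to average.")
  M <- as.matrix(methylation[, probe_mask, drop = FALSE])
  if (any(M < 0 | M > 1, na.rm = TRUE)) abort("Beta values must lie in [0, 1].")
  tibble::tibble(sample_id = methylation$sample_id,
                 gwam = rowMeans(M, na.rm = TRUE))
}

#' Regression of lipid residuals on genome-wide average methylation
#'
#' Per lipid, ordinary least-squares regression of the lipid residual on
#' standardized GWAM, reporting slope, SE, t, p and McFadden's pseudo-r2
#' from the null/full log-likelihoods. Standardizing GWAM makes the slope
#' invariant to adding a constant to every beta value.
#'
#' @param lipids Tibble `sample_id` + lipid residual columns.
#' @param gwam Tibble from [compute_gwam()].
#' @param lipid_cols Lipids to test (default all non-id columns).
#' @return Tibble: `lipid`, `beta`, `se`, `statistic`, `p_value`,
#'   `mcfadden`, `n`.
#' @export
gwam_association <- function(lipids, gwam, lipid_cols = NULL) {
  lipid_cols <- lipid_cols %||% setdiff(names(lipids), "sample_id")
  dat <- dplyr::inner_join(lipids, gwam, by = "sample_id")
  if (sd(dat$gwam) < 1e-12) abort("GWAM has zero variance across samples.")
  g <- as.numeric(scale(dat$gwam))
  purrr::map_dfr(lipid_cols, function(l) {
    y <- dat[[l]]
    fit <- lm(y ~ g)
    sm <- summary(fit)$coefficients
    ll0 <- as.numeric(logLik(lm(y ~ 1)))
    ll1 <- as.numeric(logLik(fit))
    tibble::tibble(
      lipid = l, beta = sm[2, 1], se = sm[2, 2], statistic = sm[2, 3],
      p_value = sm[2, 4],
      mcfadden = min(max(1 - ll1 / ll0, 0), 1),
      n = length(y))
  })
}

#' Site-level CpG associations near lipid-associated transcripts
#'
#' Applies the same pair-clustered regression machinery as
#' [mixed_model_association()] to individual CpG sites restricted by a
#' gene-to-CpG proximity map: each (trait, CpG) pair listed in `map` is
#' tested, and unadjusted p < 0.05 is flagged `suggestive` (no
#' multiple-testing correction is applied at this exploratory stage).
#'
#' @param traits Tibble `sample_id` + trait columns (lipid or probe
#'   residuals).
#' @param cpgs Tibble `sample_id` + CpG columns (beta values or residuals).
#' @param map Tibble with columns `trait`, `cpg` naming the pairs to test.
#' @param meta Optional tibble `sample_id`, `pair_id`; when supplied the
#'   regression includes a random pair intercept, otherwise ordinary least
#'   squares is used.
#' @return Tibble: `trait`, `cpg`, `beta`, `se`, `statistic`, `p_value`,
#'   `suggestive`, `direction`. Empty map gives an empty tibble.
#' @export
site_level_association <- function(traits, cpgs, map, meta = NULL) {
  map <- tibble::as_tibble(map)
  if (nrow(map) == 0) {
    return(tibble::tibble(trait = character(), cpg = character(),
                          beta = double(), se = double(), statistic = double(),
                          p_value = double(), suggestive = logical(),
                          direction = character()))
  }
  dat <- dplyr::inner_join(traits, cpgs, by = "sample_id")
  if (!is.null(meta)) {
    dat <- dplyr::inner_join(dat, dplyr::select(meta, "sample_id", "pair_id"),
                             by = "sample_id")
  }
  purrr::pmap_dfr(map, function(trait, cpg, ...) {
    y <- dat[[trait]]
    x <- dat[[cpg]]
    res <- if (!is.null(meta)) {
      assoc_mixed_one(y, x, dat$pair_id)[, c("beta", "se", "statistic", "p_value")]
    } else {
      sm <- summary(lm(y ~ scale(x)))$coefficients
      tibble::tibble(beta = sm[2, 1], se = sm[2, 2], statistic = sm[2, 3],
                     p_value = sm[2, 4])
    }
    dplyr::bind_cols(tibble::tibble(trait = trait, cpg = cpg), res)
  }) |>
    dplyr::mutate(suggestive = .data$p_value < 0.05,
                  direction = dplyr::if_else(.data$beta >= 0, "positive", "inverse"))
}
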