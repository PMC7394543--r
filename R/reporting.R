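# Summary artifacts: saturation and carbon-class stratifications,
# transcript-association count bins, heritable-vs-non-heritable transcript
# sets, cohort characteristics table, heritability summaries.

#' Classify lipids by acyl-chain saturation
#'
#' Saturated = no fatty-acyl double bonds, monounsaturated = exactly one,
#' polyunsaturated = two or more, judged on the total double bonds across
#' all chains.
#'
#' @param species Parsed species tibble from [parse_lipid_name()].
#' @return Tibble `raw_name`, `saturation` (factor with levels saturated /
#'   monounsaturated / polyunsaturated).
#' @examples
#' classify_saturation(parse_lipid_name("TG(18:0/17:0/18:0)"))
#' @export
classify_saturation <- function(species) {
  tibble::tibble(
    raw_name = species$raw_name,
    saturation = factor(
      dplyr::case_when(
        species$total_double_bonds == 0 ~ "saturated",
        species$total_double_bonds == 1 ~ "monounsaturated",
        TRUE ~ "polyunsaturated"),
      levels = c("saturated", "monounsaturated", "polyunsaturated"))
  )
}

#' Classify lipids by total carbon number
#'
#' Low < 49 carbons, medium 49-55, high >= 56 (boundaries: 48 is low, 49 and
#' 55 are medium, 56 is high).
#'
#' @param species Parsed species tibble from [parse_lipid_name()].
#' @return Tibble `raw_name`, `carbon_class` (factor low / medium / high).
#' @export
classify_carbons <- function(species) {
  tibble::tibble(
    raw_name = species$raw_name,
    carbon_class = factor(
      dplyr::case_when(
        species$total_carbons <= 48 ~ "low",
        species$total_carbons <= 55 ~ "medium",
        TRUE ~ "high"),
      levels = c("low", "medium", "high"))
  )
}

#' Bin transcripts by how many lipids they associate with, per stratum
#'
#' Within each stratum (e.g. TG saturation class or carbon class), counts
#' the number of significantly associated lipids per transcript and tallies
#' how many transcripts fall in the bins 1-2, 3-8 and >8 lipids.
#'
#' @param associations Association tibble with `lipid`, `probe`,
#'   `significant`.
#' @param strata Tibble mapping `lipid` to `stratum`.
#' @return Tibble `stratum`, `bin` (`"1-2"`, `"3-8"`, `">8"`), `n_transcripts`;
#'   all bins reported (zero-filled) for every stratum present.
#' @export
count_association_bins <- function(associations, strata) {
  bins <- c("1-2", "3-8", ">8")
  sig <- dplyr::filter(associations, .data$significant)
  counts <- sig |>
    dplyr::inner_join(strata, by = "lipid") |>
    dplyr::distinct(.data$stratum, .data$probe, .data$lipid) |>
    dplyr::count(.data$stratum, .data$probe, name = "n_lipids") |>
    dplyr::mutate(bin = dplyr::case_when(
      .data$n_lipids <= 2 ~ "1-2",
      .data$n_lipids <= 8 ~ "3-8",
      TRUE ~ ">8"))
  tidyr::expand_grid(stratum = unique(strata$stratum), bin = bins) |>
    dplyr::left_join(dplyr::count(counts, .data$stratum, .data$bin,
                                  name = "n_transcripts"),
                     by = c("stratum", "bin")) |>
    dplyr::mutate(n_transcripts = tidyr::replace_na(.data$n_transcripts, 0L),
                  bin = factor(.data$bin, levels = bins)) |>
    dplyr::arrange(.data$stratum, .data$bin)
}

#' Compare transcript sets of heritable vs non-heritable lipids
#'
#' Partitions the transcripts significantly associated with any lipid into
#' those unique to heritable lipids, unique to non-heritable lipids, and
#' shared, with positive/inverse direction tallies per set.
#'
#' @param associations Association tibble with `lipid`, `probe`,
#'   `significant`, `direction`.
#' @param heritability_calls Tibble `lipid`, `heritable` (logical).
#' @return List with `sets` (character vectors `unique_heritable`,
#'   `unique_nonheritable`, `shared`) and `summary` (tibble `set`,
#'   `n_transcripts`, `n_positive`, `n_inverse`).
#' @export
heritable_vs_nonheritable_sets <- function(associations, heritability_calls) {
  sig <- dplyr::filter(associations, .data$significant) |>
    dplyr::inner_join(heritability_calls, by = "lipid")
  her <- unique(sig$probe[sig$heritable])
  non <- unique(sig$probe[!sig$heritable])
  sets <- list(
    unique_heritable = setdiff(her, non),
    unique_nonheritable = setdiff(non, her),
    shared = intersect(her, non))
  summarise_set <- function(nm) {
    probes <- sets[[nm]]
    sub <- dplyr::filter(sig, .data$probe %in% probes)
    dirs <- sub |> dplyr::distinct(.data$probe, .data$direction)
    tibble::tibble(set = nm, n_transcripts = length(probes),
                   n_positive = sum(dirs$direction == "positive"),
                   n_inverse = sum(dirs$direction == "inverse"))
  }
  list(sets = sets, summary = purrr::map_dfr(names(sets), summarise_set))
}

#' Welch two-sample t statistic from group summaries
#'
#' @param m1,s1,n1,m2,s2,n2 Group means, SDs and sizes.
#' @return Tibble `statistic`, `df`, `p_value`.
#' @examples
#' welch_t_summary(75.7, 5.47, 150, 76.07, 5.31, 110) # t = -0.548
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(statistic = t, df = df,
                 p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Cohort characteristics table with MZ/DZ group comparisons
#'
#' Continuous variables are compared with Welch's unequal-variance t test
#' (from raw values, or from printed mean/SD/n summaries via
#' [welch_t_summary()]); categorical variables with Pearson's chi-square
#' test without continuity correction. Groups with fewer than 2 members
#' skip the variable with a warning.
#'
#' @param meta Per-individual tibble with `zygosity` plus the variables.
#' @param continuous,categorical Character vectors of column names.
#' @return Tibble: `variable`, `type`, `mz_summary`, `dz_summary`,
#'   `statistic`, `p_value`.
#' @export
cohort_table <- function(meta, continuous = c("age", "bmi", "education"),
                         categorical = c("sex", "smoking", "apoe_e4")) {
  grp <- split(meta, meta$zygosity)
  if (any(vapply(grp, nrow, 1L) < 2)) {
    warn("A zygosity group has fewer than 2 members; skipping all comparisons.")
    return(tibble::tibble())
  }
  cont <- purrr::map_dfr(intersect(continuous, names(meta)), function(v) {
    x <- grp$MZ[[v]]; y <- grp$DZ[[v]]
    tt <- welch_t_summary(mean(x, na.rm = TRUE), sd(x, na.rm = TRUE), sum(!is.na(x)),
                          mean(y, na.rm = TRUE), sd(y, na.rm = TRUE), sum(!is.na(y)))
    tibble::tibble(
      variable = v, type = "continuous",
      mz_summary = sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE)),
      dz_summary = sprintf("%.2f (%.2f)", mean(y, na.rm = TRUE), sd(y, na.rm = TRUE)),
      statistic = tt$statistic, p_value = tt$p_value)
  })
  cat_rows <- purrr::map_dfr(intersect(categorical, names(meta)), function(v) {
    tab <- table(meta$zygosity, meta[[v]])
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    lead <- colnames(tab)[ncol(tab)]
    fmt <- function(g) sprintf("%d (%.0f%%)", tab[g, lead],
                               100 * tab[g, lead] / sum(tab[g, ]))
    tibble::tibble(
      variable = v, type = "categorical",
      mz_summary = fmt("MZ"), dz_summary = fmt("DZ"),
      statistic = unname(ct$statistic), p_value = ct$p.value)
  })
  dplyr::bind_rows(cont, cat_rows)
}

#' Pearson chi-square statistic without continuity correction
#'
#' @param counts 2x2 (or larger) contingency matrix.
#' @return Tibble `statistic`, `df`, `p_value`.
#' @examples
#' chisq_nocorrect(matrix(c(100, 50, 79, 31), 2, byrow = TRUE)) # 0.785
#' @export
chisq_nocorrect <- function(counts) {
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value)
}

#' Summarise heritability fits across lipids
#'
#' Counts and percentages of significantly heritable lipids overall and per
#' lipid class, with median h2 among the significant and non-significant
#' sets (absent, not zero, when a set is empty). Percentages are rounded to
#' one decimal.
#'
#' @param fits Tibble with at least `lipid`, `h2`, `p_h2` (e.g. from
#'   [fit_lipidome_heritability()]).
#' @param alpha Significance level for the heritability call, default 0.05.
#' @return List with `overall` (tibble `n_total`, `n_significant`,
#'   `pct_significant`, `median_h2_significant`,
#'   `median_h2_nonsignificant`) and `by_class` (same per `lipid_class`,
#'   classes parsed from the lipid names).
#' @examples
#' fits <- tibble::tibble(lipid = sprintf("TG(16:0/18:1/18:%d)", 0:2),
#'                        h2 = c(0.4, 0.1, 0.3), p_h2 = c(0.01, 0.6, 0.2))
#' heritability_summary(fits)$overall
#' @export
heritability_summary <- function(fits, alpha = 0.05) {
  fits <- dplyr::mutate(tibble::as_tibble(fits),
                        significant = .data$p_h2 < alpha)
  summ <- function(df) {
    tibble::tibble(
      n_total = nrow(df),
      n_significant = sum(df$significant),
      pct_significant = round(100 * sum(df$significant) / nrow(df), 1),
      median_h2_significant = if (any(df$significant)) {
        median(df$h2[df$significant])
      } else NA_real_,
      median_h2_nonsignificant = if (any(!df$significant)) {
        median(df$h2[!df$significant])
      } else NA_real_)
  }
  cls <- parse_lipid_name(fits$lipid)$lipid_class
  by_class <- fits |>
    dplyr::mutate(lipid_class = cls) |>
    dplyr::group_by(.data$lipid_class) |>
    dplyr::group_modify(~ summ(.x)) |>
    dplyr::ungroup()
  list(overall = summ(fits), by_class = by_class)
}
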