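# Peak-table quality control: internal-standard normalization, CV
# computation, rule-based filtering, duplicate resolution, group sums and
# the Friedewald LDL-C estimate.

#' Normalize peak areas by class internal standards
#'
#' Divides each raw peak area by the internal-standard (IS) area of the
#' lipid's class for the same sample, the standard per-class IS
#' normalization for targeted lipidomics panels. The IS areas come either
#' from an `is_area` column already on `peaks` or from a `standards` table
#' with one IS area per (sample, lipid_class).
#'
#' @param peaks Tibble of peak records; requires columns `lipid`,
#'   `lipid_class`, `sample`, `area`, plus `is_area` unless `standards` is
#'   given.
#' @param standards Optional tibble with columns `sample`, `lipid_class`,
#'   `is_area`.
#' @return `peaks` with a `norm_abundance` column (`area / is_area`).
#' @examples
#' normalize_by_class_standard(
#'   tibble::tibble(lipid = "PC(16:0/18:1)", lipid_class = "PC",
#'                  sample = "S1", area = 2000, is_area = 1000))
#' @export
normalize_by_class_standard <- function(peaks, standards = NULL) {
  peaks <- tibble::as_tibble(peaks)
  if (!is.null(standards)) {
    peaks$is_area <- NULL
    peaks <- dplyr::left_join(peaks, standards, by = c("sample", "lipid_class"))
  }
  if (!"is_area" %in% names(peaks)) {
    abort("No internal-standard areas: supply an `is_area` column or a `standards` table.")
  }
  bad <- peaks |>
    dplyr::filter(is.na(.data$is_area) | .data$is_area <= 0) |>
    dplyr::distinct(.data$sample, .data$lipid_class)
  if (nrow(bad)) {
    abort(paste0(
      "Missing or non-positive internal-standard area for (sample, class): ",
      paste(sprintf("(%s, %s)", bad$sample, bad$lipid_class), collapse = ", ")))
  }
  dplyr::mutate(peaks, norm_abundance = .data$area / .data$is_area)
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean, the intra-assay CV used to
#' judge repeated injections of quality-control standards.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return A single number, `sd(values) / mean(values)`.
#' @examples
#' compute_cv(c(2, 4)) # 0.4714
#' @export
compute_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) abort("CV needs at least 2 values.")
  m <- mean(values)
  if (m == 0) abort("CV is undefined for mean 0.")
  sd(values) / m
}

#' Filter lipid features by QC rules
#'
#' Applies the standard post-alignment inclusion rules to a normalized peak
#' table: keep a feature only if its rejection flag is 0, its average peak
#' quality exceeds `peak_quality_min`, its QC-injection CV is below `cv_max`,
#' and it was detected in every alignment batch. Excluded features are
#' recorded in an audit log naming the violated rule.
#'
#' @param peaks Normalized peak tibble (see [normalize_by_class_standard()]);
#'   needs `feature_id`, `lipid`, `batch`, `sample_type`, `norm_abundance`,
#'   `rej`, `peak_quality`.
#' @param cv_max QC CV threshold (exclusive), default 0.4.
#' @param peak_quality_min Average peak-quality threshold (exclusive),
#'   default 0.75.
#' @param n_batches Number of alignment batches a feature must appear in;
#'   default the number of distinct batches present in `peaks`.
#' @return List with `kept` (the surviving rows of `peaks`), `qc` (per-feature
#'   QC summary with the computed CV) and `audit` (tibble `feature_id`,
#'   `lipid`, `rule`, `detail` for every exclusion).
#' @export
filter_lipids <- function(peaks, cv_max = 0.4, peak_quality_min = 0.75,
                          n_batches = NULL) {
  peaks <- tibble::as_tibble(peaks)
  n_batches <- n_batches %||% dplyr::n_distinct(peaks$batch)

  qc <- peaks |>
    dplyr::group_by(.data$feature_id, .data$lipid) |>
    dplyr::summarise(
      rej = max(.data$rej),
      avg_peak_quality = mean(.data$peak_quality),
      n_batches_present = dplyr::n_distinct(.data$batch),
      qc_cv = if (sum(.data$sample_type == "qc") >= 2) {
        compute_cv(.data$norm_abundance[.data$sample_type == "qc"])
      } else NA_real_,
      .groups = "drop"
    )

  audit <- dplyr::bind_rows(
    qc |> dplyr::filter(.data$rej != 0) |>
      dplyr::transmute(.data$feature_id, .data$lipid, rule = "rej",
                       detail = sprintf("rej = %d", .data$rej)),
    qc |> dplyr::filter(.data$avg_peak_quality <= peak_quality_min) |>
      dplyr::transmute(.data$feature_id, .data$lipid, rule = "peak quality",
                       detail = sprintf("average peak quality %.3f <= %.2f",
                                        .data$avg_peak_quality, peak_quality_min)),
    qc |> dplyr::filter(!is.na(.data$qc_cv) & .data$qc_cv >= cv_max) |>
      dplyr::transmute(.data$feature_id, .data$lipid, rule = "cv",
                       detail = sprintf("QC CV %.3f >= %.2f", .data$qc_cv, cv_max)),
    qc |> dplyr::filter(.data$n_batches_present < n_batches) |>
      dplyr::transmute(.data$feature_id, .data$lipid, rule = "batch presence",
                       detail = sprintf("present in %d of %d batches",
                                        .data$n_batches_present, n_batches))
  )
  kept <- dplyr::anti_join(peaks, dplyr::distinct(audit, .data$feature_id),
                           by = "feature_id")
  list(kept = kept, qc = qc, audit = audit)
}

#' Resolve duplicate lipid identifications
#'
#' When the same lipid annotation was integrated more than once (identical
#' annotation and m/z within tolerance, similar retention time), one feature
#' is kept per lipid: lowest QC CV first, then highest average peak quality,
#' then highest average m-score; remaining exact ties fall back to input
#' order and are logged as ambiguous.
#'
#' @param peaks Normalized peak tibble with `feature_id`, `lipid`,
#'   `sample_type`, `norm_abundance`, `peak_quality`, `m_score`.
#' @return List with `kept` (rows of the surviving features), `choices`
#'   (per-lipid survivor and ranking keys) and `ambiguous` (lipids decided by
#'   input order).
#' @export
resolve_duplicates <- function(peaks) {
  peaks <- tibble::as_tibble(peaks)
  keys <- peaks |>
    dplyr::mutate(.order = match(.data$feature_id, unique(peaks$feature_id))) |>
    dplyr::group_by(.data$lipid, .data$feature_id) |>
    dplyr::summarise(
      qc_cv = if (sum(.data$sample_type == "qc") >= 2) {
        compute_cv(.data$norm_abundance[.data$sample_type == "qc"])
      } else Inf,
      avg_peak_quality = mean(.data$peak_quality),
      avg_m_score = mean(.data$m_score),
      .order = min(.data$.order),
      .groups = "drop"
    )
  choices <- keys |>
    dplyr::group_by(.data$lipid) |>
    dplyr::arrange(.data$qc_cv, dplyr::desc(.data$avg_peak_quality),
                   dplyr::desc(.data$avg_m_score), .data$.order,
                   .by_group = TRUE) |>
    dplyr::mutate(
      survivor = dplyr::row_number() == 1L,
      n_candidates = dplyr::n(),
      ambiguous = dplyr::n() > 1 &&
        sum(.data$qc_cv == .data$qc_cv[1] &
              .data$avg_peak_quality == .data$avg_peak_quality[1] &
              .data$avg_m_score == .data$avg_m_score[1]) > 1
    ) |>
    dplyr::ungroup()
  surv <- choices |> dplyr::filter(.data$survivor)
  list(
    kept = dplyr::semi_join(peaks, surv, by = "feature_id"),
    choices = dplyr::select(choices, -".order"),
    ambiguous = unique(choices$lipid[choices$ambiguous & choices$n_candidates > 1])
  )
}

#' Per-sample lipid class and saturation group sums
#'
#' Adds lipids within a class (and within class-by-saturation subclasses,
#' e.g. total monounsaturated TG) per sample. Classes with no lipids are
#' absent from the output rather than zero-filled.
#'
#' @param abundance Tidy tibble with columns `sample`, `lipid`, `value`.
#' @param species Parsed species from [parse_lipid_name()] covering every
#'   lipid in `abundance`; parsed on the fly when omitted.
#' @return Tibble `sample`, `group` (e.g. `"total TG"`,
#'   `"TG monounsaturated"`), `value`.
#' @export
group_sums <- function(abundance, species = NULL) {
  abundance <- tibble::as_tibble(abundance)
  species <- species %||% parse_lipid_name(unique(abundance$lipid))
  sat <- classify_saturation(species)
  ann <- dplyr::left_join(
    abundance,
    dplyr::select(dplyr::left_join(
      dplyr::select(species, "raw_name", "lipid_class"),
      dplyr::select(sat, "raw_name", "saturation"), by = "raw_name"),
      lipid = "raw_name", "lipid_class", "saturation"),
    by = "lipid")
  class_tot <- ann |>
    dplyr::group_by(.data$sample, group = paste("total", .data$lipid_class)) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop")
  sat_tot <- ann |>
    dplyr::group_by(.data$sample,
                    group = paste(.data$lipid_class, .data$saturation)) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop")
  dplyr::arrange(dplyr::bind_rows(class_tot, sat_tot), .data$sample, .data$group)
}

#' Friedewald estimate of LDL cholesterol
#'
#' `LDL-C = total cholesterol - HDL-C - triglycerides / 2.2`, all in mmol/L.
#' Negative estimates are returned as-is but flagged.
#'
#' @param tc,hdl,tg Total cholesterol, HDL cholesterol and triglycerides
#'   (mmol/L), vectors of equal length.
#' @return Tibble with `ldl` and logical `flag_negative`.
#' @examples
#' friedewald_ldl(5.2, 1.3, 1.1) # 3.4 mmol/L
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(tc < 0 | hdl < 0 | tg < 0, na.rm = TRUE)) {
    abort("Inputs to the Friedewald equation must be non-negative.")
  }
  ldl <- tc - hdl - tg / 2.2
  tibble::tibble(ldl = ldl, flag_negative = ldl < 0)
}
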