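# Raw peak-table fixture exercising every lipidomics QC rule.

#' Simulate a raw lipid peak table for QC testing
#'
#' Builds a small, fully deterministic peak table in the layout exported by a
#' spectral-search program after alignment: one row per (feature, sample,
#' batch) with peak area, class internal-standard area, a rejection flag,
#' peak-quality score and identification match score (m-score). With
#' `violations = TRUE` (default) the table contains one planned violation of
#' each filtering rule plus a duplicate identification trio, so the
#' post-filter survivor set can be enumerated by hand:
#'
#' * `F03a/F03b/F03c`: the same TG identified three times with QC coefficients
#'   of variation 0.1 / 0.2 / 0.3 (duplicate resolution keeps `F03a`);
#' * `F04`: QC CV 0.45 (fails the CV < 0.4 rule);
#' * `F05`: average peak quality 0.70 (fails the > 0.75 rule);
#' * `F06`: rej = 1;
#' * `F07`: absent from one alignment batch.
#'
#' The clean survivors are features `F01`, `F02`, `F03a` and `F08`.
#'
#' @param n_batches Number of alignment batches (default 4).
#' @param violations Include the planned rule violations? With `FALSE` every
#'   feature passes every rule, so filtering is the identity.
#' @return Tibble with columns `feature_id`, `lipid`, `lipid_class`, `batch`,
#'   `sample`, `sample_type` (`study` or `qc`), `area`, `is_area`, `rej`,
#'   `peak_quality`, `m_score`.
#' @examples
#' raw <- simulate_raw_peak_table()
#' dplyr::count(raw, feature_id)
#' @export
simulate_raw_peak_table <- function(n_batches = 4, violations = TRUE) {
  features <- tibble::tribble(
    ~feature_id, ~lipid,                ~rej, ~peak_quality, ~m_score, ~qc_cv, ~miss_batch,
    "F01",  "Cer(d18:1/16:0)",   0L, 0.95, 8.1, 0.05, NA_integer_,
    "F02",  "PC(16:0/18:1)",     0L, 0.90, 7.5, 0.10, NA_integer_,
    "F03a", "TG(16:0/18:1/18:2)", 0L, 0.92, 7.0, 0.10, NA_integer_,
    "F03b", "TG(16:0/18:1/18:2)", 0L, 0.93, 7.2, 0.20, NA_integer_,
    "F03c", "TG(16:0/18:1/18:2)", 0L, 0.91, 6.8, 0.30, NA_integer_,
    "F08",  "PI(18:0/20:4)",     0L, 0.85, 6.2, 0.15, NA_integer_
  )
  if (violations) {
    features <- dplyr::bind_rows(features, tibble::tribble(
      ~feature_id, ~lipid,            ~rej, ~peak_quality, ~m_score, ~qc_cv, ~miss_batch,
      "F04", "SM(d18:1/24:1)",   0L, 0.88, 7.0, 0.45, NA_integer_,
      "F05", "LPC(18:1e)",       0L, 0.70, 6.5, 0.12, NA_integer_,
      "F06", "PE(16:0/20:4)",    1L, 0.89, 7.3, 0.08, NA_integer_,
      "F07", "DG(18:1/18:1)",    0L, 0.90, 7.1, 0.10, 3L
    ))
  }
  samples <- tibble::tibble(
    sample = c("S1", "S2", "S3", "QC1", "QC2", "QC3"),
    sample_type = c(rep("study", 3), rep("qc", 3))
  )
  grid <- tidyr::expand_grid(features, batch = seq_len(n_batches), samples) |>
    dplyr::filter(is.na(.data$miss_batch) | .data$batch != .data$miss_batch)

  # Normalized abundances are area / is_area with is_area fixed at 1000.
  # QC-sample values are (1 - d, 1, 1 + d) in every batch; across b batches
  # (3b values, mean 1) the sample SD is d * sqrt(2b / (3b - 1)), so d is
  # scaled to make the realized QC CV exactly the planned one.
  qc_mult <- c(QC1 = -1, QC2 = 0, QC3 = 1)
  d_scale <- sqrt((3 * n_batches - 1) / (2 * n_batches))
  base_study <- c(S1 = 0.8, S2 = 1.0, S3 = 1.3)
  grid |>
    dplyr::mutate(
      lipid_class = sub("\\(.*", "", .data$lipid),
      is_area = 1000,
      norm = dplyr::if_else(
        .data$sample_type == "qc",
        1 + qc_mult[.data$sample] * .data$qc_cv * d_scale,
        base_study[.data$sample] * (1 + 0.01 * .data$batch)
      ),
      area = .data$norm * .data$is_area
    ) |>
    dplyr::select("feature_id", "lipid", "lipid_class", "batch", "sample",
                  "sample_type", "area", "is_area", "rej", "peak_quality",
                  "m_score")
}
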