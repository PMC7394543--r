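# Covariate residualization and rank-based inverse normal transformation,
# the two data transformations applied to every trait before modelling.

#' Ordinary least-squares residualization against covariates
#'
#' Regresses a response on the covariate design and returns the residuals
#' (mean zero by construction). Rows with missing values in the response or
#' any covariate are dropped and reported.
#'
#' @param values Numeric response vector.
#' @param covariates Data frame of covariates (factors/characters are
#'   expanded to dummies via `model.matrix`).
#' @return List with `residuals` (named by the row indices kept), `kept`
#'   (logical vector of rows used) and `n_dropped`.
#' @export
residualize <- function(values, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(values)) {
    abort("`values` and `covariates` must have the same number of rows.")
  }
  keep <- complete.cases(covariates) & !is.na(values)
  X <- model.matrix(~ ., data = covariates[keep, , drop = FALSE])
  if (qr(X)$rank < ncol(X)) {
    r <- qr(X)
    collinear <- colnames(X)[r$pivot[seq(r$rank + 1, ncol(X))]]
    abort(paste0("Rank-deficient covariate design; collinear columns: ",
                 paste(collinear, collapse = ", ")))
  }
  fit <- lm.fit(X, values[keep])
  res <- fit$residuals
  names(res) <- which(keep)
  list(residuals = res, kept = keep, n_dropped = sum(!keep))
}

#' Rank-based inverse normal transform
#'
#' Maps values onto normal quantiles through their ranks:
#' `qnorm((rank - c) / (n - 2c + 1))` with Blom's offset `c = 3/8` by
#' default. Ties receive average ranks; the output is monotone in the input
#' and has mean zero by the symmetry of the offset ranks.
#'
#' @param values Numeric vector, length >= 3, not all identical.
#' @param offset Rank offset `c` in (0, 0.5], default `3/8`.
#' @return Numeric vector of transformed values.
#' @examples
#' inverse_normal_transform(c(3, 1, 2)) # middle value maps to 0
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) abort("Inverse normal transform needs at least 3 values.")
  if (max(values) == min(values)) {
    abort("Inverse normal transform is undefined when all values are identical.")
  }
  r <- rank(values, ties.method = "average")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Residualize and inverse-normal-transform a trait matrix
#'
#' Applies [residualize()] then [inverse_normal_transform()] to every trait
#' column, the standard two-step transformation applied to lipid abundances
#' before twin modelling and association testing. Samples with incomplete
#' covariates are dropped from all traits so the output stays rectangular.
#'
#' @param data Tibble with a `sample_id` column and one column per trait.
#' @param covariates Tibble aligned with `data` rows holding the adjustment
#'   covariates (no `sample_id` column needed; it is ignored if present).
#' @param int Apply the inverse normal transform after residualization
#'   (default `TRUE`).
#' @param offset INT rank offset, default Blom's 3/8.
#' @return Tibble with `sample_id` and the transformed trait columns.
#' @export
residualize_matrix <- function(data, covariates, int = TRUE, offset = 3 / 8) {
  data <- tibble::as_tibble(data)
  stopifnot("sample_id" %in% names(data))
  covariates <- dplyr::select(tibble::as_tibble(covariates),
                              -dplyr::any_of("sample_id"))
  traits <- setdiff(names(data), "sample_id")
  keep <- complete.cases(covariates)
  X <- model.matrix(~ ., data = as.data.frame(covariates[keep, , drop = FALSE]))
  qx <- qr(X)
  out <- purrr::map(traits, function(tr) {
    res <- qr.resid(qx, data[[tr]][keep])
    if (int) inverse_normal_transform(res, offset) else res
  })
  names(out) <- traits
  dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id[keep]),
                   tibble::as_tibble(out))
}
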