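# Lipidome-wide heritability screen: per-lipid model fits in one tidy table.

#' Fit twin variance-component models across a lipid panel
#'
#' For every trait column fits the four nested twin models (ACE, AE, CE, E),
#' reports the standardized components, heritability with its
#' profile-likelihood CI and likelihood-ratio p-value from the ACE fit, and
#' flags the AIC-best model per lipid.
#'
#' @param meta Per-individual metadata (see [make_twin_pairs()]).
#' @param values Tibble `sample_id` + trait columns (typically residualized,
#'   inverse-normal-transformed lipids).
#' @param traits Trait columns to fit (default all non-id columns).
#' @param models Models to fit per trait.
#' @param ci Compute profile CIs (slower), default TRUE.
#' @param h2_test Reference for the h2 test, see [fit_twin_ace()].
#' @return Tibble with one row per (lipid, model): `lipid`, `model`, `a2`,
#'   `c2`, `e2` (standardized), `h2`, `ci_lo`, `ci_hi`, `p_h2`, `loglik`,
#'   `aic`, `n_pairs`, `aic_best`.
#' @export
fit_lipidome_heritability <- function(meta, values, traits = NULL,
                                      models = c("ACE", "AE", "CE", "E"),
                                      ci = TRUE,
                                      h2_test = c("chisq1", "mixture")) {
  h2_test <- match.arg(h2_test)
  traits <- traits %||% setdiff(names(values), "sample_id")
  purrr::map_dfr(traits, function(tr) {
    pr <- make_twin_pairs(meta, values, tr)
    rows <- purrr::map_dfr(models, function(m) {
      fit <- fit_twin_ace(pr, m, ci = ci && m %in% c("ACE", "AE"),
                          h2_test = h2_test)
      tibble::tibble(
        lipid = tr, model = m,
        a2 = unname(fit$std_components["a2"]),
        c2 = unname(fit$std_components["c2"]),
        e2 = unname(fit$std_components["e2"]),
        h2 = fit$h2, ci_lo = fit$h2_ci[[1]], ci_hi = fit$h2_ci[[2]],
        p_h2 = fit$p_h2, loglik = fit$loglik, aic = fit$aic,
        n_pairs = fit$n_pairs)
    })
    dplyr::mutate(rows, aic_best = .data$aic == min(.data$aic))
  })
}

#' Genetic and environmental correlations across trait pairs
#'
#' Fits the bivariate Cholesky model ([fit_bivariate_cholesky()]) to every
#' requested trait pair.
#'
#' @param meta,values As in [fit_lipidome_heritability()].
#' @param trait_pairs Two-column data frame (or tibble) of trait name pairs;
#'   default all distinct pairs of the value columns.
#' @return Tibble: `trait1`, `trait2`, `rg`, `rc`, `re`, `rp`, `loglik`.
#' @export
twin_correlations_table <- function(meta, values, trait_pairs = NULL) {
  if (is.null(trait_pairs)) {
    traits <- setdiff(names(values), "sample_id")
    cmb <- utils::combn(traits, 2)
    trait_pairs <- tibble::tibble(trait1 = cmb[1, ], trait2 = cmb[2, ])
  }
  trait_pairs <- tibble::as_tibble(trait_pairs)
  names(trait_pairs)[1:2] <- c("trait1", "trait2")
  purrr::pmap_dfr(trait_pairs[, 1:2], function(trait1, trait2) {
    pr <- make_twin_pairs_biv(meta, values, c(trait1, trait2))
    fit <- fit_bivariate_cholesky(pr)
    tibble::tibble(trait1 = trait1, trait2 = trait2, rg = fit$rg,
                   rc = fit$rc, re = fit$re, rp = fit$rp, loglik = fit$loglik)
  })
}
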