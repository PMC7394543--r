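# Pair-clustered association of lipid residuals with expression probes,
# Bonferroni control, penalized probe selection and likelihood-based
# variance explained.

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 35971) # 1.39e-06
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (n_tests < 1) abort("`n_tests` must be >= 1.")
  alpha / n_tests
}

# One mixed-model association: y ~ x (standardized) with a random pair
# intercept, fitted by ML. Wald t with containment-style residual df
# n_obs - 2 fixed effects - (n_groups - 1); a boundary (singular) random
# effect is flagged, where the fit coincides with ordinary least squares.
assoc_mixed_one <- function(y, x, pair_id) {
  xs <- as.numeric(scale(x))
  df <- data.frame(y = y, x = xs, pair_id = pair_id)
  fit <- suppressMessages(lme4::lmer(y ~ x + (1 | pair_id), data = df,
                                     REML = FALSE))
  beta <- lme4::fixef(fit)[["x"]]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2]
  n <- nrow(df)
  ddf <- n - 2 - (dplyr::n_distinct(pair_id) - 1)
  stat <- beta / se
  tibble::tibble(
    beta = beta, se = se, statistic = stat,
    p_value = 2 * stats::pt(abs(stat), df = max(ddf, 1), lower.tail = FALSE),
    singular_fit = lme4::isSingular(fit)
  )
}

#' Mixed-model association of lipids with expression probes
#'
#' For every (lipid, probe) combination fits the linear mixed model
#' `lipid ~ probe + (1 | pair)` by maximum likelihood, with the probe values
#' standardized to unit variance so effect sizes are comparable across
#' probes, and tests the probe coefficient by a Wald t test. Significance is
#' called at the Bonferroni threshold `alpha / (number of probe columns)`.
#'
#' @param lipids Tibble `sample_id` + lipid residual columns.
#' @param expression Tibble `sample_id` + probe residual columns.
#' @param meta Tibble with `sample_id`, `pair_id`.
#' @param lipid_cols,probe_cols Columns to test (default: all non-id
#'   columns).
#' @param alpha Family-wise error rate for the Bonferroni call, default
#'   0.05.
#' @return Tibble with one row per (lipid, probe): `lipid`, `probe`, `beta`,
#'   `se`, `statistic`, `p_value`, `significant`, `direction`
#'   (`"positive"` / `"inverse"`), `singular_fit`, plus the threshold used
#'   as an attribute `"threshold"`.
#' @export
mixed_model_association <- function(lipids, expression, meta,
                                    lipid_cols = NULL, probe_cols = NULL,
                                    alpha = 0.05) {
  lipid_cols <- lipid_cols %||% setdiff(names(lipids), "sample_id")
  probe_cols <- probe_cols %||% setdiff(names(expression), "sample_id")
  dat <- dplyr::inner_join(
    dplyr::inner_join(lipids, expression, by = "sample_id"),
    dplyr::select(meta, "sample_id", "pair_id"), by = "sample_id")
  thr <- bonferroni_threshold(alpha, length(probe_cols))
  out <- tidyr::expand_grid(lipid = lipid_cols, probe = probe_cols) |>
    dplyr::mutate(res = purrr::map2(.data$lipid, .data$probe, function(l, p) {
      assoc_mixed_one(dat[[l]], dat[[p]], dat$pair_id)
    })) |>
    tidyr::unnest("res") |>
    dplyr::mutate(
      significant = .data$p_value <= thr,
      direction = dplyr::if_else(.data$beta >= 0, "positive", "inverse")
    )
  attr(out, "threshold") <- thr
  out
}

#' Lasso selection of associated probes
#'
#' L1-penalized linear regression of a lipid on its candidate probes (those
#' passing the Bonferroni screen), with the penalty chosen by seeded k-fold
#' cross-validation: at the minimum-CV lambda by default, or at the sparser
#' one-standard-error lambda with `rule = "lambda.1se"`. Probes with non-zero
#' coefficients are returned; under exact collinearity the lasso keeps at
#' least one member of a duplicated pair, which one being an arbitrary but
#' deterministic tie-break of the coordinate-descent path.
#'
#' @param y Lipid residual vector.
#' @param probes Matrix or tibble of candidate probe values (columns named).
#' @param nfolds Cross-validation folds, default 10.
#' @param seed Seed controlling the fold assignment.
#' @param rule Penalty choice, `"lambda.min"` (default) or `"lambda.1se"`.
#' @return Character vector of selected probe names (possibly empty).
#' @export
select_probes_penalized <- function(y, probes, nfolds = 10, seed = 1,
                                    rule = c("lambda.min", "lambda.1se")) {
  rule <- match.arg(rule)
  X <- as.matrix(probes)
  if (ncol(X) < 1) abort("Need at least one candidate probe.")
  if (ncol(X) == 1) {
    # cv.glmnet needs >= 2 columns; fall back to the marginal test
    # (suppressed warning: lm flags an essentially perfect fit when the
    # single candidate equals the response, which is a legitimate input here)
    p <- suppressWarnings(summary(lm(y ~ X[, 1]))$coefficients[2, 4])
    return(if (p < 0.05) colnames(X) else character(0))
  }
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), length(y))))
  cvfit <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = foldid)
  cf <- as.matrix(coef(cvfit, s = rule))[-1, 1]
  names(cf)[cf != 0]
}

#' Likelihood-based variance explained (McFadden and Nagelkerke pseudo-r2)
#'
#' Compares the maximum-likelihood fits of the full model
#' `lipid ~ selected probes + (1 | pair)` and the null model
#' `lipid ~ 1 + (1 | pair)`:
#' McFadden `= 1 - ll_full / ll_null` and Nagelkerke
#' `= (1 - exp(2/n (ll_null - ll_full))) / (1 - exp(2/n ll_null))`, both
#' clipped to `[0, 1]`. An empty probe set yields 0 for both.
#'
#' @param y Lipid residual vector.
#' @param probes Matrix/tibble of the selected probes (0 columns allowed).
#' @param pair_id Pair identifiers for the random intercept.
#' @return Tibble: `n_probes`, `mcfadden`, `nagelkerke`, `loglik_null`,
#'   `loglik_full`.
#' @export
variance_explained <- function(y, probes, pair_id) {
  X <- as.matrix(probes)
  df <- data.frame(y = y, pair_id = pair_id)
  ll0 <- as.numeric(logLik(suppressMessages(
    lme4::lmer(y ~ 1 + (1 | pair_id), data = df, REML = FALSE))))
  if (ncol(X) == 0) {
    return(tibble::tibble(n_probes = 0L, mcfadden = 0, nagelkerke = 0,
                          loglik_null = ll0, loglik_full = ll0))
  }
  if (nrow(df) <= ncol(X) + 2) abort("Too few samples for the selected probe count.")
  df2 <- cbind(df, as.data.frame(X))
  fml <- as.formula(paste("y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + "),
                          "+ (1 | pair_id)"))
  ll1 <- as.numeric(logLik(suppressMessages(
    lme4::lmer(fml, data = df2, REML = FALSE))))
  if (ll1 < ll0 - 1e-6) {
    abort("Full-model likelihood below null: refit required.")
  }
  n <- length(y)
  tibble::tibble(
    n_probes = ncol(X),
    mcfadden = min(max(1 - ll1 / ll0, 0), 1),
    nagelkerke = min(max((1 - exp(2 / n * (ll0 - ll1))) / (1 - exp(2 / n * ll0)), 0), 1),
    loglik_null = ll0, loglik_full = ll1
  )
}
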