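# Univariate twin structural equation models (ACE / AE / CE / E) by maximum
# likelihood.
#
# The pair likelihood uses the classical identities: with path coefficients
# (a, c, e) the trait variance is v = a^2 + c^2 + e^2 and the within-pair
# covariance is a^2 + c^2 for MZ pairs and 0.5 a^2 + c^2 for DZ pairs. The
# sum/difference transform s = (y1 + y2)/sqrt(2), d = (y1 - y2)/sqrt(2)
# diagonalizes the exchangeable 2x2 covariance (Var s = v + cov,
# Var d = v - cov, independent), so the whole-sample log-likelihood is a
# closed function of per-group sufficient statistics (n, sum s, sum s^2,
# sum d^2). Every optimizer step is then O(1) in the number of pairs, which
# is what makes the replicate-heavy calibration studies cheap.

#' Build a per-pair trait table from individual-level data
#'
#' Joins per-individual metadata with one trait column and reshapes to one
#' row per complete twin pair. Pairs with a missing co-twin value are
#' dropped (listwise per trait).
#'
#' @param meta Tibble with `sample_id`, `pair_id`, `zygosity`, `member`,
#'   `sex`, `age` (e.g. `simulate_twin_cohort()$pairs`).
#' @param values Tibble with `sample_id` and trait columns.
#' @param trait Name of the trait column to extract.
#' @return Tibble with `pair_id`, `zygosity`, `age`, `sex1`, `sex2`,
#'   `y1`, `y2`.
#' @export
make_twin_pairs <- function(meta, values, trait) {
  df <- dplyr::left_join(
    dplyr::select(meta, "sample_id", "pair_id", "zygosity", "member",
                  dplyr::any_of(c("sex", "age"))),
    dplyr::select(values, "sample_id", dplyr::all_of(trait)),
    by = "sample_id")
  names(df)[names(df) == trait] <- ".y"
  wide <- df |>
    tidyr::pivot_wider(id_cols = c("pair_id", "zygosity", dplyr::any_of("age")),
                       names_from = "member",
                       values_from = c(dplyr::any_of("sex"), ".y")) |>
    dplyr::rename(y1 = ".y_1", y2 = ".y_2")
  if ("sex_1" %in% names(wide)) {
    wide <- dplyr::rename(wide, sex1 = "sex_1", sex2 = "sex_2")
  }
  dplyr::filter(wide, !is.na(.data$y1) & !is.na(.data$y2))
}

# per-zygosity sufficient statistics for the exchangeable bivariate normal
univ_suffstats <- function(pairs) {
  lapply(split(pairs, pairs$zygosity), function(g) {
    s <- (g$y1 + g$y2) / sqrt(2)
    d <- (g$y1 - g$y2) / sqrt(2)
    list(n = nrow(g), sum_s = sum(s), sum_s2 = sum(s^2), sum_d2 = sum(d^2))
  })
}

LL_FLOOR <- -1e15

ll_from_suffstats <- function(a, c, e, mu, st) {
  v <- a^2 + c^2 + e^2
  ll <- 0
  for (z in names(st)) {
    covz <- if (z == "MZ") a^2 + c^2 else 0.5 * a^2 + c^2
    ss <- v + covz
    dd <- v - covz
    g <- st[[z]]
    if (ss <= 1e-12) return(LL_FLOOR * (1 + abs(ss)))
    if (dd <= 1e-12) {
      # singular within-pair covariance: impossible unless members are equal
      if (g$sum_d2 > 1e-20) return(LL_FLOOR * (1 - dd))
      dd_part <- 0
    } else {
      dd_part <- -g$n / 2 * log(2 * pi * dd) - g$sum_d2 / (2 * dd)
    }
    qs <- g$sum_s2 - 2 * sqrt(2) * mu * g$sum_s + 2 * g$n * mu^2
    ll <- ll - g$n / 2 * log(2 * pi * ss) - qs / (2 * ss) + dd_part
  }
  ll
}

#' Twin-pair log-likelihood of an ACE parameterization
#'
#' Sum over pairs of the bivariate normal log-density implied by path
#' coefficients `(a, c, e)` and a free grand mean: variance
#' `a^2 + c^2 + e^2` for each member, within-pair covariance `a^2 + c^2`
#' (MZ) or `0.5 a^2 + c^2` (DZ). Returns `-Inf` (never an error) when the
#' implied covariance is singular or not positive definite, so it is safe
#' inside an optimizer.
#'
#' @param params Numeric vector `c(a, c, e, mu)`.
#' @param pairs Pair tibble from [make_twin_pairs()].
#' @return The log-likelihood (scalar), `-Inf` for degenerate parameters.
#' @export
pair_loglik <- function(params, pairs) {
  st <- univ_suffstats(pairs)
  ll <- ll_from_suffstats(params[1], params[2], params[3], params[4], st)
  if (ll <= LL_FLOOR) -Inf else ll
}

# Multi-start Nelder-Mead with BFGS polish; returns the best converged fit.
ml_optimize <- function(starts, fn, reltol = 1e-10) {
  best <- NULL
  for (p0 in starts) {
    o <- tryCatch(
      optim(p0, fn, method = "Nelder-Mead",
            control = list(fnscale = -1, reltol = reltol, maxit = 2000)),
      error = function(e) NULL)
    if (is.null(o)) next
    o2 <- tryCatch(
      optim(o$par, fn, method = "BFGS",
            control = list(fnscale = -1, reltol = reltol, maxit = 500)),
      error = function(e) o)
    if (!is.null(o2) && o2$value >= o$value) o <- o2
    if (is.null(best) || o$value > best$value) best <- o
  }
  if (is.null(best) || best$value <= LL_FLOOR / 2) {
    abort("Twin model optimization failed to converge from all starting points.")
  }
  best
}

ace_starts <- function(pairs, model) {
  cors <- twin_correlations(pairs)
  vtot <- var(c(pairs$y1, pairs$y2))
  mu0 <- mean(c(pairs$y1, pairs$y2))
  h2_0 <- min(max(2 * (cors$r_mz - cors$r_dz), 0.01), 0.95)
  c2_0 <- min(max(2 * cors$r_dz - cors$r_mz, 0.01), 0.95)
  e2_0 <- max(1 - h2_0 - c2_0, 0.05)
  tot <- h2_0 + c2_0 + e2_0
  base <- sqrt(vtot * c(h2_0, c2_0, e2_0) / tot)
  jitters <- list(c(1, 1, 1), c(0.5, 0.5, 1.4), c(1.4, 0.3, 1),
                  c(0.3, 1.4, 1), c(1, 1, 0.6))
  lapply(jitters, function(j) {
    p <- base * j
    switch(model,
           ACE = c(p[1], p[2], p[3], mu0),
           AE  = c(sqrt(p[1]^2 + p[2]^2), p[3], mu0),
           CE  = c(sqrt(p[1]^2 + p[2]^2), p[3], mu0),
           E   = c(sqrt(sum(p^2)), mu0))
  })
}

#' Empirical within-pair twin correlations
#'
#' Pearson correlations between co-twin trait values per zygosity group.
#'
#' @param pairs Pair tibble from [make_twin_pairs()].
#' @return Tibble with `r_mz`, `r_dz` and group sizes.
#' @export
twin_correlations <- function(pairs) {
  by_z <- split(pairs, pairs$zygosity)
  tibble::tibble(
    r_mz = if (!is.null(by_z$MZ)) cor(by_z$MZ$y1, by_z$MZ$y2) else NA_real_,
    r_dz = if (!is.null(by_z$DZ)) cor(by_z$DZ$y1, by_z$DZ$y2) else NA_real_,
    n_mz = if (!is.null(by_z$MZ)) nrow(by_z$MZ) else 0L,
    n_dz = if (!is.null(by_z$DZ)) nrow(by_z$DZ) else 0L
  )
}

#' Falconer's moment estimator of heritability
#'
#' `h^2 = 2 (rMZ - rDZ)`, clipped to `[0, 1]`; the classical closed-form
#' estimate used here as an independent cross-check of the maximum-likelihood
#' fits.
#'
#' @param r_mz,r_dz Within-pair correlations for MZ and DZ pairs.
#' @return Heritability estimate in `[0, 1]`.
#' @examples
#' falconer_h2(0.7, 0.45) # 0.5
#' @export
falconer_h2 <- function(r_mz, r_dz) {
  if (any(abs(c(r_mz, r_dz)) > 1, na.rm = TRUE)) {
    abort("Correlations must lie in [-1, 1].")
  }
  pmin(pmax(2 * (r_mz - r_dz), 0), 1)
}

#' Fit a univariate twin variance-component model
#'
#' Maximum-likelihood fit of the ACE model or its nested submodels (AE, CE,
#' E) to twin-pair data, parameterized by path coefficients so variance
#' components are non-negative by construction. Optimization is multi-start
#' (Nelder-Mead with BFGS polish) from moment-based starting values. The
#' returned object reports raw components, standardized shares
#' (`h2 = a2 / (a2 + c2 + e2)` etc.), log-likelihood and AIC; with
#' `ci = TRUE` it adds a profile-likelihood confidence interval for `h2`
#' and, for the ACE model, the likelihood-ratio p-value for the additive
#' genetic component against the CE submodel.
#'
#' @param pairs Pair tibble from [make_twin_pairs()].
#' @param model One of `"ACE"`, `"AE"`, `"CE"`, `"E"`.
#' @param ci Compute the profile-likelihood CI for h2 (ACE/AE only)?
#' @param level CI level, default 0.95.
#' @param h2_test Reference distribution for the h2 likelihood-ratio test:
#'   `"chisq1"` (default) or `"mixture"` (50:50 chi0/chi1 boundary mixture).
#' @param n_starts Number of optimizer starts (>= 1).
#' @return An object of class `twin_ace_fit`; see [tidy.twin_ace_fit()] and
#'   [glance.twin_ace_fit()].
#' @examples
#' cohort <- simulate_twin_cohort(
#'   twin_sim_config(n_mz_pairs = 200, n_dz_pairs = 200, n_lipids = 1,
#'                   a2 = 0.5, c2 = 0.2, e2 = 0.3, seed = 11))
#' pr <- make_twin_pairs(cohort$pairs, cohort$lipids,
#'                       cohort$truth$lipid_names[1])
#' fit <- fit_twin_ace(pr, ci = FALSE)
#' fit$h2
#' @export
fit_twin_ace <- function(pairs, model = c("ACE", "AE", "CE", "E"),
                         ci = TRUE, level = 0.95,
                         h2_test = c("chisq1", "mixture"), n_starts = 5) {
  model <- match.arg(model)
  h2_test <- match.arg(h2_test)
  if (model %in% c("ACE", "AE")) {
    zt <- table(pairs$zygosity)
    if (is.na(zt["MZ"]) || is.na(zt["DZ"]) || zt["MZ"] < 2 || zt["DZ"] < 2) {
      abort("Models with an A component need at least 2 MZ and 2 DZ pairs.")
    }
  }
  st <- univ_suffstats(pairs)
  fn <- switch(model,
    ACE = function(p) ll_from_suffstats(p[1], p[2], p[3], p[4], st),
    AE  = function(p) ll_from_suffstats(p[1], 0, p[2], p[3], st),
    CE  = function(p) ll_from_suffstats(0, p[1], p[2], p[3], st),
    E   = function(p) ll_from_suffstats(0, 0, p[1], p[2], st))
  starts <- head(ace_starts(pairs, model), max(1, n_starts))
  best <- ml_optimize(starts, fn)
  p <- abs(best$par)
  comp <- switch(model,
    ACE = c(a2 = p[1]^2, c2 = p[2]^2, e2 = p[3]^2),
    AE  = c(a2 = p[1]^2, c2 = 0, e2 = p[2]^2),
    CE  = c(a2 = 0, c2 = p[1]^2, e2 = p[2]^2),
    E   = c(a2 = 0, c2 = 0, e2 = p[1]^2))
  mu <- best$par[length(best$par)]
  tot <- sum(comp)
  std <- comp / tot
  npar <- length(best$par)
  fit <- structure(list(
    model = model,
    paths = sqrt(comp),
    components = comp,
    std_components = std,
    h2 = unname(std["a2"]),
    c2_std = unname(std["c2"]),
    e2_std = unname(std["e2"]),
    mean = mu,
    loglik = best$value,
    npar = npar,
    aic = -2 * best$value + 2 * npar,
    n_pairs = nrow(pairs),
    h2_ci = c(NA_real_, NA_real_),
    p_h2 = NA_real_,
    level = level,
    suffstats = st
  ), class = "twin_ace_fit")
  if (model == "ACE") {
    ce <- fit_twin_ace(pairs, "CE", ci = FALSE, n_starts = n_starts)
    fit$p_h2 <- h2_significance(fit, ce, reference = h2_test)
  }
  if (ci && model %in% c("ACE", "AE")) {
    fit$h2_ci <- h2_profile_ci(pairs, fit, level = level)
  }
  fit
}

#' @export
print.twin_ace_fit <- function(x, ...) {
  cat(sprintf("<twin_ace_fit: %s model, %d pairs>\n", x$model, x$n_pairs))
  cat(sprintf("  h2 = %.3f  c2 = %.3f  e2 = %.3f  (standardized)\n",
              x$h2, x$c2_std, x$e2_std))
  if (!is.na(x$h2_ci[1])) {
    cat(sprintf("  h2 %d%% CI [%.3f, %.3f]\n", round(100 * x$level),
                x$h2_ci[1], x$h2_ci[2]))
  }
  if (!is.na(x$p_h2)) cat(sprintf("  p(h2) = %.4g\n", x$p_h2))
  cat(sprintf("  logLik = %.3f  AIC = %.2f\n", x$loglik, x$aic))
  invisible(x)
}

#' Likelihood-ratio test of the additive genetic component
#'
#' Refers `2 * (logLik(ACE) - logLik(CE))` to a chi-square reference with
#' 1 df (default) or to the 50:50 chi0/chi1 boundary mixture that accounts
#' for the variance component being tested on its boundary. A p-value below
#' 0.05 indicates significant heritability.
#'
#' @param ace_fit,ce_fit Fits from [fit_twin_ace()] on identical data.
#' @param reference `"chisq1"` or `"mixture"`.
#' @return The p-value.
#' @export
h2_significance <- function(ace_fit, ce_fit, reference = c("chisq1", "mixture")) {
  reference <- match.arg(reference)
  lr <- 2 * (ace_fit$loglik - ce_fit$loglik)
  if (lr < -1e-4) {
    abort("Negative likelihood ratio: the ACE fit did not reach its optimum; refit.")
  }
  lr <- max(lr, 0)
  if (lr == 0) return(1)
  p1 <- pchisq(lr, df = 1, lower.tail = FALSE)
  if (reference == "chisq1") p1 else 0.5 * p1
}

# profile log-likelihood at a fixed h2 = t: a2 = t*V, c2 = s*V,
# e2 = (1 - t - s)*V with free (log V, logit share, mu)
profile_ll_at_h2 <- function(t, st, fit) {
  t <- min(max(t, 0), 1 - 1e-9)
  vhat <- sum(fit$components)
  s0 <- if (fit$c2_std > 0 && fit$c2_std < 1) {
    min(max(fit$c2_std / max(1 - fit$h2, 1e-6), 1e-4), 1 - 1e-4)
  } else 0.2
  fn <- function(q) {
    V <- exp(q[1])
    s <- (1 - t) * plogis(q[2])
    ll_from_suffstats(sqrt(t * V), sqrt(s * V), sqrt(max(1 - t - s, 0) * V),
                      q[3], st)
  }
  starts <- list(c(log(vhat), qlogis(s0), fit$mean),
                 c(log(vhat), qlogis(0.5), fit$mean),
                 c(log(vhat), qlogis(0.05), fit$mean))
  ml_optimize(starts, fn, reltol = 1e-9)$value
}

#' Profile-likelihood confidence interval for heritability
#'
#' Bounds are the values of `h2` at which twice the drop from the maximized
#' log-likelihood equals the chi-square(1) quantile of the requested level,
#' with total variance, the c2 share and the mean re-maximized at every
#' candidate `h2` (profile likelihood). Bounds are clipped to `[0, 1]`.
#'
#' @param pairs Pair tibble from [make_twin_pairs()].
#' @param fit A converged `"ACE"` or `"AE"` fit from [fit_twin_ace()].
#' @param level Confidence level, default 0.95.
#' @return Numeric `c(lo, hi)`.
#' @export
h2_profile_ci <- function(pairs, fit, level = 0.95) {
  st <- fit$suffstats %||% univ_suffstats(pairs)
  crit <- qchisq(level, df = 1)
  llhat <- fit$loglik
  f <- function(t) 2 * (llhat - profile_ll_at_h2(t, st, fit)) - crit
  h2 <- min(max(fit$h2, 1e-6), 1 - 1e-6)
  lo <- if (f(0) <= 0) 0 else {
    uniroot(f, lower = 0, upper = h2, tol = 1e-5, extendInt = "no")$root
  }
  hi_probe <- 1 - 1e-6
  hi <- if (f(hi_probe) <= 0) 1 else {
    uniroot(f, lower = h2, upper = hi_probe, tol = 1e-5, extendInt = "no")$root
  }
  c(lo = max(0, lo), hi = min(1, hi))
}
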