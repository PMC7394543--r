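# broom-style tidy() / glance() methods for the fitted twin models.

#' Tidy a univariate twin fit
#'
#' @param x A `twin_ace_fit`.
#' @param ... Unused.
#' @return Tibble with one row per variance component: `term`, `estimate`
#'   (raw), `std_estimate` (share of total variance).
#' @export
tidy.twin_ace_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a2", "c2", "e2"),
    estimate = unname(x$components),
    std_estimate = unname(x$std_components))
}

#' One-row summary of a univariate twin fit
#'
#' @param x A `twin_ace_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `h2`, `h2_lo`, `h2_hi`, `p_h2`, `logLik`,
#'   `AIC`, `npar`, `n_pairs`.
#' @export
glance.twin_ace_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, h2 = x$h2,
    h2_lo = x$h2_ci[[1]], h2_hi = x$h2_ci[[2]], p_h2 = x$p_h2,
    logLik = x$loglik, AIC = x$aic, npar = x$npar, n_pairs = x$n_pairs)
}

#' Tidy a bivariate Cholesky fit
#'
#' @param x A `twin_biv_fit`.
#' @param ... Unused.
#' @return Tibble `term` (`rg`, `rc`, `re`, `rp`), `estimate`.
#' @export
tidy.twin_biv_fit <- function(x, ...) {
  tibble::tibble(term = c("rg", "rc", "re", "rp"),
                 estimate = c(x$rg, x$rc, x$re, x$rp))
}

#' @export
glance.twin_biv_fit <- function(x, ...) {
  tibble::tibble(rg = x$rg, rc = x$rc, re = x$re, rp = x$rp,
                 logLik = x$loglik, AIC = x$aic, n_pairs = x$n_pairs,
                 degenerate = x$degenerate)
}

#' Tidy a sex-heterogeneity fit
#'
#' @param x A `twin_sexhet_fit`.
#' @param ... Unused.
#' @return Tibble `sex`, `term`, `std_estimate`.
#' @export
tidy.twin_sexhet_fit <- function(x, ...) {
  tibble::tibble(
    sex = rep(c("male", "female"), each = 3),
    term = rep(c("a2", "c2", "e2"), 2),
    std_estimate = c(unname(x$male), unname(x$female)))
}

#' @export
glance.twin_sexhet_fit <- function(x, ...) {
  tibble::tibble(h2_male = unname(x$h2_male), h2_female = unname(x$h2_female),
                 logLik_het = x$loglik_het, logLik_hom = x$loglik_hom,
                 lrt = x$lrt, df = x$df, p_value = x$p_value,
                 n_pairs = x$n_pairs)
}

#' Tidy an age-moderation fit
#'
#' @param x A `twin_gxe_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` for the six path coefficients.
#' @export
tidy.twin_gxe_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.twin_gxe_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, logLik_ace = x$loglik_ace,
                 lrt = x$lrt, df = x$df, p_value = x$p_value,
                 n_pairs = x$n_pairs)
}
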