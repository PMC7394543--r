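# Bivariate Cholesky twin model: genetic, shared- and unique-environment
# correlations between two traits from the 4-variate pair likelihood.
#
# Each of the A, C and E 2x2 covariance matrices is parameterized by a lower
# triangular Cholesky factor, which keeps the implied 4x4 pair covariance
# positive semidefinite by construction. As in the univariate case the
# sum/difference transform across co-twins splits the 4-variate density into
# two independent 2-variate ones, and per-group sufficient statistics make
# each likelihood evaluation O(1) in pair count.

#' Build a per-pair table for two traits
#'
#' @param meta,values As in [make_twin_pairs()].
#' @param traits Character vector of two trait column names.
#' @return Tibble with `pair_id`, `zygosity` and the four trait values
#'   `y1_t1`, `y1_t2`, `y2_t1`, `y2_t2` (member index first).
#' @export
make_twin_pairs_biv <- function(meta, values, traits) {
  stopifnot(length(traits) == 2)
  p1 <- make_twin_pairs(meta, values, traits[1])
  p2 <- make_twin_pairs(meta, values, traits[2])
  out <- dplyr::inner_join(
    dplyr::select(p1, "pair_id", "zygosity", y1_t1 = "y1", y2_t1 = "y2"),
    dplyr::select(p2, "pair_id", y1_t2 = "y1", y2_t2 = "y2"),
    by = "pair_id")
  out
}

biv_suffstats <- function(pairs) {
  lapply(split(pairs, pairs$zygosity), function(g) {
    s <- cbind((g$y1_t1 + g$y2_t1), (g$y1_t2 + g$y2_t2)) / sqrt(2)
    d <- cbind((g$y1_t1 - g$y2_t1), (g$y1_t2 - g$y2_t2)) / sqrt(2)
    list(n = nrow(g), sum_s = colSums(s),
         ss_s = crossprod(s), ss_d = crossprod(d))
  })
}

# quadratic-form log-likelihood piece for one 2x2 covariance M given raw
# second moments SS, sum vector sv (zero for differences) and mean m
ll_gauss2 <- function(M, n, SS, sv, m) {
  det_m <- M[1, 1] * M[2, 2] - M[1, 2]^2
  if (det_m <= 1e-14 || M[1, 1] <= 0) return(NA_real_)
  Minv <- matrix(c(M[2, 2], -M[1, 2], -M[1, 2], M[1, 1]), 2) / det_m
  quad <- sum(Minv * SS) - 2 * drop(m %*% Minv %*% sv) + n * drop(m %*% Minv %*% m)
  -n * log(2 * pi) - n / 2 * log(det_m) - quad / 2
}

biv_ll <- function(par, st) {
  L <- function(v) matrix(c(v[1], v[2], 0, v[3]), 2)
  A <- tcrossprod(L(par[1:3]))
  C <- tcrossprod(L(par[4:6]))
  E <- tcrossprod(L(par[7:9]))
  mu <- par[10:11]
  W <- A + C + E
  ll <- 0
  for (z in names(st)) {
    gamma <- if (z == "MZ") 1 else 0.5
    B <- gamma * A + C
    g <- st[[z]]
    ll_s <- ll_gauss2(W + B, g$n, g$ss_s, g$sum_s, sqrt(2) * mu)
    ll_d <- ll_gauss2(W - B, g$n, g$ss_d, c(0, 0), c(0, 0))
    if (is.na(ll_s) || is.na(ll_d)) return(LL_FLOOR)
    ll <- ll + ll_s + ll_d
  }
  ll
}

component_cor <- function(M, tol = 1e-6) {
  if (M[1, 1] < tol || M[2, 2] < tol) return(NA_real_)
  max(min(M[1, 2] / sqrt(M[1, 1] * M[2, 2]), 1), -1)
}

#' Fit the bivariate Cholesky twin model
#'
#' Maximum-likelihood fit of the two-trait ACE model with A, C and E each
#' parameterized by a 2x2 lower-triangular Cholesky factor. Reports the
#' genetic correlation `rg = A12 / sqrt(A11 A22)`, the shared- and
#' unique-environment correlations `rc`, `re` likewise, and the phenotypic
#' correlation `rp` from the implied total covariance. A correlation whose
#' component variance is numerically zero is reported as `NA` (absent), not
#' as 0. If the two traits are numerically identical the model is singular;
#' the marginal univariate fit is returned with all correlations set to 1.
#'
#' @param pairs Pair tibble from [make_twin_pairs_biv()].
#' @param n_starts Number of optimizer starts.
#' @return An object of class `twin_biv_fit` with elements `rg`, `rc`, `re`,
#'   `rp`, the component matrices `A`, `C`, `E`, Cholesky factors, marginal
#'   standardized components, `loglik`, `npar`, `aic`.
#' @export
fit_bivariate_cholesky <- function(pairs, n_starts = 4) {
  y_t1 <- c(pairs$y1_t1, pairs$y2_t1)
  y_t2 <- c(pairs$y1_t2, pairs$y2_t2)
  if (abs(cor(y_t1, y_t2)) > 1 - 1e-12) {
    uni <- fit_twin_ace(to_univ_pairs(pairs, 1), "ACE", ci = FALSE)
    comp <- uni$components
    mk <- function(v) matrix(v * c(1, 1, 1, 1), 2)
    out <- structure(list(
      rg = 1, rc = if (comp["c2"] > 1e-6) 1 else NA_real_, re = 1, rp = 1,
      A = mk(comp["a2"]), C = mk(comp["c2"]), E = mk(comp["e2"]),
      chol = NULL, marginal = list(uni$std_components, uni$std_components),
      loglik = NA_real_, npar = NA_integer_, aic = NA_real_,
      n_pairs = nrow(pairs), degenerate = TRUE
    ), class = "twin_biv_fit")
    return(out)
  }
  st <- biv_suffstats(pairs)
  fn <- function(p) biv_ll(p, st)

  u1 <- fit_twin_ace(to_univ_pairs(pairs, 1), "ACE", ci = FALSE)
  u2 <- fit_twin_ace(to_univ_pairs(pairs, 2), "ACE", ci = FALSE)
  rp0 <- cor(y_t1, y_t2)
  mu0 <- c(mean(y_t1), mean(y_t2))
  mk_start <- function(rho) {
    # seed cross paths so each component carries correlation rho
    f <- function(fit1, fit2, comp) {
      s1 <- sqrt(max(fit1$components[comp], 1e-3))
      s2 <- sqrt(max(fit2$components[comp], 1e-3))
      c(s1, rho * s2, sqrt(max(1 - rho^2, 1e-4)) * s2)
    }
    c(f(u1, u2, "a2"), f(u1, u2, "c2"), f(u1, u2, "e2"), mu0)
  }
  starts <- lapply(c(rp0, 0, 0.7 * sign(rp0 + 1e-12), -0.3), mk_start)
  best <- ml_optimize(head(starts, max(1, n_starts)), fn)

  p <- best$par
  L <- function(v) matrix(c(v[1], v[2], 0, v[3]), 2)
  A <- tcrossprod(L(p[1:3])); C <- tcrossprod(L(p[4:6])); E <- tcrossprod(L(p[7:9]))
  W <- A + C + E
  marg <- lapply(1:2, function(i) {
    tot <- W[i, i]
    c(a2 = A[i, i] / tot, c2 = C[i, i] / tot, e2 = E[i, i] / tot)
  })
  structure(list(
    rg = component_cor(A), rc = component_cor(C), re = component_cor(E),
    rp = component_cor(W, tol = 1e-12),
    A = A, C = C, E = E,
    chol = list(a = L(p[1:3]), c = L(p[4:6]), e = L(p[7:9])),
    mean = p[10:11],
    marginal = marg,
    loglik = best$value, npar = 11L, aic = -2 * best$value + 22,
    n_pairs = nrow(pairs), degenerate = FALSE
  ), class = "twin_biv_fit")
}

to_univ_pairs <- function(pairs, trait) {
  tibble::tibble(
    pair_id = pairs$pair_id, zygosity = pairs$zygosity,
    y1 = pairs[[paste0("y1_t", trait)]],
    y2 = pairs[[paste0("y2_t", trait)]])
}

#' @export
print.twin_biv_fit <- function(x, ...) {
  cat(sprintf("<twin_biv_fit: %d pairs%s>\n", x$n_pairs,
              if (x$degenerate) ", degenerate (identical traits)" else ""))
  cat(sprintf("  rg = %s  rc = %s  re = %s  rp = %s\n",
              format(round(x$rg, 3)), format(round(x$rc, 3)),
              format(round(x$re, 3)), format(round(x$rp, 3))))
  invisible(x)
}
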