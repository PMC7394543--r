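# Sex-limitation (heterogeneity) and age-moderation (gene-by-environment)
# extensions of the univariate ACE model.

# exchangeable-group log-likelihood from univariate-style sufficient stats
ll_exch_group <- function(v, covz, mu, g) {
  ss <- v + covz
  dd <- v - covz
  if (ss <= 1e-12) return(NA_real_)
  if (dd <= 1e-12) {
    if (g$sum_d2 > 1e-20) return(NA_real_)
    dd_part <- 0
  } else {
    dd_part <- -g$n / 2 * log(2 * pi * dd) - g$sum_d2 / (2 * dd)
  }
  qs <- g$sum_s2 - 2 * sqrt(2) * mu * g$sum_s + 2 * g$n * mu^2
  -g$n / 2 * log(2 * pi * ss) - qs / (2 * ss) + dd_part
}

sexhet_suffstats <- function(pairs) {
  stopifnot(all(c("sex1", "sex2") %in% names(pairs)))
  same <- pairs$sex1 == pairs$sex2
  ss <- pairs[same, ]
  os <- pairs[!same, ]
  groups <- lapply(split(ss, paste(ss$zygosity, ss$sex1, sep = ".")), function(g) {
    s <- (g$y1 + g$y2) / sqrt(2)
    d <- (g$y1 - g$y2) / sqrt(2)
    list(zyg = g$zygosity[1], sex = g$sex1[1], n = nrow(g),
         sum_s = sum(s), sum_s2 = sum(s^2), sum_d2 = sum(d^2))
  })
  os_stat <- NULL
  if (nrow(os)) {
    # orient male first so the cross covariance is always a_m a_f / 2 + c_m c_f
    flip <- os$sex1 == "F"
    ym <- ifelse(flip, os$y2, os$y1)
    yf <- ifelse(flip, os$y1, os$y2)
    x <- cbind(ym, yf)
    os_stat <- list(n = nrow(os), sum_x = colSums(x), ss = crossprod(x))
  }
  list(same = groups, os = os_stat)
}

ll_sexhet <- function(pm, pf, mu_m, mu_f, st) {
  ll <- 0
  for (g in st$same) {
    p <- if (g$sex == "M") pm else pf
    mu <- if (g$sex == "M") mu_m else mu_f
    gamma <- if (g$zyg == "MZ") 1 else 0.5
    v <- sum(p^2)
    covz <- gamma * p[1]^2 + p[2]^2
    li <- ll_exch_group(v, covz, mu, g)
    if (is.na(li)) return(LL_FLOOR)
    ll <- ll + li
  }
  if (!is.null(st$os)) {
    vm <- sum(pm^2); vf <- sum(pf^2)
    cmf <- 0.5 * pm[1] * pf[1] + pm[2] * pf[2]
    M <- matrix(c(vm, cmf, cmf, vf), 2)
    li <- ll_gauss2(M, st$os$n, st$os$ss, st$os$sum_x, c(mu_m, mu_f))
    if (is.na(li)) return(LL_FLOOR)
    ll <- ll + li
  }
  ll
}

#' Fit the sex-heterogeneity twin model
#'
#' The heterogeneity model gives males and females their own ACE path
#' coefficients (and means); opposite-sex DZ pairs are modelled with the
#' cross-products of the male and female paths (within-pair covariance
#' `0.5 a_m a_f + c_m c_f`) and the full likelihood is the sum over MZ, DZ
#' same-sex and DZ opposite-sex groups. Equality of the male and female path
#' coefficients is tested by a likelihood-ratio test against the constrained
#' homogeneity model (3 df; sex-specific means are retained in both models).
#'
#' @param pairs Pair tibble from [make_twin_pairs()] including `sex1`,
#'   `sex2`.
#' @param n_starts Optimizer starts per model.
#' @return Object of class `twin_sexhet_fit`: per-sex standardized
#'   components and h2, both log-likelihoods, `lrt` statistic, `df`,
#'   `p_value`.
#' @export
fit_sex_heterogeneity <- function(pairs, n_starts = 3) {
  st <- sexhet_suffstats(pairs)
  n_by_sex <- table(c(pairs$sex1, pairs$sex2))
  for (s in c("M", "F")) {
    n_pairs_s <- sum(pairs$sex1 == s | pairs$sex2 == s)
    if (n_pairs_s > 0 && n_pairs_s < 5) {
      warn(sprintf("Only %d pairs include sex %s; estimates will be unstable.",
                   n_pairs_s, s))
    }
  }

  base <- fit_twin_ace(pairs, "ACE", ci = FALSE)
  p0 <- base$paths
  mu_by_sex <- c(
    M = mean(c(pairs$y1[pairs$sex1 == "M"], pairs$y2[pairs$sex2 == "M"])),
    F = mean(c(pairs$y1[pairs$sex1 == "F"], pairs$y2[pairs$sex2 == "F"])))
  mu_by_sex[is.na(mu_by_sex)] <- base$mean

  fn_het <- function(p) ll_sexhet(p[1:3], p[4:6], p[7], p[8], st)
  fn_hom <- function(p) ll_sexhet(p[1:3], p[1:3], p[4], p[5], st)
  jit <- list(1, 0.7, 1.3)
  het_starts <- lapply(jit, function(j) c(p0 * j, p0 / j, mu_by_sex["M"], mu_by_sex["F"]))
  hom_starts <- lapply(jit, function(j) c(p0 * j, mu_by_sex["M"], mu_by_sex["F"]))
  het <- ml_optimize(head(het_starts, n_starts), fn_het)
  hom <- ml_optimize(head(hom_starts, n_starts), fn_hom)

  std <- function(p) {
    comp <- p^2 / sum(p^2)
    setNames(comp, c("a2", "c2", "e2"))
  }
  lrt <- max(0, 2 * (het$value - hom$value))
  structure(list(
    male = std(het$par[1:3]), female = std(het$par[4:6]),
    h2_male = std(het$par[1:3])["a2"], h2_female = std(het$par[4:6])["a2"],
    means = c(M = het$par[7], F = het$par[8]),
    loglik_het = het$value, loglik_hom = hom$value,
    lrt = lrt, df = 3L, p_value = pchisq(lrt, 3, lower.tail = FALSE),
    n_pairs = nrow(pairs), n_by_sex = n_by_sex
  ), class = "twin_sexhet_fit")
}

#' @export
print.twin_sexhet_fit <- function(x, ...) {
  cat(sprintf("<twin_sexhet_fit: %d pairs>\n", x$n_pairs))
  cat(sprintf("  h2 male = %.3f, h2 female = %.3f\n", x$h2_male, x$h2_female))
  cat(sprintf("  LRT(path equality) = %.3f on %d df, p = %.4g\n",
              x$lrt, x$df, x$p_value))
  invisible(x)
}

gxe_ll <- function(par, s, d, x, gamma) {
  a <- par[1] + par[2] * x
  cc <- par[3] + par[4] * x
  e <- par[5] + par[6] * x
  mu <- par[7]
  v <- a^2 + cc^2 + e^2
  covz <- gamma * a^2 + cc^2
  ss <- v + covz
  dd <- v - covz
  if (any(ss <= 1e-12) || any(dd <= 1e-12)) return(LL_FLOOR)
  sum(-0.5 * log(2 * pi * ss) - (s - sqrt(2) * mu)^2 / (2 * ss)
      - 0.5 * log(2 * pi * dd) - d^2 / (2 * dd))
}

#' Fit the age-moderation (gene-by-environment) twin model
#'
#' Path coefficients are linear in centred age,
#' `a(x) = a0 + a1 x`, `c(x) = c0 + c1 x`, `e(x) = e0 + e1 x` with
#' `x = age - mean(age)`, so heritability itself becomes a function of age:
#' `h2(x) = a(x)^2 / (a(x)^2 + c(x)^2 + e(x)^2)`. Moderation is tested by a
#' 3-df likelihood-ratio test of `a1 = c1 = e1 = 0` against the plain ACE
#' model, whose likelihood the constrained model reproduces exactly.
#'
#' @param pairs Pair tibble from [make_twin_pairs()] including pair-shared
#'   `age`.
#' @param age_grid Ages at which to report `h2(age)`; defaults to 5 points
#'   spanning the observed range.
#' @param n_starts Optimizer starts.
#' @return Object of class `twin_gxe_fit`: coefficients
#'   `(a0, a1, c0, c1, e0, e1)`, `h2_by_age` tibble, both log-likelihoods,
#'   `lrt`, `df`, `p_value`.
#' @export
fit_gxe_age <- function(pairs, age_grid = NULL, n_starts = 3) {
  stopifnot("age" %in% names(pairs))
  base <- fit_twin_ace(pairs, "ACE", ci = FALSE)
  if (var(pairs$age) < 1e-12) {
    warn("No age variation: returning the unmoderated ACE fit.")
    cf <- c(a0 = base$paths[["a2"]], a1 = 0, c0 = base$paths[["c2"]], c1 = 0,
            e0 = base$paths[["e2"]], e1 = 0)
    return(structure(list(
      coefficients = cf, center = mean(pairs$age),
      h2_by_age = tibble::tibble(age = mean(pairs$age), h2 = base$h2),
      loglik = base$loglik, loglik_ace = base$loglik,
      lrt = 0, df = 3L, p_value = 1, n_pairs = nrow(pairs)
    ), class = "twin_gxe_fit"))
  }
  x <- pairs$age - mean(pairs$age)
  s <- (pairs$y1 + pairs$y2) / sqrt(2)
  d <- (pairs$y1 - pairs$y2) / sqrt(2)
  gamma <- ifelse(pairs$zygosity == "MZ", 1, 0.5)
  fn <- function(p) gxe_ll(p, s, d, x, gamma)
  p0 <- base$paths
  starts <- list(
    c(p0[1], 0, p0[2], 0, p0[3], 0, base$mean),
    c(p0[1], 0.01, p0[2], -0.01, p0[3], 0.01, base$mean),
    c(p0[1] * 1.2, -0.01, p0[2] * 0.8, 0.01, p0[3], -0.01, base$mean))
  best <- ml_optimize(head(starts, n_starts), fn)
  cf <- setNames(best$par[1:6], c("a0", "a1", "c0", "c1", "e0", "e1"))
  age_grid <- age_grid %||%
    seq(min(pairs$age), max(pairs$age), length.out = 5)
  xg <- age_grid - mean(pairs$age)
  h2g <- (cf["a0"] + cf["a1"] * xg)^2 /
    ((cf["a0"] + cf["a1"] * xg)^2 + (cf["c0"] + cf["c1"] * xg)^2 +
       (cf["e0"] + cf["e1"] * xg)^2)
  lrt <- max(0, 2 * (best$value - base$loglik))
  structure(list(
    coefficients = cf, center = mean(pairs$age),
    h2_by_age = tibble::tibble(age = age_grid, h2 = unname(h2g)),
    loglik = best$value, loglik_ace = base$loglik,
    lrt = lrt, df = 3L, p_value = pchisq(lrt, 3, lower.tail = FALSE),
    n_pairs = nrow(pairs)
  ), class = "twin_gxe_fit")
}

#' @export
print.twin_gxe_fit <- function(x, ...) {
  cat(sprintf("<twin_gxe_fit: %d pairs>\n", x$n_pairs))
  cat(sprintf("  moderation LRT = %.3f on %d df, p = %.4g\n",
              x$lrt, x$df, x$p_value))
  print(x$h2_by_age)
  invisible(x)
}
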