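# Univariate ACE-family fits, likelihood contracts, CIs, Falconer agreement.

test_that("pair log-likelihood reduces to iid normal under pure E", {
  set.seed(12)
  pr <- tibble::tibble(
    pair_id = sprintf("P%03d", 1:50), zygosity = rep(c("MZ", "DZ"), 25),
    y1 = rnorm(50), y2 = rnorm(50))
  ll <- pair_loglik(c(0, 0, 1, 0), pr)
  expect_equal(ll, sum(dnorm(c(pr$y1, pr$y2), log = TRUE)), tolerance = 1e-10)
})

test_that("singular implied covariance yields -Inf, not an error", {
  pr <- tibble::tibble(pair_id = c("P1", "P2", "P3", "P4"),
                       zygosity = c("MZ", "MZ", "DZ", "DZ"),
                       y1 = c(0.3, -0.1, 0.5, 0.2),
                       y2 = c(0.4, 0.2, -0.5, 0.1))
  expect_identical(pair_loglik(c(1, 0, 0, 0), pr), -Inf)  # MZ members differ
})

test_that("finite-difference gradient vanishes at the ML optimum", {
  co <- simulate_twin_cohort(twin_sim_config(
    n_mz_pairs = 1000, n_dz_pairs = 1000, n_lipids = 1,
    a2 = 0.4, c2 = 0.1, e2 = 0.5, seed = 55))
  pr <- make_twin_pairs(co$pairs, co$lipids, co$truth$lipid_names[1])
  fit <- fit_twin_ace(pr, ci = FALSE)
  par <- c(unname(fit$paths), fit$mean)
  h <- 1e-5
  grad <- vapply(1:4, function(i) {
    e <- replace(rep(0, 4), i, h)
    (pair_loglik(par + e, pr) - pair_loglik(par - e, pr)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(grad)) / nrow(pr), 0.01)
})

test_that("ACE recovers planted components and agrees with Falconer", {
  pr <- big_pairs()                        # true (0.5, 0.2, 0.3), 5000/group
  fit <- fit_twin_ace(pr, ci = FALSE)
  expect_lt(abs(fit$h2 - 0.5), 0.05)
  cors <- twin_correlations(pr)
  expect_lt(abs(fit$h2 - falconer_h2(cors$r_mz, cors$r_dz)), 0.05)
  # standardized shares sum to one and lie in [0, 1]
  expect_equal(sum(fit$std_components), 1, tolerance = 1e-8)
  expect_true(all(fit$std_components >= 0 & fit$std_components <= 1))
})

test_that("null heritability is recovered as near zero", {
  co <- simulate_twin_cohort(twin_sim_config(
    n_mz_pairs = 5000, n_dz_pairs = 5000, n_lipids = 1,
    a2 = 0, c2 = 0.3, e2 = 0.7, seed = 77))
  pr <- make_twin_pairs(co$pairs, co$lipids, co$truth$lipid_names[1])
  fit <- fit_twin_ace(pr, ci = FALSE)
  expect_lt(fit$h2, 0.05)
  # CE fit on A-free data attains nearly the ACE likelihood
  ce <- fit_twin_ace(pr, "CE", ci = FALSE)
  expect_lt(fit$loglik - ce$loglik, 0.5)
})

test_that("likelihood nesting holds across the model family", {
  for (seed in c(1, 2)) {
    co <- simulate_twin_cohort(twin_sim_config(
      n_mz_pairs = 150, n_dz_pairs = 150, n_lipids = 1,
      a2 = 0.35, c2 = 0.15, e2 = 0.5, seed = seed))
    pr <- make_twin_pairs(co$pairs, co$lipids, co$truth$lipid_names[1])
    ll <- vapply(c("ACE", "AE", "CE", "E"), function(m) {
      fit_twin_ace(pr, m, ci = FALSE)$loglik
    }, numeric(1))
    expect_gte(ll["ACE"] + 1e-6, ll["AE"])
    expect_gte(ll["ACE"] + 1e-6, ll["CE"])
    expect_gte(ll["AE"] + 1e-6, ll["E"])
    expect_gte(ll["CE"] + 1e-6, ll["E"])
  }
})

test_that("h2 likelihood-ratio p-value follows the chi-square reference", {
  mk <- function(ll) structure(list(loglik = ll), class = "twin_ace_fit")
  expect_equal(h2_significance(mk(-100), mk(-100)), 1)
  expect_equal(h2_significance(mk(-100 + 3.84 / 2), mk(-100)),
               pchisq(3.84, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(h2_significance(mk(-100 + 3.84 / 2), mk(-100)), 0.05,
               tolerance = 1e-3)
  expect_equal(h2_significance(mk(-98), mk(-100), reference = "mixture"),
               0.5 * pchisq(4, 1, lower.tail = FALSE))
  expect_error(h2_significance(mk(-101), mk(-100)), "refit")
})

test_that("profile CI contains the estimate and tightens with n", {
  pr <- big_pairs()
  fit <- fit_twin_ace(pr)                  # ci = TRUE
  expect_true(fit$h2_ci[1] <= fit$h2 && fit$h2 <= fit$h2_ci[2])
  expect_lt(fit$h2_ci[2] - fit$h2_ci[1], 0.12)
  expect_true(fit$h2_ci[1] >= 0 && fit$h2_ci[2] <= 1)
})

test_that("Falconer estimator closed form and clipping", {
  expect_equal(falconer_h2(0.7, 0.45), 0.5)
  expect_equal(falconer_h2(0.5, 0.5), 0)
  expect_equal(falconer_h2(0.9, 0.1), 1)   # clipped at 1
  expect_error(falconer_h2(1.2, 0), "\\[-1, 1\\]")
})

test_that("tidy and glance return the documented shapes", {
  co <- small_cohort(seed = 61, n_lipids = 1)
  pr <- make_twin_pairs(co$pairs, co$lipids, co$truth$lipid_names[1])
  fit <- fit_twin_ace(pr, ci = FALSE)
  td <- tidy(fit)
  expect_equal(td$term, c("a2", "c2", "e2"))
  expect_equal(sum(td$std_estimate), 1, tolerance = 1e-8)
  gl <- glance(fit)
  expect_equal(gl$model, "ACE")
  expect_equal(gl$n_pairs, nrow(pr))
})
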