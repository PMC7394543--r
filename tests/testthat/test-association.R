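# Mixed-model association, Bonferroni control, lasso selection,
# pseudo-r2 variance explained.

test_that("Bonferroni threshold arithmetic", {
  expect_equal(signif(bonferroni_threshold(0.05, 35971), 3), 1.39e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("mixed model recovers a near-deterministic probe effect", {
  set.seed(81)
  n <- 200
  meta <- tibble::tibble(sample_id = as.character(1:n),
                         pair_id = rep(sprintf("P%03d", 1:(n / 2)), each = 2))
  y <- as.numeric(scale(rnorm(n)))   # unit SD: the standardized-probe slope is 1
  lip <- tibble::tibble(sample_id = meta$sample_id, lip = y)
  ex <- tibble::tibble(sample_id = meta$sample_id,
                       p1 = y + rnorm(n, sd = 0.1),
                       p2 = -0.5 * y + rnorm(n, sd = 0.2),
                       p3 = rnorm(n))
  res <- mixed_model_association(lip, ex, meta)
  r1 <- res[res$probe == "p1", ]
  expect_lt(abs(r1$beta - 1), 0.05)
  expect_lt(r1$p_value, 1e-20)
  expect_true(r1$significant)
  expect_equal(res$direction[res$probe == "p2"], "inverse")
  expect_false(res$significant[res$probe == "p3"])
  expect_equal(attr(res, "threshold"), 0.05 / 3)
})

test_that("association p-values are uniform under a permutation null", {
  set.seed(82)
  n <- 80
  meta <- tibble::tibble(sample_id = as.character(1:n),
                         pair_id = rep(sprintf("P%03d", 1:(n / 2)), each = 2))
  # pair-structured lipid so the random intercept matters
  u <- rep(rnorm(n / 2, sd = 0.7), each = 2)
  lip <- tibble::tibble(sample_id = meta$sample_id, lip = u + rnorm(n, sd = 0.7))
  x <- rnorm(n)
  pvals <- vapply(1:400, function(i) {
    ex <- tibble::tibble(sample_id = meta$sample_id, p = sample(x))
    mixed_model_association(lip, ex, meta)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  rej <- mean(pvals < 0.05)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("family-wise error under the global null stays near alpha", {
  set.seed(83)
  n <- 60
  m <- 100
  meta_pair <- rep(sprintf("P%03d", 1:(n / 2)), each = 2)
  thr <- bonferroni_threshold(0.05, m)
  hits <- vapply(1:120, function(i) {
    meta <- tibble::tibble(sample_id = as.character(1:n), pair_id = meta_pair)
    lip <- tibble::tibble(sample_id = meta$sample_id, lip = rnorm(n))
    ex <- dplyr::bind_cols(
      tibble::tibble(sample_id = meta$sample_id),
      tibble::as_tibble(matrix(rnorm(n * m), n, m,
                               dimnames = list(NULL, sprintf("p%03d", 1:m)))))
    any(mixed_model_association(lip, ex, meta)$p_value <= thr)
  }, logical(1))
  # binomial(120, 0.05) three-sigma upper bound
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})

test_that("lasso keeps planted probes and discards most noise", {
  set.seed(84)
  n <- 300
  y <- rnorm(n)
  X <- matrix(rnorm(n * 52), n, 52,
              dimnames = list(NULL, sprintf("probe%02d", 1:52)))
  X[, 1] <- 0.8 * y + rnorm(n, sd = 0.5)
  X[, 2] <- -0.6 * y + rnorm(n, sd = 0.5)
  sel <- select_probes_penalized(y, X, seed = 9)
  expect_true(all(c("probe01", "probe02") %in% sel))
  # the sparser 1-SE rule keeps the signal and controls false selections
  sel1se <- select_probes_penalized(y, X, seed = 9, rule = "lambda.1se")
  expect_true(all(c("probe01", "probe02") %in% sel1se))
  expect_lte(length(setdiff(sel1se, c("probe01", "probe02"))), 3)
  # single candidate equal to the lipid is selected
  expect_equal(select_probes_penalized(y, cbind(self = y), seed = 9), "self")
  # duplicated true probe: at least one of the pair survives
  Xd <- cbind(dup1 = X[, 1], dup2 = X[, 1])
  expect_gte(length(intersect(select_probes_penalized(y, Xd, seed = 9),
                              c("dup1", "dup2"))), 1)
})

test_that("pseudo-r2 tracks the analytic variance explained", {
  set.seed(85)
  n <- 1000
  pair <- rep(sprintf("P%04d", 1:(n / 2)), each = 2)
  x <- rnorm(n)
  y <- 0.7 * x + rnorm(n, sd = sqrt(0.51))      # true R2 = 0.49
  ols_r2 <- summary(lm(y ~ x))$r.squared
  ve <- variance_explained(y, cbind(probe = x), pair)
  expect_lt(abs(ve$nagelkerke - ols_r2), 0.05)
  expect_true(ve$mcfadden >= 0 && ve$mcfadden <= 1)
  expect_true(ve$nagelkerke >= 0 && ve$nagelkerke <= 1)
  # empty selection -> both zero
  ve0 <- variance_explained(y, matrix(numeric(0), n, 0), pair)
  expect_equal(c(ve0$mcfadden, ve0$nagelkerke), c(0, 0))
  # adding a pure-noise probe barely moves Nagelkerke
  ve2 <- variance_explained(y, cbind(probe = x, noise = rnorm(n)), pair)
  expect_lt(abs(ve2$nagelkerke - ve$nagelkerke), 0.02)
})

test_that("McFadden and Nagelkerke agree in rank order across effect sizes", {
  set.seed(86)
  n <- 400
  pair <- rep(sprintf("P%04d", 1:(n / 2)), each = 2)
  betas <- seq(0.1, 1.2, length.out = 8)
  r2s <- purrr::map_dfr(betas, function(b) {
    x <- rnorm(n)
    y <- b * x + rnorm(n)
    variance_explained(y, cbind(p = x), pair)
  })
  expect_gt(cor(r2s$mcfadden, r2s$nagelkerke, method = "spearman"), 0.95)
})
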