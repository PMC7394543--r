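# Shorthand parsing, QC rules, group sums, Friedewald, residualization, INT.

test_that("shorthand parser handles all printed dialects", {
  sp <- parse_lipid_name(c("TG(18:0/17:0/18:0)", "Cer(d17:1/24:1)",
                           "LPC(18:1e)", "TG(16_0/14_0/18_1)",
                           "TG18:1_17:1_22:6"))
  expect_equal(sp$lipid_class, c("TG", "Cer", "LPC", "TG", "TG"))
  expect_equal(sp$n_chains, c(3L, 2L, 1L, 3L, 3L))
  expect_equal(sp$total_carbons, c(53L, 41L, 18L, 48L, 57L))
  expect_equal(sp$total_double_bonds, c(0L, 2L, 1L, 1L, 8L))
  expect_equal(sp$chains[[2]]$prefix[1], "d")
  expect_equal(sp$chains[[3]]$prefix, "e")
  # totals are consistent with the per-chain breakdown
  expect_equal(sp$total_carbons,
               vapply(sp$chains, function(ch) sum(ch$carbons), integer(1)))
})

test_that("parser rejects unknown classes and malformed chains by name", {
  expect_error(parse_lipid_name("XX(18:0)"), "Unknown lipid class token 'XX'")
  expect_error(parse_lipid_name("TG(18:0/banana)"), "banana")
  expect_error(parse_lipid_name(""), "non-empty")
})

test_that("parse -> format -> parse round-trips", {
  names_in <- c("TG(18:0/17:0/18:0)", "Cer(d17:1/24:1)", "LPC(18:1e)",
                "PC(16:0/22:6)", "TG18:1_17:1_22:6", "CE(18:2)")
  sp1 <- parse_lipid_name(names_in)
  sp2 <- parse_lipid_name(format_lipid_name(sp1))
  expect_equal(sp1[, setdiff(names(sp1), "raw_name")],
               sp2[, setdiff(names(sp2), "raw_name")])
})

test_that("internal-standard normalization divides by the class IS", {
  pk <- tibble::tibble(lipid = c("PC(16:0/18:1)", "TG(16:0/18:1/18:2)"),
                       lipid_class = c("PC", "TG"), sample = "S1",
                       area = c(2000, 0), is_area = c(1000, 500))
  out <- normalize_by_class_standard(pk)
  expect_equal(out$norm_abundance, c(2.0, 0.0))
  # standards table route and missing-IS error
  st <- tibble::tibble(sample = "S1", lipid_class = "PC", is_area = 1000)
  out2 <- normalize_by_class_standard(pk[1, ], standards = st)
  expect_equal(out2$norm_abundance, 2.0)
  expect_error(normalize_by_class_standard(pk[2, ], standards = st),
               "\\(S1, TG\\)")
})

test_that("coefficient of variation matches closed form and is scale invariant", {
  expect_equal(compute_cv(c(1, 1, 1)), 0)
  expect_equal(compute_cv(c(2, 4)), sqrt(2) / 3, tolerance = 1e-12)
  v <- c(3.2, 4.1, 2.8, 5.0)
  expect_equal(compute_cv(v * 7), compute_cv(v))
  expect_error(compute_cv(c(-1, 1)), "mean 0")
  expect_error(compute_cv(3), "at least 2")
})

test_that("filter_lipids applies every rule and is idempotent", {
  norm <- normalize_by_class_standard(simulate_raw_peak_table())
  filt <- filter_lipids(norm)
  expect_setequal(unique(filt$audit$rule),
                  c("rej", "peak quality", "cv", "batch presence"))
  expect_equal(filt$audit$rule[filt$audit$feature_id == "F07"],
               "batch presence")
  # idempotence
  again <- filter_lipids(filt$kept)
  expect_equal(dplyr::arrange(again$kept, feature_id, batch, sample),
               dplyr::arrange(filt$kept, feature_id, batch, sample))
  expect_equal(nrow(again$audit), 0)
})

test_that("duplicate resolution ranks by CV, then quality, then m-score", {
  mk <- function(id, cv, pq, ms) tibble::tibble(
    feature_id = id, lipid = "TG(16:0/18:1/18:2)",
    sample = c("QC1", "QC2", "QC3"), sample_type = "qc",
    norm_abundance = c(1 - cv, 1, 1 + cv), peak_quality = pq, m_score = ms)
  # CV decides
  r1 <- resolve_duplicates(dplyr::bind_rows(mk("A", .1, .9, 6), mk("B", .2, .95, 7),
                                            mk("C", .3, .99, 8)))
  expect_equal(unique(r1$kept$feature_id), "A")
  # CV tie -> quality decides
  r2 <- resolve_duplicates(dplyr::bind_rows(mk("A", .1, .8, 6), mk("B", .1, .9, 5)))
  expect_equal(unique(r2$kept$feature_id), "B")
  # CV and quality tie -> m-score decides
  r3 <- resolve_duplicates(dplyr::bind_rows(mk("A", .1, .9, 5), mk("B", .1, .9, 6)))
  expect_equal(unique(r3$kept$feature_id), "B")
  # full tie -> first by input order, flagged ambiguous
  r4 <- resolve_duplicates(dplyr::bind_rows(mk("A", .1, .9, 6), mk("B", .1, .9, 6)))
  expect_equal(unique(r4$kept$feature_id), "A")
  expect_equal(r4$ambiguous, "TG(16:0/18:1/18:2)")
  # survivor's per-sample values are untouched
  expect_equal(r1$kept$norm_abundance, mk("A", .1, .9, 6)$norm_abundance)
})

test_that("group sums add within class and saturation subclass", {
  ab <- tibble::tibble(
    sample = "S1",
    lipid = c("Cer(d18:1/16:0)", "Cer(d18:1/24:1)", "TG(16:0/18:1/18:0)"),
    value = c(1.5, 2.5, 3))
  gs <- group_sums(ab)
  expect_equal(gs$value[gs$group == "total Cer"], 4.0)
  # the sphingoid-base double bond counts: d18:1/16:0 is monounsaturated
  expect_equal(gs$value[gs$group == "Cer monounsaturated"], 1.5)
  expect_equal(gs$value[gs$group == "Cer polyunsaturated"], 2.5)
  expect_equal(gs$value[gs$group == "TG monounsaturated"], 3)   # group of one
  expect_false(any(grepl("^total PC", gs$group)))               # absent, not 0
})

test_that("Friedewald equation and negative-result flag", {
  expect_equal(friedewald_ldl(5.2, 1.3, 1.1)$ldl, 3.4)
  expect_equal(friedewald_ldl(0, 0, 0)$ldl, 0)
  expect_equal(friedewald_ldl(4.4, 1.0, 2.2)$ldl, 2.4)
  out <- friedewald_ldl(1, 1, 2.2)
  expect_true(out$flag_negative)
  expect_equal(out$ldl, -1)
  expect_error(friedewald_ldl(-1, 0, 0), "non-negative")
})

test_that("residualization projects out covariates", {
  set.seed(21)
  n <- 200
  cov <- data.frame(age = rnorm(n, 75, 5), sex = sample(c("M", "F"), n, TRUE))
  # exact linear function of covariates -> residuals ~ 0
  y_lin <- 2 + 0.1 * cov$age + 3 * (cov$sex == "M")
  r <- residualize(y_lin, cov)
  expect_lt(max(abs(r$residuals)), 1e-8)
  # confounded response -> residual correlation with covariate ~ 0
  y <- 0.5 * cov$age + rnorm(n)
  r2 <- residualize(y, cov)
  expect_lt(abs(cor(r2$residuals, cov$age)), 1e-8)
  expect_lt(abs(mean(r2$residuals)), 1e-10)
  # collinear design errors with the column named
  cov$age2 <- cov$age
  expect_error(residualize(y, cov), "age2")
})

test_that("inverse normal transform matches normal order statistics", {
  expect_equal(inverse_normal_transform(c(3, 1, 2))[3], 0)  # middle rank of odd n
  x5 <- inverse_normal_transform(c(10, 20, 30, 40, 50))
  expect_equal(x5[1], qnorm((1 - 3 / 8) / (5 - 2 * 3 / 8 + 1)), tolerance = 1e-12)
  expect_equal(x5[1], -1.1798, tolerance = 1e-4)
  set.seed(4)
  x <- rexp(101)
  z <- inverse_normal_transform(x)
  expect_lt(abs(mean(z)), 1e-6)
  expect_equal(order(z), order(x))                # rank order preserved
  expect_error(inverse_normal_transform(rep(1, 5)), "identical")
})

test_that("residualize-then-INT restores normality of skewed traits", {
  set.seed(7)
  n <- 400
  covars <- tibble::tibble(age = rnorm(n, 75, 5), bmi = rnorm(n, 27, 4))
  y <- exp(0.05 * covars$age + rnorm(n))          # strongly right-skewed
  dat <- tibble::tibble(sample_id = as.character(seq_len(n)), lipid = y)
  out <- residualize_matrix(dat, covars)
  z <- out$lipid
  skew <- mean((z - mean(z))^3) / sd(z)^3
  expect_lt(abs(skew), 0.05)
  expect_lt(abs(mean(z)), 1e-6)
})
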