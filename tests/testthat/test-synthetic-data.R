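# Twin cohort, expression, methylation and raw-peak generators.

test_that("config validation catches bad variance fractions and matrices", {
  expect_error(twin_sim_config(a2 = 0.5, c2 = 0.2, e2 = 0.2),
               "offending lipid index")
  expect_error(twin_sim_config(n_lipids = 2, rg_matrix = matrix(c(1, 2, 2, 1), 2)),
               "rg_matrix")
  expect_error(twin_sim_config(sex_params = list(male = c(1, 0, 0),
                                                 female = c(1, 0, 0)),
                               age_moderation = rep(0, 6)),
               "cannot both")
  expect_error(
    twin_sim_config(n_probes = 10,
                    planted_assoc = data.frame(lipid = 1, probe = 11, beta = 1)),
    "out of range")
})

test_that("within-pair covariance matches the MZ/DZ twin identities", {
  cfg <- twin_sim_config(n_mz_pairs = 5000, n_dz_pairs = 5000, n_lipids = 1,
                         a2 = 0.5, c2 = 0.2, e2 = 0.3, seed = 31)
  co <- simulate_twin_cohort(cfg)
  pr <- make_twin_pairs(co$pairs, co$lipids, co$truth$lipid_names[1])
  cors <- twin_correlations(pr)
  mc <- 3 / sqrt(5000)
  expect_lt(abs(cors$r_mz - 0.7), mc)   # a2 + c2
  expect_lt(abs(cors$r_dz - 0.45), mc)  # 0.5 a2 + c2
  # unit total variance when the components sum to 1
  expect_lt(abs(var(c(pr$y1, pr$y2)) - 1), 0.05)
})

test_that("pure-environment traits are uncorrelated within pairs", {
  cfg <- twin_sim_config(n_mz_pairs = 800, n_dz_pairs = 800, n_lipids = 1,
                         a2 = 0, c2 = 0, e2 = 1, seed = 32)
  co <- simulate_twin_cohort(cfg)
  pr <- make_twin_pairs(co$pairs, co$lipids, co$truth$lipid_names[1])
  cors <- twin_correlations(pr)
  expect_lt(abs(cors$r_mz), 3 / sqrt(800))
})

test_that("generation is fully reproducible from the seed", {
  cfg <- twin_sim_config(n_mz_pairs = 10, n_dz_pairs = 10, n_lipids = 3,
                         n_probes = 20, n_cpg = 30, seed = 99)
  a <- simulate_twin_cohort(cfg)
  b <- simulate_twin_cohort(cfg)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$lipids, b$lipids)
  expect_identical(simulate_expression(a, cfg), simulate_expression(b, cfg))
  expect_identical(simulate_methylation(a, cfg), simulate_methylation(b, cfg))
})

test_that("cohort structure is well formed", {
  co <- small_cohort()
  expect_true(all(co$pairs$zygosity %in% c("MZ", "DZ")))
  # MZ pairs are same-sex; ages are pair-shared and within range
  by_pair <- split(co$pairs, co$pairs$pair_id)
  for (g in by_pair) {
    expect_equal(g$age[1], g$age[2])
    if (g$zygosity[1] == "MZ") expect_equal(g$sex[1], g$sex[2])
  }
  expect_true(all(co$pairs$age >= 69 & co$pairs$age <= 93))
  # some opposite-sex DZ pairs exist at the default probability
  dz <- dplyr::filter(co$pairs, zygosity == "DZ")
  os <- tapply(dz$sex, dz$pair_id, function(s) s[1] != s[2])
  expect_gt(sum(os), 0)
})

test_that("planted expression probes carry the configured signal", {
  cfg <- twin_sim_config(
    n_mz_pairs = 100, n_dz_pairs = 100, n_lipids = 2, n_probes = 30,
    expr_noise_sd = 0.1,
    planted_assoc = data.frame(lipid = c(1, 2), probe = c(1, 2),
                               beta = c(1, -0.8)),
    seed = 33)
  co <- simulate_twin_cohort(cfg)
  ex <- simulate_expression(co, cfg)
  l1 <- co$lipids[[co$truth$lipid_names[1]]]
  l2 <- co$lipids[[co$truth$lipid_names[2]]]
  # corr = beta / sqrt(beta^2 + sd^2) = 1/sqrt(1.01) for beta 1, sd 0.1
  expect_gt(cor(l1, ex$probe_0001), 0.9)
  expect_lt(cor(l2, ex$probe_0002), 0)   # sign preservation
  # unplanted probes consistent with the null
  expect_lt(max(abs(cor(l1, as.matrix(ex[, 4:31])))), 5 / sqrt(400))
})

test_that("methylation betas stay in (0,1) and centre at 0.5 for zero latents", {
  expect_equal(plogis(0), 0.5)
  co <- small_cohort(n_lipids = 1, n_cpg = 50)
  cfg <- co$truth$config
  me <- simulate_methylation(co, cfg)
  M <- as.matrix(me[, -1])
  expect_true(all(M > 0 & M < 1))
  expect_true(all(plogis(c(-10, 10)) > 0 & plogis(c(-10, 10)) < 1))
})

test_that("raw peak fixture exercises every QC rule, clean variant passes all", {
  raw <- simulate_raw_peak_table()
  expect_setequal(
    unique(raw$feature_id),
    c("F01", "F02", "F03a", "F03b", "F03c", "F04", "F05", "F06", "F07", "F08"))
  # F07 missing from batch 3
  expect_false(3 %in% raw$batch[raw$feature_id == "F07"])
  clean <- simulate_raw_peak_table(violations = FALSE)
  filt <- filter_lipids(normalize_by_class_standard(clean))
  expect_equal(nrow(filt$audit), 0)
  expect_equal(nrow(filt$kept), nrow(clean))
})
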