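# Stratifications, association bins, set comparisons, cohort table,
# heritability summaries.

test_that("saturation classes follow the double-bond rule", {
  sp <- parse_lipid_name(c("TG(18:0/17:0/18:0)", "TG(16_0/14_0/18_1)",
                           "TG(16_0/22_6/22_6)"))
  cls <- classify_saturation(sp)
  expect_equal(as.character(cls$saturation),
               c("saturated", "monounsaturated", "polyunsaturated"))
  # total function over parsed TGs: every species classified exactly once
  expect_equal(nrow(cls), nrow(sp))
  expect_false(anyNA(cls$saturation))
})

test_that("carbon classes use the 49/56 boundaries", {
  sp <- parse_lipid_name(c("TG(16:0/14:0/18:0)",  # 48 C -> low
                           "TG(16:0/15:0/18:0)",  # 49 C -> medium
                           "TG(18:0/17:0/18:0)",  # 53 C -> medium
                           "TG(18:0/19:0/18:0)",  # 55 C -> medium
                           "TG(18:0/20:0/18:0)")) # 56 C -> high
  cls <- classify_carbons(sp)
  expect_equal(as.character(cls$carbon_class),
               c("low", "medium", "medium", "medium", "high"))
})

test_that("association bins count transcripts by per-stratum lipid hits", {
  assoc <- tibble::tibble(
    lipid = c("L1", "L2", "L1", "L2", "L3", "L4", "L5", "L6", "L7", "L8", "L9"),
    probe = c("X", "X", "Y", "Y", "Y", "Y", rep("Z", 5)),
    significant = TRUE)
  strata <- tibble::tibble(lipid = paste0("L", 1:9), stratum = "saturated")
  # X hits 2 lipids, Y hits 4, Z hits 5
  bins <- count_association_bins(assoc, strata)
  expect_equal(bins$n_transcripts[bins$bin == "1-2"], 1L)
  expect_equal(bins$n_transcripts[bins$bin == "3-8"], 2L)
  expect_equal(bins$n_transcripts[bins$bin == ">8"], 0L)
  # bin counts sum to distinct transcripts per stratum
  expect_equal(sum(bins$n_transcripts), 3L)
  # >8 bin
  big <- tibble::tibble(lipid = paste0("L", 1:9), probe = "W", significant = TRUE)
  bins2 <- count_association_bins(big, strata)
  expect_equal(bins2$n_transcripts[bins2$bin == ">8"], 1L)
  # no associations -> all zero
  bins0 <- count_association_bins(dplyr::mutate(assoc, significant = FALSE),
                                  strata)
  expect_true(all(bins0$n_transcripts == 0L))
})

test_that("heritable vs non-heritable transcript partition is exact", {
  assoc <- tibble::tibble(
    lipid = c("H1", "H1", "N1", "N1", "H2", "N2"),
    probe = c("A", "B", "B", "C", "D", "D"),
    significant = TRUE,
    direction = c("positive", "inverse", "inverse", "inverse", "positive",
                  "positive"))
  calls <- tibble::tibble(lipid = c("H1", "H2", "N1", "N2"),
                          heritable = c(TRUE, TRUE, FALSE, FALSE))
  out <- heritable_vs_nonheritable_sets(assoc, calls)
  expect_setequal(out$sets$unique_heritable, "A")
  expect_setequal(out$sets$unique_nonheritable, "C")
  expect_setequal(out$sets$shared, c("B", "D"))
  # partition is disjoint and covers the union
  all_probes <- unique(assoc$probe)
  expect_setequal(unlist(out$sets), all_probes)
  expect_equal(sum(lengths(out$sets)), length(all_probes))
  # disjoint planted sets -> empty intersection
  out2 <- heritable_vs_nonheritable_sets(assoc[c(1, 4), ], calls)
  expect_length(out2$sets$shared, 0)
})

test_that("cohort table reproduces the printed group comparisons", {
  tt <- welch_t_summary(75.7, 5.47, 150, 76.07, 5.31, 110)
  expect_equal(tt$statistic, -0.548, tolerance = 1e-3)
  cs <- chisq_nocorrect(matrix(c(100, 50, 79, 31), 2, byrow = TRUE))
  expect_equal(cs$statistic, 0.785, tolerance = 1e-3)
  expect_equal(cs$df, 1)
  # equal groups -> t = 0
  expect_equal(welch_t_summary(5, 1, 50, 5, 1, 50)$statistic, 0)
  # end to end on a synthetic cohort
  co <- small_cohort(seed = 64)
  ctab <- cohort_table(co$pairs)
  expect_true(all(c("age", "sex") %in% ctab$variable))
  expect_true(all(ctab$p_value >= 0 & ctab$p_value <= 1))
  r_age <- ctab[ctab$variable == "age", ]
  mz <- co$pairs$age[co$pairs$zygosity == "MZ"]
  dz <- co$pairs$age[co$pairs$zygosity == "DZ"]
  expect_equal(r_age$statistic, unname(t.test(mz, dz)$statistic),
               tolerance = 1e-8)
})

test_that("heritability summary reports counts, percentages and medians", {
  fits <- tibble::tibble(
    lipid = sprintf("TG(15:0/%d:1/18:1)", 14 + 1:203),
    h2 = c(seq(0.3, 0.6, length.out = 27), rep(0.1, 176)),
    p_h2 = c(rep(0.01, 27), rep(0.5, 176)))
  hs <- heritability_summary(fits)
  expect_equal(hs$overall$n_significant, 27L)
  expect_equal(hs$overall$pct_significant, 13.3)
  expect_equal(hs$overall$median_h2_significant, median(fits$h2[1:27]))
  # all significant -> 100 %; none -> 0 % with absent median
  hs1 <- heritability_summary(dplyr::mutate(fits, p_h2 = 0.01))
  expect_equal(hs1$overall$pct_significant, 100)
  hs0 <- heritability_summary(dplyr::mutate(fits, p_h2 = 0.5))
  expect_equal(hs0$overall$pct_significant, 0)
  expect_true(is.na(hs0$overall$median_h2_significant))
})

test_that("plot constructors return ggplot objects", {
  fits <- tibble::tibble(lipid = c("TG(16:0/18:1/18:2)", "Cer(d18:1/24:1)"),
                         h2 = c(0.4, 0.5), p_h2 = c(0.01, 0.2))
  expect_s3_class(plot_heritability_by_class(fits), "ggplot")
  ve <- tibble::tibble(lipid = fits$lipid, nagelkerke = c(0.2, 0.1))
  expect_s3_class(plot_h2_vs_varexp(fits, ve), "ggplot")
})
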