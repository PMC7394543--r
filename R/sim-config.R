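#' Configuration for the synthetic twin-lipidome generator
#'
#' Bundles every parameter of the synthetic data generator: cohort size and
#' zygosity split, per-lipid true variance components, optional genetic /
#' shared- / unique-environment correlation structure between lipids, optional
#' sex-specific path coefficients, optional age moderation of the paths, and
#' the sizes of the companion expression and methylation matrices. One seed
#' determines every downstream draw, so identical configurations reproduce
#' byte-identical tables.
#'
#' The per-lipid components `a2`, `c2`, `e2` are variance *fractions* of a
#' unit-variance trait: additive genetic, shared (common) environment and
#' unique environment. They must sum to 1 for every lipid. Monozygotic (MZ)
#' co-twins then have within-pair trait covariance `a2 + c2` and dizygotic
#' (DZ) co-twins `0.5 * a2 + c2`, the classical twin-design identities.
#'
#' @param n_mz_pairs,n_dz_pairs Number of MZ and DZ twin pairs (defaults 75
#'   and 55, the cohort sizes the generator emulates).
#' @param n_lipids Number of lipid species to simulate.
#' @param a2,c2,e2 Numeric vectors (recycled to `n_lipids`) of true variance
#'   fractions; `a2 + c2 + e2` must equal 1 per lipid (tolerance 1e-12).
#' @param rg_matrix,rc_matrix,re_matrix Optional `n_lipids` x `n_lipids`
#'   correlation matrices for the latent genetic, shared-environment and
#'   unique-environment factors (symmetric, unit diagonal, positive
#'   semidefinite). Default identity.
#' @param sex_params Optional list with elements `male` and `female`, each a
#'   numeric vector of path coefficients `c(a, c, e)` applied to all lipids;
#'   enables sex-limitation scenarios. Cannot be combined with
#'   `age_moderation`.
#' @param age_moderation Optional numeric vector
#'   `c(a0, a1, c0, c1, e0, e1)`: paths become linear in centred age,
#'   `a(x) = a0 + a1 * x` etc. Applied to all lipids; cannot be combined with
#'   `sex_params`.
#' @param age_range Length-2 numeric; pair ages drawn uniformly in this range
#'   (default 69-93 years, matching an older-adult twin cohort).
#' @param prob_female Probability that a same-sex pair is female.
#' @param prob_opposite_sex Probability that a DZ pair is opposite-sex.
#' @param n_probes Number of expression probes (default 500).
#' @param expr_noise_sd Residual SD of unplanted probe signal.
#' @param planted_assoc Optional data frame with columns `lipid`, `probe`
#'   (integer indices) and `beta`: probes carrying a planted lipid signal.
#' @param n_cpg Number of CpG methylation probes (default 1000).
#' @param gwam_beta Planted effect linking genome-wide average methylation to
#'   `gwam_lipid`; sign sets the association direction, 0 disables it.
#' @param gwam_lipid Index of the lipid carrying the planted GWAM effect.
#' @param gwam_probe_frac Fraction of CpG probes whose latents receive the
#'   planted shift.
#' @param seed Integer master seed.
#'
#' @return An object of class `twin_sim_config` (a validated list).
#' @examples
#' cfg <- twin_sim_config(n_mz_pairs = 20, n_dz_pairs = 20, n_lipids = 3,
#'                        a2 = 0.5, c2 = 0.2, e2 = 0.3, seed = 1)
#' cfg$n_lipids
#' @export
twin_sim_config <- function(n_mz_pairs = 75,
                            n_dz_pairs = 55,
                            n_lipids = 60,
                            a2 = 0.3,
                            c2 = 0.1,
                            e2 = 0.6,
                            rg_matrix = NULL,
                            rc_matrix = NULL,
                            re_matrix = NULL,
                            sex_params = NULL,
                            age_moderation = NULL,
                            age_range = c(69, 93),
                            prob_female = 0.6,
                            prob_opposite_sex = 0.5,
                            n_probes = 500,
                            expr_noise_sd = 1,
                            planted_assoc = NULL,
                            n_cpg = 1000,
                            gwam_beta = 0,
                            gwam_lipid = 1L,
                            gwam_probe_frac = 0.2,
                            seed = 1L) {
  n_mz_pairs <- stopifnot_scalar_count(n_mz_pairs, "n_mz_pairs")
  n_dz_pairs <- stopifnot_scalar_count(n_dz_pairs, "n_dz_pairs")
  n_lipids   <- stopifnot_scalar_count(n_lipids, "n_lipids", min = 1L)
  n_probes   <- stopifnot_scalar_count(n_probes, "n_probes")
  n_cpg      <- stopifnot_scalar_count(n_cpg, "n_cpg")

  a2 <- rep_len(as.numeric(a2), n_lipids)
  c2 <- rep_len(as.numeric(c2), n_lipids)
  e2 <- rep_len(as.numeric(e2), n_lipids)
  bad <- which(abs(a2 + c2 + e2 - 1) > 1e-12 | a2 < 0 | c2 < 0 | e2 < 0)
  if (length(bad)) {
    abort(sprintf(
      "Variance fractions must be non-negative and sum to 1; offending lipid index: %s.",
      paste(bad, collapse = ", ")))
  }

  for (nm in c("rg_matrix", "rc_matrix", "re_matrix")) {
    m <- get(nm)
    if (!is.null(m)) {
      if (!is_correlation_matrix(m) || nrow(m) != n_lipids) {
        abort(sprintf(
          "`%s` must be a symmetric unit-diagonal positive-semidefinite %d x %d matrix.",
          nm, n_lipids, n_lipids))
      }
    }
  }

  if (!is.null(sex_params) && !is.null(age_moderation)) {
    abort("`sex_params` and `age_moderation` cannot both be set.")
  }
  if (!is.null(sex_params)) {
    if (!is.list(sex_params) || !all(c("male", "female") %in% names(sex_params)) ||
        length(sex_params$male) != 3L || length(sex_params$female) != 3L) {
      abort("`sex_params` must be list(male = c(a, c, e), female = c(a, c, e)).")
    }
  }
  if (!is.null(age_moderation) && length(age_moderation) != 6L) {
    abort("`age_moderation` must be c(a0, a1, c0, c1, e0, e1).")
  }

  if (!is.null(planted_assoc)) {
    planted_assoc <- tibble::as_tibble(planted_assoc)
    if (!all(c("lipid", "probe", "beta") %in% names(planted_assoc))) {
      abort("`planted_assoc` needs columns lipid, probe, beta.")
    }
    if (any(planted_assoc$lipid < 1 | planted_assoc$lipid > n_lipids)) {
      abort("`planted_assoc$lipid` index out of range.")
    }
    if (any(planted_assoc$probe < 1 | planted_assoc$probe > n_probes)) {
      abort("`planted_assoc$probe` index out of range.")
    }
  }
  if (gwam_lipid < 1 || gwam_lipid > n_lipids) abort("`gwam_lipid` index out of range.")

  structure(
    list(
      n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs, n_lipids = n_lipids,
      a2 = a2, c2 = c2, e2 = e2,
      rg_matrix = rg_matrix, rc_matrix = rc_matrix, re_matrix = re_matrix,
      sex_params = sex_params, age_moderation = age_moderation,
      age_range = as.numeric(age_range),
      prob_female = prob_female, prob_opposite_sex = prob_opposite_sex,
      n_probes = n_probes, expr_noise_sd = expr_noise_sd,
      planted_assoc = planted_assoc,
      n_cpg = n_cpg, gwam_beta = gwam_beta, gwam_lipid = as.integer(gwam_lipid),
      gwam_probe_frac = gwam_probe_frac,
      seed = as.integer(seed)
    ),
    class = "twin_sim_config"
  )
}

#' @export
print.twin_sim_config <- function(x, ...) {
  cat("<twin_sim_config>\n")
  cat(sprintf("  pairs: %d MZ + %d DZ; lipids: %d; probes: %d; CpGs: %d\n",
              x$n_mz_pairs, x$n_dz_pairs, x$n_lipids, x$n_probes, x$n_cpg))
  cat(sprintf("  mean components: a2=%.2f c2=%.2f e2=%.2f; seed=%d\n",
              mean(x$a2), mean(x$c2), mean(x$e2), x$seed))
  invisible(x)
}
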