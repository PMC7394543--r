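# Twin cohort simulation under the classical ACE generative model.

# Deterministic pool of parseable shorthand lipid names, spread over the nine
# supported classes so group-sum and stratification code paths are exercised.
synthetic_lipid_names <- function(n) {
  carbons <- function(k, lo, hi) seq(lo, hi, by = 2)[((seq_len(k) - 1) %% length(seq(lo, hi, by = 2))) + 1]
  pool <- character(0)
  # triglycerides dominate real panels; give them the largest share
  tg_ch <- expand.grid(c1 = c(16, 18), c2 = c(14, 17, 18, 22), d2 = 0:2,
                       c3 = c(18, 20, 22), d3 = 0:3)
  pool <- c(pool, sprintf("TG(%d:0/%d:%d/%d:%d)",
                          tg_ch$c1, tg_ch$c2, tg_ch$d2, tg_ch$c3, tg_ch$d3))
  pool <- c(pool,
            sprintf("Cer(d18:1/%d:%d)", c(16, 18, 20, 22, 24, 24), c(0, 0, 0, 0, 0, 1)),
            sprintf("PC(16:0/%d:%d)", c(18, 18, 20, 22), c(1, 2, 4, 6)),
            sprintf("PE(16:0/%d:%d)", c(18, 20, 22), c(2, 4, 6)),
            sprintf("PI(18:0/%d:%d)", c(18, 20), c(1, 4)),
            sprintf("SM(d18:1/%d:%d)", c(16, 24, 24), c(0, 0, 1)),
            sprintf("LPC(%d:%d)", c(16, 18, 18, 20), c(0, 0, 1, 4)),
            sprintf("LPC(18:1e)"),
            sprintf("DG(18:1/%d:%d)", c(18, 18, 16), c(1, 2, 0)),
            sprintf("CE(%d:%d)", c(16, 18, 18, 20), c(0, 1, 2, 4)))
  pool <- unique(pool)
  if (n > length(pool)) {
    pool <- c(pool, sprintf("TG(15:0/%d:1/18:%d)",
                            14 + seq_len(n), seq_len(n) %% 4))
  }
  pool[seq_len(n)]
}

# Draw one latent factor matrix (n draws x n_lipids) with the requested
# between-lipid correlation (identity when NULL).
draw_latent <- function(n, corr, n_lipids) {
  z <- matrix(rnorm(n * n_lipids), n, n_lipids)
  if (is.null(corr)) return(z)
  z %*% t(safe_chol_factor(corr))
}

#' Simulate a twin cohort with lipid traits of known heritability
#'
#' Generates monozygotic and dizygotic twin pairs whose lipid traits follow
#' the classical additive-genetic / shared-environment / unique-environment
#' decomposition: each unit-variance trait is
#' `y = a*A + c*C + e*E` with `A` fully shared within MZ pairs and correlated
#' 0.5 within DZ pairs, `C` shared within every pair and `E` individual.
#' The implied within-pair covariances are therefore `a2 + c2` (MZ) and
#' `0.5*a2 + c2` (DZ). Ages are pair-shared and uniform over
#' `config$age_range`; DZ pairs may be opposite-sex. Optional sex-specific
#' paths or age-moderated paths replace the constant paths.
#'
#' @param config A [twin_sim_config()].
#' @return A list with elements
#'   * `pairs`: tibble, one row per individual (`sample_id`, `pair_id`,
#'     `zygosity`, `member`, `sex`, `age` and covariates `education`, `bmi`,
#'     `smoking`, `lipid_med`, `apoe_e4`, `batch`);
#'   * `lipids`: tibble of `sample_id` plus one column per lipid species;
#'   * `truth`: list carrying the generating components, the latent genetic /
#'     shared / unique draws and the config, sufficient to compute oracle
#'     recoveries.
#' @examples
#' cohort <- simulate_twin_cohort(
#'   twin_sim_config(n_mz_pairs = 30, n_dz_pairs = 30, n_lipids = 2, seed = 7))
#' head(cohort$pairs)
#' @export
simulate_twin_cohort <- function(config) {
  stopifnot(inherits(config, "twin_sim_config"))
  if (config$n_mz_pairs < 2 || config$n_dz_pairs < 2) {
    abort("Need at least 2 MZ and 2 DZ pairs.")
  }
  with_seed(child_seed(config$seed, 1), simulate_twin_cohort_impl(config))
}

simulate_twin_cohort_impl <- function(config) {
  n_mz <- config$n_mz_pairs; n_dz <- config$n_dz_pairs
  n_pairs <- n_mz + n_dz
  nl <- config$n_lipids
  lipid_names <- synthetic_lipid_names(nl)

  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  pair_id <- sprintf("P%04d", seq_len(n_pairs))
  age <- runif(n_pairs, config$age_range[1], config$age_range[2])

  opposite <- zyg == "DZ" & runif(n_pairs) < config$prob_opposite_sex
  same_sex_female <- runif(n_pairs) < config$prob_female
  sex1 <- ifelse(opposite, "M", ifelse(same_sex_female, "F", "M"))
  sex2 <- ifelse(opposite, "F", sex1)

  # latent factors
  g_pair <- draw_latent(n_pairs, config$rg_matrix, nl)
  g_ind1 <- draw_latent(n_pairs, config$rg_matrix, nl)
  g_ind2 <- draw_latent(n_pairs, config$rg_matrix, nl)
  c_pair <- draw_latent(n_pairs, config$rc_matrix, nl)
  e_ind1 <- draw_latent(n_pairs, config$re_matrix, nl)
  e_ind2 <- draw_latent(n_pairs, config$re_matrix, nl)

  dz <- zyg == "DZ"
  A1 <- g_pair; A2 <- g_pair
  A1[dz, ] <- sqrt(0.5) * g_pair[dz, , drop = FALSE] + sqrt(0.5) * g_ind1[dz, , drop = FALSE]
  A2[dz, ] <- sqrt(0.5) * g_pair[dz, , drop = FALSE] + sqrt(0.5) * g_ind2[dz, , drop = FALSE]

  paths_for <- function(sex, agex) {
    # returns list of n_pairs x nl matrices a, c, e
    if (!is.null(config$sex_params)) {
      sm <- config$sex_params$male; sf <- config$sex_params$female
      male <- sex == "M"
      list(a = matrix(ifelse(male, sm[1], sf[1]), n_pairs, nl),
           c = matrix(ifelse(male, sm[2], sf[2]), n_pairs, nl),
           e = matrix(ifelse(male, sm[3], sf[3]), n_pairs, nl))
    } else if (!is.null(config$age_moderation)) {
      m <- config$age_moderation
      x <- agex - mean(config$age_range)
      list(a = matrix(m[1] + m[2] * x, n_pairs, nl),
           c = matrix(m[3] + m[4] * x, n_pairs, nl),
           e = matrix(m[5] + m[6] * x, n_pairs, nl))
    } else {
      list(a = matrix(sqrt(config$a2), n_pairs, nl, byrow = TRUE),
           c = matrix(sqrt(config$c2), n_pairs, nl, byrow = TRUE),
           e = matrix(sqrt(config$e2), n_pairs, nl, byrow = TRUE))
    }
  }
  p1 <- paths_for(sex1, age); p2 <- paths_for(sex2, age)
  y1 <- p1$a * A1 + p1$c * c_pair + p1$e * e_ind1
  y2 <- p2$a * A2 + p2$c * c_pair + p2$e * e_ind2

  id1 <- paste0(pair_id, "_1"); id2 <- paste0(pair_id, "_2")
  n_ind <- 2L * n_pairs
  pairs <- tibble::tibble(
    sample_id = c(rbind(id1, id2)),
    pair_id   = rep(pair_id, each = 2L),
    zygosity  = rep(zyg, each = 2L),
    member    = rep(c(1L, 2L), n_pairs),
    sex       = c(rbind(sex1, sex2)),
    age       = rep(age, each = 2L),
    education = pmax(6, round(rnorm(n_ind, 11, 3.2))),
    bmi       = round(rnorm(n_ind, 27.7, 4.8), 1),
    smoking   = sample(c("never", "former", "current"), n_ind, TRUE,
                       prob = c(0.5, 0.35, 0.15)),
    lipid_med = rbinom(n_ind, 1, 0.3),
    apoe_e4   = rbinom(n_ind, 1, 0.27),
    batch     = sample(1:2, n_ind, TRUE)
  )

  lip <- matrix(NA_real_, n_ind, nl)
  lip[seq(1, n_ind, 2), ] <- y1
  lip[seq(2, n_ind, 2), ] <- y2
  colnames(lip) <- lipid_names
  lipids <- dplyr::bind_cols(tibble::tibble(sample_id = pairs$sample_id),
                             tibble::as_tibble(lip))

  genetic <- matrix(NA_real_, n_ind, nl)
  genetic[seq(1, n_ind, 2), ] <- A1
  genetic[seq(2, n_ind, 2), ] <- A2
  colnames(genetic) <- lipid_names

  truth <- list(
    lipid_names = lipid_names,
    a2 = setNames(config$a2, lipid_names),
    c2 = setNames(config$c2, lipid_names),
    e2 = setNames(config$e2, lipid_names),
    rg_matrix = config$rg_matrix, rc_matrix = config$rc_matrix,
    re_matrix = config$re_matrix,
    sex_params = config$sex_params, age_moderation = config$age_moderation,
    genetic_values = genetic,
    shared_env = c_pair,
    config = config
  )
  list(pairs = pairs, lipids = lipids, truth = truth)
}

#' Simulate gene-expression probes with planted lipid associations
#'
#' Probe values are independent Gaussian noise except for configured
#' (lipid, probe, beta) triples, where the probe equals
#' `beta * standardized lipid + N(0, expr_noise_sd^2)`. The planted-probe
#' correlation with the lipid is therefore `beta / sqrt(beta^2 + sd^2)`.
#'
#' @param cohort Output of [simulate_twin_cohort()].
#' @param config The same [twin_sim_config()].
#' @return Tibble: `sample_id` plus one column per probe
#'   (`probe_0001`, ...).
#' @export
simulate_expression <- function(cohort, config) {
  stopifnot(inherits(config, "twin_sim_config"))
  with_seed(child_seed(config$seed, 2), {
    n <- nrow(cohort$pairs)
    np <- config$n_probes
    expr <- matrix(rnorm(n * np, sd = config$expr_noise_sd), n, np)
    colnames(expr) <- sprintf("probe_%04d", seq_len(np))
    pa <- config$planted_assoc
    if (!is.null(pa) && nrow(pa)) {
      lip_mat <- as.matrix(cohort$lipids[, -1])
      if (max(pa$lipid) > ncol(lip_mat)) abort("Planted lipid index out of range.")
      for (i in seq_len(nrow(pa))) {
        x <- as.numeric(scale(lip_mat[, pa$lipid[i]]))
        expr[, pa$probe[i]] <- pa$beta[i] * x + rnorm(n, sd = config$expr_noise_sd)
      }
    }
    dplyr::bind_cols(tibble::tibble(sample_id = cohort$pairs$sample_id),
                     tibble::as_tibble(expr))
  })
}

#' Simulate CpG methylation beta values with an optional planted GWAM effect
#'
#' Each CpG gets a probe-level baseline latent plus per-sample Gaussian noise,
#' mapped to (0, 1) through the inverse logit, emulating array beta values.
#' When `gwam_beta` is non-zero, each sample additionally carries a global
#' methylation shift (applied to a fraction `gwam_probe_frac` of probes) whose
#' correlation with the standardized target lipid equals `gwam_beta`, so the
#' regression slope of the lipid on standardized genome-wide average
#' methylation is approximately `gwam_beta`, with the configured sign.
#'
#' @inheritParams simulate_expression
#' @return Tibble: `sample_id` plus one column per CpG (`cpg_00001`, ...),
#'   all values strictly inside (0, 1).
#' @export
simulate_methylation <- function(cohort, config) {
  stopifnot(inherits(config, "twin_sim_config"))
  with_seed(child_seed(config$seed, 3), {
    n <- nrow(cohort$pairs)
    np <- config$n_cpg
    base <- rnorm(np, 0, 1)                      # probe-level methylation setpoints
    latent <- matrix(base, n, np, byrow = TRUE) + matrix(rnorm(n * np, sd = 0.5), n, np)
    if (config$gwam_beta != 0) {
      n_aff <- max(1L, round(config$gwam_probe_frac * np))
      lip <- as.numeric(scale(as.matrix(cohort$lipids[, -1])[, config$gwam_lipid]))
      b <- max(min(config$gwam_beta, 1), -1)
      # unit-variance per-sample global shift correlated b with the lipid
      global <- b * lip + sqrt(1 - b^2) * rnorm(n)
      latent[, seq_len(n_aff)] <- latent[, seq_len(n_aff)] + 0.4 * global
    }
    beta <- plogis(latent)
    colnames(beta) <- sprintf("cpg_%05d", seq_len(np))
    dplyr::bind_cols(tibble::tibble(sample_id = cohort$pairs$sample_id),
                     tibble::as_tibble(beta))
  })
}
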