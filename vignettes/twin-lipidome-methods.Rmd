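---
title: "Methods: twin variance-component models for the plasma lipidome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin variance-component models for the plasma lipidome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinlipids)
```

This vignette is the package's own account of its statistical machinery:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was genuinely
open.

## The twin variance-component model

The classical twin design decomposes a trait's variance into additive
genetic (A), shared/common environment (C) and unique environment (E)
components. With path coefficients $a, c, e$, each individual's trait is
$y = a A + c C + e E$ with unit-variance latent factors, giving total
variance $a^2 + c^2 + e^2$ and within-pair covariance $a^2 + c^2$ for
monozygotic (MZ) pairs and $\tfrac12 a^2 + c^2$ for dizygotic (DZ) pairs —
the identities that follow from MZ co-twins sharing all, and DZ co-twins
half, of the segregating genetic variation. Narrow-sense heritability is
the standardized additive share $h^2 = a^2/(a^2+c^2+e^2)$.

Key assumptions inherited from the design: equal environments across
zygosity groups, no dominance or epistasis (no ADE variant is offered),
random mating, and a single grand mean per trait shared by both members and
both zygosity groups (means equality across zygosity is assumed, not
tested).

**Likelihood.** Each pair contributes a bivariate normal log-density. The
package works on per-group sufficient statistics after the sum/difference
transform $s = (y_1+y_2)/\sqrt2$, $d = (y_1-y_2)/\sqrt2$, which
diagonalizes the exchangeable within-pair covariance
($\mathrm{Var}\,s = v + \mathrm{cov}$, $\mathrm{Var}\,d = v - \mathrm{cov}$,
independent). Every likelihood evaluation is then O(1) in the number of
pairs, which is what makes the replicate-heavy calibration studies in the
test suite affordable. Models are parameterized by the paths themselves
(squared inside the likelihood), so variance components are non-negative by
construction without box constraints. Degenerate parameter points (singular
implied covariance) return `-Inf` rather than raising, so optimizers can
traverse them.

**Optimization.** Multi-start Nelder–Mead (default 5 moment-based,
jittered starts seeded from the empirical MZ/DZ correlations via Falconer's
formula) followed by a BFGS polish, objective tolerance 1e-10. Failure of
every start raises an error rather than returning a doubtful fit.

**Submodels and the heritability test.** AE, CE and E are fitted by fixing
the dropped paths at zero; nesting ($\ell_{ACE} \ge \ell_{AE} \ge \ell_E$,
likewise through CE) is exercised by tests. Significance of the additive
component is the likelihood-ratio statistic $2(\ell_{ACE}-\ell_{CE})$
referred, by default, to $\chi^2_1$; a 50:50 $\chi^2_0/\chi^2_1$ boundary
mixture is available (`h2_test = "mixture"`) and is the reference the null
calibration study uses, since the component is tested on the boundary of
its parameter space. All four fits are reported per lipid and the AIC-best
is flagged; no automatic sub-model selection is imposed because the
selection rule in comparable published analyses is typically unstated.

**Confidence intervals.** Profile likelihood on $h^2$: for fixed $h^2 = t$
the likelihood is re-maximized over total variance, the shared-environment
share and the mean (a 3-parameter inner optimization), and the bounds solve
$2(\hat\ell - \ell_p(t)) = \chi^2_1(0.95)$, clipped to $[0, 1]$. A
delta-method interval was considered and rejected: near the boundary it is
both poorly calibrated and can leave $[0,1]$. Coverage is verified by a
500-replicate study in the acceptance tests (92–98% band at 500
pairs/group).

## Bivariate Cholesky model

For two traits, A, C and E each get a $2\times2$ covariance matrix
parameterized by a lower-triangular Cholesky factor, which keeps the
implied $4\times4$ pair covariance positive semidefinite by construction.
The genetic correlation is $r_g = A_{12}/\sqrt{A_{11}A_{22}}$, likewise
$r_c$, $r_e$; $r_p$ comes from the implied total covariance. When a
component variance is numerically zero (below 1e-6) its correlation is
undefined and reported as `NA`, never as 0. Exactly duplicated traits make
the model singular; that case is detected and returns the univariate
marginal fit with unit correlations instead of letting the optimizer chase
an unbounded likelihood.

## Sex heterogeneity and age moderation

The sex-limitation model gives each sex its own paths and mean; the
opposite-sex DZ within-pair covariance is the cross-product
$\tfrac12 a_m a_f + c_m c_f$, and the total likelihood sums over MZ
same-sex, DZ same-sex and DZ opposite-sex groups (a dataset with no
opposite-sex pairs simply drops that term). Path equality is tested by a
3-df likelihood-ratio test against the homogeneity model; sex-specific
means are retained in both models so the test isolates the paths. No
scalar/non-scalar sex-limitation variants (e.g. a free DZ-opposite-sex
genetic correlation below 0.5) are offered.

The age-moderation (gene-by-environment) model makes each path linear in
age centred at the sample mean — $a(x) = a_0 + a_1 x$ and likewise for $c$
and $e$ — so $h^2$ itself becomes a function of age. Centring is a
numerical choice (the published analyses this mirrors do not state one);
it decorrelates intercepts and slopes. With all three slopes at zero the
likelihood equals the plain ACE likelihood exactly, giving a clean 3-df
LRT. Because the implied covariance varies by pair, this likelihood is
O(n), vectorized.

## Lipidomics preprocessing

Shorthand names are parsed into class, chains, total carbons and total
double bonds. Both `carbons:bonds` and `carbons_bonds` dialects, both `/`
and `_` chain separators, bare class-prefixed forms, and the prefixes `d`
(sphingoid base), `e` (ether), `p` (plasmalogen) are accepted, because
exported peak tables mix these dialects freely. Note the sphingoid-base
double bond counts toward the total, so `Cer(d18:1/16:0)` is
monounsaturated.

QC follows the standard post-alignment rules: keep a feature only if
`rej = 0`, average peak quality > 0.75, quality-control-injection CV < 0.4,
and presence in every alignment batch (the batch count is a parameter, not
hard-coded at four). The CV rule uses QC-injection CV — within-cohort CV is
computable but not the filter — because repeated QC injections, not
biological spread, measure assay repeatability. Duplicate identifications
(same annotation) are resolved by lowest QC CV, then highest average peak
quality, then highest average m-score; residual exact ties fall back to
input order and are logged as ambiguous. Every exclusion is written to an
audit log naming the rule. Filtering is idempotent and duplicate resolution
never alters a surviving feature's per-sample values.

Traits are residualized against covariates by OLS and then rank-based
inverse-normal transformed, in that order: $\Phi^{-1}((r - c)/(n - 2c + 1))$
with Blom's offset $c = 3/8$ (configurable; the offset choice is
conventional, the tool this mirrors does not document one) and average
ranks for ties. Negative Friedewald LDL-C values are returned but flagged
rather than nulled, leaving the exclusion decision to the analyst.

## Omics association

Lipid–probe association uses the linear mixed model
`lipid ~ probe + (1 | pair)` fitted by ML (not REML) via lme4, so
likelihood-based pseudo-r² comparisons across nested fits are well-defined.
The twin pair is the random-effect grouping — it is the only clustering in
the design. Probe values are standardized to unit variance first, making
effects comparable across probes. The Wald t uses containment-style
residual df, $n - 2 - (G - 1)$ for $G$ pairs; its type-I error is verified
by simulation. A singular (zero) pair variance degenerates to OLS and is
flagged. Significance is Bonferroni at $\alpha/m$ with $m$ recomputed from
the actual probe count of the input, never hard-coded.

Probe selection is the lasso with 10-fold seeded cross-validation at the
minimum-CV penalty by default; the sparser one-standard-error rule is
available (`rule = "lambda.1se"`) and is the better choice when false
selections are costlier than missed ones, since the min-CV rule habitually
over-selects. Variance explained compares ML fits of the full and
intercept-plus-random-intercept null models: McFadden
$1 - \ell_1/\ell_0$ and Nagelkerke
$(1 - e^{2(\ell_0-\ell_1)/n})/(1 - e^{2\ell_0/n})$, both clipped to
$[0,1]$ (with Gaussian likelihoods McFadden can stray outside otherwise).
Both are always reported because neither dominates in practice and
published tables mix them.

GWAM is the unweighted per-sample mean of CpG beta values over retained
probes; by default it is computed from raw masked betas (residualized
betas are equally usable as input — the function is agnostic), because the
quantity is defined on the beta scale. The GWAM regression standardizes
GWAM, making the slope invariant to adding a constant to all betas.
Site-level CpG tests reuse the same regression machinery restricted by a
gene-to-CpG proximity map and flag unadjusted p < 0.05 as *suggestive*
only — no correction is applied at that deliberately exploratory stage.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions everything else is tested under: 75 MZ + 55 DZ pairs, ages
uniform on 69–93 (pair-shared), MZ pairs same-sex, DZ pairs opposite-sex
with probability 0.5, traits of unit total variance (so fits report
standardized components directly). Latent genetic, shared and unique
factors can carry between-lipid correlation matrices (`rg_matrix`, and —
so environmental-correlation recovery is also testable — `rc_matrix`,
`re_matrix`). Covariates (education, BMI, smoking, lipid-lowering
medication, APOE ε4, batch) use plausible older-cohort marginals; they are
documented defaults, not estimates, and are independent of the traits, so
residualization is exercised but confounding recovery is not. Expression
probes are Gaussian noise plus planted `beta × standardized lipid` signals.
Methylation betas are inverse-logit transforms of probe baselines plus
Gaussian noise (the beta-value generative model is a package choice; array
preprocessing is out of scope), and a planted GWAM effect adds a per-sample
global latent shift whose correlation with the target lipid equals
`gwam_beta`, calibrating the planted regression slope. Default companion
sizes (500 probes, 1000 CpGs, 60 lipids) keep test runs around a minute;
full array scales are reachable through the config but are not defaults.

What passing tests on these data do **not** show about real cohorts:
lipid abundances here are exactly Gaussian with exactly additive
components — no skew the INT must repair beyond what is planted, no
assortative mating, no missing co-twins, no batch-by-lipid interactions,
no cell-composition confounding, and expression/methylation noise is
independent across probes. Recovery and calibration results transfer to
real data only to the extent those idealizations hold.

## Numerical choices and degenerate inputs

Tie-breaks and edge cases are deterministic and documented where they
occur: duplicate-resolution ties fall back to input order; empty lipid
classes are absent from group sums rather than zero-filled; an empty lasso
selection yields pseudo-r² of 0; an empty CpG mask, zero GWAM variance, an
all-identical INT input and a rank-deficient covariate design are errors
naming the offending columns; pairs with a missing co-twin value are
dropped listwise per trait. Problem sizes in the test and acceptance
studies (2000–5000 pairs/group for recovery, 200–500 replicates for
coverage and calibration) were chosen as the smallest sizes at which the
Monte-Carlo error is comfortably inside the asserted bands.

## Known limitations

Only univariate and bivariate (not higher-order multivariate) twin models;
no dominance (ADE) models, extended pedigrees or SNP-based heritability; no
epigenome-wide site-level scan (deliberately — the GWAM summary exists to
avoid that multiplicity burden); microarray and methylation-array
preprocessing are upstream of the package's inputs; and the profile-CI
inner optimization, while robust in the tested regimes, inherits the usual
caveats of nested numerical optimization very close to $h^2 = 1$.
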