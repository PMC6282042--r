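---
title: "Latent-trait construction and single-step genomic scans: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-trait construction and single-step genomic scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semscan)
```

## The problem

Meat and carcass quality in beef cattle are measured through panels of
correlated indicator traits — marbling score, quality grade and fat over the
ribeye on the carcass side; juiciness, tenderness and connective-tissue score
from a trained sensory panel on the eating-quality side.  Treating each
indicator as its own GWAS target wastes information and muddles
interpretation, because the indicators are noisy readouts of a small number
of underlying constructs.  `semscan` implements a two-stage alternative:

1. condense the indicators into latent variables with a confirmatory
   structural equation model (SEM) that also carries a causal path between
   the latents ("carcass quality" upstream, "meat quality" downstream);
2. run single-step GBLUP (ssGBLUP) whole-genome scans on the per-animal
   latent factor scores, partition the additive variance into windows of 20
   adjacent SNPs, and classify each window as **direct** (one trait),
   **pleiotropic** (both traits, signal surviving conditioning) or
   **indirect** (downstream signal that disappears once the upstream latent
   score is included as a covariate).

## Stage 1: the structural equation model

With `x` the indicators of the exogenous latent `xi` and `y` those of the
endogenous latent `eta`, the model is the standard LISREL system

```
x = Lambda_x xi + delta
y = Lambda_y eta + epsilon
eta = B eta + Gamma xi + zeta
```

with uncorrelated disturbances and diagonal residual covariances.  The
implied covariance `Sigma(theta)` is assembled blockwise and the parameters
are estimated by minimizing the ML discrepancy
`F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`; the test statistic is
`(n-1) F(theta_hat)`.

**Identification and the df = 10 question.**  Counting moments against free
parameters gives `df = p(p+1)/2 - q`.  Under the conventional marker
identification (first loading of each latent fixed to 1, latent variances
free) the final 6-indicator model has q = 13 and df = 8.  The published
account of this model reports df = 10, which implies q = 11; that count is
reproduced exactly by a doubly constrained parameterization — marker
loadings fixed *and* unit latent/disturbance variances — exposed here as
`identification = "marker_unit"`.  This parameterization restricts the
model (it pins the marker indicator's common variance) and we do not make it
the default; both counts are available and printed by
`model_degrees_of_freedom()`.

**Numerical choices.**  Variances are optimized on the log scale, so Heywood
cases cannot go negative; a variance pinned at the floor (1e-8 of the mean
indicator variance) raises a flag.  Optimization uses `nlminb` with
`rel.tol = 1e-12`; stationarity is declared when the numeric
central-difference gradient of `F` falls below 1e-4 (an exact analytic
1e-8 gradient norm is unattainable with finite-difference noise, and the
difference is invisible at the reported precision).  Robust (sandwich)
standard errors and a Satorra–Bentler-type scaled statistic are computed
from fourth-order moments when raw data are supplied; they change standard
errors and the test statistic only, never the point estimates — a property
the test suite asserts.

**Factor scores.**  The downstream mixed models need one phenotype per
animal per latent.  The scoring method is not dictated by the published
analysis, so both standard choices are implemented: regression scores
`E[latent | observed]` (default) and Bartlett scores; both are rescaled to
the latent's model-implied variance.  With the default measurement design
(standardized loadings 0.8) regression scores correlate ~0.93 with the true
latents in simulation.

**Bootstrap model check.**  The adequacy bootstrap resamples rows, refits,
and reports the proportion of draws rejecting the model.  Naively
resampling raw rows is grossly anti-conservative: the resampled covariance
inherits the sample's chance misfit as noncentrality, and with n = 2000
model-true data the naive failing proportion measured ~0.6 at a nominal
0.05.  The implementation therefore applies the Bollen–Stine rotation
(`Y = Xc S^-1/2 Sigma_hat^1/2`) by default, under which the check is
correctly calibrated (~0.05–0.06 measured); `rotate = FALSE` restores the
raw bootstrap for use as a misfit/power probe.

## Stage 2: kinship, ssGBLUP and variance components

SNP QC applies, in order: monomorphic removal, minor-allele frequency
(default 0.05), call rate (default 0.9), attributing each removed SNP to
the first rule it fails so the QC report always adds up; missing calls of
retained SNPs are imputed to twice the allele frequency.  The pedigree
matrix `A` uses the tabular method with inbreeding; the genomic matrix is
VanRaden's first method, `G = Zc Zc' / (2 sum p q)`.  Note that with sample
allele frequencies `G` is singular by construction (centering makes the
rows sum to zero), which is why the single-step matrix blends
`0.95 G + 0.05 A22` before inversion and
`H^-1 = A^-1 + [0, 0; 0, G^-1 - A22^-1]` uses the blended inverse
(tau = omega = 1, BLUPf90-style defaults).

**EM-REML.**  Single-trait variance components come from EM-REML
(relative-change tolerance 1e-6, cap 500 iterations by default).  A
one-time generalized eigendecomposition of the absorbed animal block makes
each EM iteration O(n), so the cap costs nothing; near the h2 = 0 boundary
EM converges slowly and legitimately reports the cap.  The heritability
standard error comes from the average-information matrix at the optimum.

**Bivariate REML.**  The genetic correlation is estimated by directly
maximizing the restricted likelihood over log-Cholesky factors of the 2x2
genetic and residual covariance matrices, after one eigendecomposition of
`K = W H W'` reduces each likelihood evaluation to O(n).  This is exact
REML — the same estimand as a bivariate EM — and is cross-checked in the
tests against a brute-force dense-matrix REML oracle; the Cholesky
parameterization keeps the covariance matrices inside the
positive-definite cone by construction.

**Back-solving and windows.**  SNP effects are recovered from genomic
breeding values by `u = Zc' G^-1 a / k`; with the unblended `G` of the same
`Zc` this reconstructs `a` exactly (asserted to 1e-8), with the blended
matrix the reconstruction error is bounded in the tests at 10% relative.
Window variance uses non-overlapping blocks of 20 map-adjacent SNPs
(trailing shorter windows kept and flagged):
`pct_w = 100 Var(Zc[,w] u[w]) / sigma2_total`.  The default denominator is
`Var(Zc u)` — the variance of the whole-genome direct genomic values — not
the REML `sigma2_a`: shrunken breeding values have variance well below
`sigma2_a`, and using the REML component would make window percentages sum
far below 100 even in the ideal unlinked case, defeating the
sum-conservation property the scan is tested against.  A REML denominator
can be passed explicitly.  Window percentages of *unlinked, unrelated*
samples sum to ~100; strong family structure correlates windows through
the genealogy and pushes the sum down — the conservation property is
therefore tested on founder-only genomes.

## The effect classifier

Three scans are run: upstream latent A, downstream latent B, and B with the
A factor score as a fixed covariate.  With `t` the association threshold,
a window is `direct_A_only` (A >= t, B < t), `direct_B_only` (A < t,
B >= t), `direct_both` (all three >= t), `indirect_via_A` (A and B >= t but
B|A < t), else `not_associated`.  "Disappearance" under conditioning is
judged by the same threshold `t`, the simplest rule consistent with the
taxonomy; both the genome-wide inventory threshold (0.05% of additive
variance) and the strong-region threshold (0.15%) are configuration
parameters, with the strong flag reported alongside the call.

## The synthetic world

The generator produces the statistical structure the analysis assumes, not
a biologically realistic cattle genome:

* **Pedigree**: founders plus `n_generations - 1` rounds of matings with a
  sire pool sized to give exactly `n_sires` sires with progeny — the
  defaults mirror a ~1,100-animal, four-generation, 143-sire herd.
* **Genotypes**: gene dropping over unlinked loci with founder frequencies
  uniform on (0.10, 0.45); the only linkage disequilibrium is that induced
  by the family structure.  Mendelian consistency is exact by construction
  and re-verified by a dosage-feasibility check.
* **Latents**: `latent_A = g_A + e_A` (unit variance),
  `latent_B = beta latent_A + g_B + e_B` with `beta = 0.28`.  With
  heritability targets 0.46/0.36 and `beta = 0.28`, solving for the
  independent genetic variance of B such that the causal path alone
  produces the target genetic correlation gives rg = 0.87 with *zero*
  pleiotropic polygenic covariance — i.e. the three published headline
  estimates are mutually consistent, and the generator's default world
  realizes all of them simultaneously.  Polygenic and environmental draws
  are rescaled to hit the target variances exactly (planted QTL effects are
  never rescaled), so parameter-recovery tests measure estimator error, not
  generator drift.
* **Indicators**: three per latent with loadings (1, 0.9, 1.1) and
  (1, 1.3, 1.1) — first loadings 1 so the latent scale equals the marker
  indicator's, and the strongest loadings sit on MARB and TD as in the
  motivating study — and measurement error giving standardized loadings of
  0.8.  Year-of-birth (categorical) and slaughter-age (continuous) fixed
  effects shift the *indicators*, mirroring an analysis that pre-adjusts
  observed traits, not latents.
* **Planted QTL**: one central SNP per nominated 20-SNP window; classes
  `direct_A`, `direct_B`, `pleiotropic`, `indirect`.  Indirect QTL touch
  only the genetics of A — their whole effect on B flows through `beta` —
  which is precisely what the conditioning scan is supposed to erase.
  Effects can be given in latent-SD units or as target shares of the
  latent's genetic variance (`share`); the share form back-computes the
  allele-substitution effect from the realized allele frequency, keeping
  planted architectures stable across seeds.

What a green test does **not** establish: realistic LD decay (there is
none beyond family structure), selection or assortative mating, breed
composition gradients, genotype-by-environment interaction, or the power
of the scan at the study's true marker density (the desk-scale genomes are
hundreds of SNPs, not 112k).

## Calibration of the acceptance worlds

*Parameter recovery* uses the default world at n = 1000 animals / 2000
SNPs, 20 replicates, and checks the means of REML heritabilities (±0.05),
the bivariate-REML genetic correlation (±0.1) and the SEM structural
coefficient (±0.05) against the generating values 0.46/0.36, 0.87, 0.28.

*Classification recovery* plants one window per effect class.  At desk
scale the published thresholds (0.05%/0.15% of a ~5,600-window genome) are
meaningless, so the test world was designed from variance arithmetic: with
`rg_target = 0.5` the share of an A-window's signal that reappears in the
B scan is `rg^2 = 0.25`; planted shares (0.18, 0.20/0.24, 0.30, 0.55 of
the respective genetic variances) and an association threshold of 6% then
separate every class by ~2.5 or more percentage points after allowing for
the ~0.5–0.9 attenuation of estimated window shares.  Heritabilities are
raised to 0.7/0.6 in this world so that the classifier's threshold logic —
not the sampling error of the scan, which is exercised elsewhere — is what
the test measures.  Share-based QTL sit on the most informative SNP of
their window and the planted genic components are orthogonalized
sequentially, so each planted share is realized exactly regardless of the
founder frequency draw and of family-structure covariance between QTL
columns (without this, planted variance drifts by several points per seed
and can overrun the heritability budget).  The design went through pilot
power iterations on seeds disjoint from the test's: margins were widened
by raising planted shares, never by moving the ≥90% recovery bar or the
per-genome spurious-indirect bound.  The no-causal-path control
(`beta = 0`) uses the same architecture and bounds spurious indirect calls
at one per genome.

*Concentration* plants a single causal SNP (h2 = 0.9) in an unrelated
sample with more animals than markers (800 vs 240): with m < n the
back-solve can localize the signal and the causal window must carry at
least 90% of the partitioned variance.  With m > n the causal column is
exactly collinear with the rest of the panel and ridge shrinkage spreads
the signal — a structural limit of GBLUP back-solving worth knowing when
interpreting real scans.

*SEM refit* (acceptance criterion 2): the study's supplementary covariance
matrix is not shipped with the package sources, so the refit is exercised
on a clearly-labelled synthetic stand-in built from the published model
structure — structural coefficient 0.28, indicator scales proportional to
the published trait SDs, strongest loadings on MARB and TD — plus
low-level Wishart noise (df 50,000, fixed seed).  The test asserts
recovery of the generating coefficient (±0.02) and good-fit bands that the
published indices themselves satisfy; it cannot, and does not, assert the
published index values digit for digit.

## Known limitations

* The scaled/adjusted robust test statistic approximates the named
  mean-and-variance-adjusted statistic by a scale correction only.
* EM-REML reports the iteration cap near variance boundaries instead of
  switching to a second-order method; estimates at the cap are still
  accurate to well below the reported precision.
* `G` inversion requires blending (or external allele frequencies); the
  pipeline falls back from the unblended to the blended matrix
  automatically when back-solving.
* The CLI is a thin wrapper (`inst/cli/semscan.R`) over `run_pipeline()`;
  it does not manage long-running or distributed workloads.
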