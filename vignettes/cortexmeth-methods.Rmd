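---
title: "Methods: cell-type-aware EWAS of cortical neuropathology"
author: "cortexmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-aware EWAS of cortical neuropathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`cortexmeth` implements a complete analysis chain for studying DNA
methylation in bulk cortical tissue against ordinal measures of
neurodegenerative pathology, together with a synthetic-data generator that
reproduces the statistical structure of such a study so every stage can be
validated against known ground truth. The chain is:

1. **Quality control** of probe × sample beta matrices: detection-p
   filtering, principal-component outlier exclusion, quantile normalization.
2. **Reference-based cell-type deconvolution**: a discriminating-site panel
   built from sorted-nuclei methylation profiles (NeuN+ neuronal, SOX10+
   oligodendrocyte, and a NeuN–/SOX10– "DN" microglia/astrocyte-enriched
   population), then per-sample constrained least squares.
3. **EWAS**: per-probe linear mixed models across two cortical regions
   (DLPFC, OCC) with a donor random intercept; joint three-measure
   likelihood-ratio tests; region-interaction tests; per-region OLS;
   proportion-versus-pathology regressions.
4. **Empirical-null adjustment** of z-statistics (bias and inflation).
5. **Fixed-effects inverse-variance-weighted meta-analysis** across cohorts.
6. **Concordance analysis**: sign tests of effect direction and bulk-versus-
   purified-fraction effect amplification.

# The measurement model

Methylation at probe $j$ in bulk sample $i$ is a proportion
$\beta_{ij} \in [0,1]$. Bulk tissue is a mixture of cell populations, so

$$\beta_{ij} \approx \sum_c \pi_{ic}\, \beta^{(c)}_{j},$$

where $\pi_{ic} \ge 0$ are nuclei proportions with $\sum_c \pi_{ic} \le 1$
(the remainder is debris and unmodeled material) and $\beta^{(c)}_j$ the
cell-type-specific methylation level. Two consequences drive the design:

* Pathology-correlated shifts in composition $\pi$ confound bulk EWAS, so
  estimated proportions enter the association models as covariates.
* A true effect of size $e$ confined to cell type $c$ appears in bulk
  attenuated to $\bar\pi_c \cdot e$. This **attenuation law** is exact for
  the noiseless generator (asserted to 1e-10 in the tests) and is the
  mechanism behind the amplification observed when the same contrast is run
  in a purified fraction: the expected fold-change is $1/\bar\pi_c$, about
  10 for a population mixing at 10%.

# The association models

Per probe, the cross-cortex model is

$$y_{ij} = \alpha + \sum_m \gamma_m \cdot \text{path}_{im} +
  \mathbf{x}_i^\top \boldsymbol\delta + u_{d(i)} + \varepsilon_{ij},$$

with pathology measures analyzed as continuous (Braak NFT stage 0–6, CERAD
score 0–3, Thal phase 0–5, Braak Lewy-body stage 0–6, TDP-43 status 0/1),
covariates $\mathbf{x}$ = age, sex, batch, PC1, and two of the three
estimated proportions (NeuN+ and DN; including all three invites
collinearity through the sum constraint), and a donor random intercept
$u_{d(i)}$ because each donor contributes both a DLPFC and an OCC sample.
Betas are analyzed untransformed so that coefficients, multiplied by 100,
read as percentage points of methylation per unit of the measure.

Numerical choices:

* Coefficient tests are Wald tests with a normal reference (REML fits). At
  the cohort sizes involved the difference from a mixed-model t
  approximation is negligible; the package documents this as a deliberate,
  configurable simplification.
* The joint test of the three AD measures (Braak, CERAD, Thal) is a
  likelihood-ratio test between full and null models **both fit by maximum
  likelihood** (REML likelihoods are not comparable across fixed-effect
  structures), referred to $\chi^2_3$. Type-I calibration on pure-null
  synthetic cohorts is part of the test suite (acceptance band 0.04–0.065
  at nominal 0.05, 2000 probes).
* When the donor-variance estimate hits the zero boundary (`isSingular`) or
  the fit fails, the model falls back to OLS with a logged flag; for the
  joint test both models then use the Gaussian ML likelihood ratio
  $n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$. On synthetic cohorts without a
  donor-level variance component this is the majority path, and it is exact
  there (verified against closed-form OLS oracles to 1e-8).
* Probe-wise complete cases for the response; samples missing covariates
  are dropped globally. Zero-variance probes are skipped and recorded.

The per-region models are plain OLS (one sample per donor within a region),
and the region-interaction test adds predictor × region to the mixed model
and Wald-tests that coefficient.

# Deconvolution

The panel is built by one-way ANOVA across cell types (selection cutoff
p < 1e-8), keeping per cell type the 50 most hypermethylated and 50 most
hypomethylated sites ranked by the contrast "mean in type − mean of
others", ties broken by F statistic then probe ID. A probe can serve only
one cell type (assigned to its largest absolute contrast) to avoid
collinear panel columns.

Proportions solve
$\min_\pi \lVert m - R\pi \rVert^2$ s.t. $\pi \ge 0,\ \sum \pi \le 1$.
With only three to four constrained dimensions, the package solves this
**exactly** by enumerating active sets (every subset of zero constraints ×
sum constraint, solving the equality-constrained least squares per subset
and keeping the feasible candidate with the smallest objective). This is
deterministic, dependency-free, and agrees with a dense grid-search oracle
in the tests; noiseless mixtures are recovered to machine precision.

`joint_normalize_and_estimate` quantile-normalizes the column-concatenated
[reference | bulk] matrix before building the panel and projecting, which
places both data sets on one scale. A caveat documented here deliberately:
bulk *mixtures* never share the distribution of purified references —
mixing compresses the bimodal beta distribution — so joint normalization
shifts absolute proportion estimates while preserving the composition
ranking. When reference and bulk are already on the same scale (the
intended use), the direct path is equally valid and more accurate on
synthetic data.

# Empirical-null adjustment

EWAS z-scores are modeled as a three-component Gaussian mixture: a central
null N(bias, inflation²) flanked by left and right signal components. The
package fits the mixture by MAP EM initialized at the median and MAD, with
three identifiability guards chosen because the unpenalized ML is
degenerate when the data are (nearly) all null:

* signal means at least 1 z-unit away from the null mean,
* signal SDs never below the null SD,
* a weakly informative Dirichlet prior on the weights (prior counts 5% of
  the number of z-scores, on the null), encoding the standard assumption
  that most probes are null — the same role the informative priors play in
  the Bayesian formulation this step emulates.

The EM is a deterministic point estimate rather than a posterior sampler;
the `seed` argument exists for interface stability. Its penalized objective
is non-decreasing per iteration (asserted in tests); non-convergence falls
back to the robust (median, MAD) estimate with a warning. Statistics are
rescaled as $z_\mathrm{adj} = (z - \mathrm{bias})/\mathrm{inflation}$, with
p-values from the normal tail and standard errors propagated as
$\mathrm{effect}/z_\mathrm{adj}$; effects themselves are left on the
percentage-point scale.

# Meta-analysis and concordance

Fixed-effects IVW pooling uses weights $w_i = 1/\mathrm{se}_i^2$; probes
must be present in at least two cohorts; Cochran's Q and I² are reported
descriptively only. Thresholding uses the full-precision $\alpha/n$;
the displayed value rounds halves away from zero (0.05/16 → 0.00313).

Direction concordance between two result sets uses the one-sided exact
binomial sign test $P(X \ge k)$, $X \sim \mathrm{Bin}(n, 1/2)$ — full
concordance reduces to $0.5^n$, which matches the convention used when such
comparisons are reported with printed p-values (a two-sided test would
double them). The fold-change report is the mean of per-site ratios
$|e_\mathrm{fraction}|/|e_\mathrm{reference}|$ (zero-reference sites
excluded and counted); a ratio-of-means variant is available behind a flag.
Because per-site ratios have a noisy denominator, small group sizes bias
the mean ratio upward; the acceptance computation therefore uses 60 donors
per pathology group, where the bias is a few percent.

# The synthetic-data generator

The generator emulates the study conditions end to end:

* **Reference profiles**: shared per-probe means, with planted
  discriminating sites per cell type (half hyper-, half hypomethylated by a
  configurable separation, default 0.5 beta units), constructed so no value
  leaves [0,1] — impossible configurations raise rather than clip.
* **Pathology**: a latent Gaussian copula thresholded to each ordinal
  range. Marginals are beta-binomials matched to cohort-typical means/SDs
  (Braak 3.72/1.90, CERAD 1.69/1.28, Thal 3.09/1.78, Lewy-body 1.34/2.26;
  TDP-43 positivity 22%); the latent correlation is 0.7 among the three AD
  measures and weaker (0.15–0.30) for the non-AD measures.
* **Composition**: Dirichlet draws (total concentration 200) around base
  means (NeuN+ 0.42, SOX10+ 0.37, DN 0.10; remainder debris). In the DLPFC
  only, the means shift linearly with Braak stage by −2.74 / +1.60 / −2.00
  percentage points per stage. The shift is centered at stage 3 (near the
  cohort mean) because an uncentered −2.00 pp/stage from a 10% base would
  cross zero at high stages; shifted means that still leave the simplex
  raise an error rather than being silently truncated. The per-stage shifts
  are read as percentage points (the scale is not stated with the source
  effect sizes; this is the generator's declared convention).
* **Effects**: differential methylation confined to a chosen cell type,
  specified per probe in percentage points per unit of a driving measure
  (default magnitude 0.44, the typical per-Braak-stage effect at
  tau-associated sites; a helper draws magnitudes around 0.44 with SD
  0.17). Several specs can be combined to plant a main effect in one cell
  type and a smaller secondary effect in another.
* **Noise**: logit-normal on the beta scale (shift on the logit scale, back
  transform; default SD 0.1), which preserves boundedness and the
  heteroscedasticity real arrays show near 0 and 1. Detection p-values are
  drawn directly — uniform on (0, 0.01) with a small failure mass on
  (0.9, 1) — rather than from an intensity model, which is out of scope.
* **Sorted-fraction studies**: low-pathology (Braak ≤ II) and
  high-pathology (Braak ≥ V) donor groups (defaults 15/13), with a total
  (bulk-like) fraction and one matrix per purified population; purified
  fractions carry planted effects at full magnitude.

Everything stochastic takes an explicit seed and touches only a local RNG
state; equal calls are bit-identical.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: probe-type chemistry and intensity-level
artifacts (the reason dasen-style normalization is out of scope and a
generic quantile normalization is used), genetic structure and SNP-probe
behavior, spatially correlated probes, cell-subtype heterogeneity within
the three populations, and non-linear pathology trajectories.

# Problem sizes and defaults used in validation

The shipped validation uses desk-scale sizes chosen to exercise every code
path with stable statistics: 2000 probes × 150 donors × 2 regions for
joint-test calibration; 200 noisy samples for deconvolution recovery
(MAE < 0.03 at noise SD 0.1, panel separation 0.5); 20 independent studies
of 60+60 donors for the fold-change computation; 10,000 z-scores for
empirical-null recovery. Where a statistical claim is inherently a rate, the
suite tests the rate over seeds rather than a single draw.

Two honest findings from validation are worth knowing. First, a
median/MAD-z PC outlier screen at 3.0 flags roughly 0.8% of samples of a
perfectly clean cohort (three PCs × the normal tail), so occasional
false removals are expected behavior, bounded by the built-in 50% guard.
Second, as noted above, joint quantile normalization of mixtures against
purified references shifts absolute proportion estimates; the direct
estimation path is preferable when scales already agree.

# Limitations

* The mixed-model Wald/normal and ML-LRT constructions are asymptotic;
  at very small donor counts (tens) their calibration degrades.
* The empirical-null EM estimates a point null; it does not decompose
  inflation by covariate, and extremely heavy signal fractions (>30%)
  would strain the "mostly null" prior.
* The deconvolution model assumes the reference panel spans the tissue's
  populations; unmodeled cell types load onto the debris slack and the
  nearest reference columns.
* Meta-analysis is fixed-effects only, matching its intended use for
  pooling harmonized cohort summaries; between-cohort heterogeneity is
  reported (Q, I²) but not modeled.
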