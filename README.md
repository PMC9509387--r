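# cortexmeth

Cell-type-aware epigenome-wide association analysis of cortical DNA
methylation against neuropathology.

## The problem

Epigenome-wide association studies (EWAS) of neurodegeneration measure DNA
methylation in *bulk* cortical tissue, but bulk methylation is a mixture
over cell populations whose composition itself shifts with pathology —
neuronal loss and glial activation confound naive per-probe regressions.
`cortexmeth` is for analysts working with methylation array data from
brain-bank cohorts who need the full chain:

* **QC**: detection-p filtering of samples and probes, PC-based outlier
  exclusion, between-sample quantile normalization;
* **deconvolution**: a discriminating-CpG reference panel built from
  sorted-nuclei profiles (NeuN+ neuronal, SOX10+ oligodendrocyte,
  NeuN–/SOX10– "DN" microglia/astrocyte-enriched), then per-sample
  constrained least squares for cell proportions;
* **EWAS**: per-probe linear mixed models across two cortical regions with
  a donor random intercept, joint multi-measure likelihood-ratio tests,
  region-interaction tests, and proportion-vs-pathology regressions;
* **empirical-null adjustment** of test statistics (bias/inflation);
* **fixed-effects inverse-variance-weighted meta-analysis** across cohorts;
* **concordance analysis**: exact binomial sign tests of effect direction
  and bulk-versus-purified-fraction effect amplification.

A synthetic-data generator emulates the whole study design — three-cell-type
mixtures in two regions per donor, correlated ordinal pathology staging
(Braak NFT, CERAD, Thal, Braak LB, TDP-43), pathology-coupled composition
drift in the DLPFC only, and cell-type-confined differential methylation —
so every stage is testable against known ground truth.

## The core model

Bulk methylation at probe $j$ in sample $i$ is
$\beta_{ij} \approx \sum_c \pi_{ic}\beta^{(c)}_{j}$ with proportions
$\pi \ge 0$, $\sum_c \pi_{ic} \le 1$. Proportions are estimated per sample
by $\min_\pi \lVert m - R\pi\rVert^2$ over that constraint set (solved
exactly by active-set enumeration), with the reference matrix $R$ built
from sorted-nuclei data via an ANOVA screen (p < 1e-8; 50 hyper- and 50
hypomethylated sites per cell type). The association model per probe is

    beta ~ pathology + age + sex + batch + PC1 + prop_NeuN + prop_DN + (1 | donor)

with coefficients reported in percentage points of methylation per unit of
the measure. An effect of size $e$ confined to cell type $c$ appears in
bulk attenuated to $\bar\pi_c e$ — the mechanism that makes effects roughly
$1/\bar\pi_c$-fold larger in the purified fraction than in bulk.

## Worked example

```r
library(cortexmeth)

# 1. Simulate a two-region cohort with a known DN-confined signal
profiles <- make_reference_profiles(n_probes = 800, n_celltypes = 3,
                                    n_discriminating_per_type = 120,
                                    separation = 0.5, seed = 11)
targets <- pick_effect_probes(profiles, 40, range = c(0.3, 0.7), seed = 12)
signal <- effect_spec(targets, "DN", effect_per_unit = 4,
                      driving_measure = "braak_nft")
cohort <- make_cohort(profiles, n_donors = 150, effect_spec = signal, seed = 13)

# 2. QC, covariates, deconvolution
qc <- pfilter(cohort$beta, cohort$detp)
pc1 <- compute_pc1(qc$beta)
reference <- simulate_reference_samples(profiles, n_per_type = 12, seed = 14)
panel <- select_discriminating_sites(reference$beta, reference$celltype)
props <- estimate_proportions(qc$beta, panel)
head(props, 3)
#>     sample_id         DN     NeuN+    SOX10+ residual_norm
#> 1 D0001_DLPFC 0.09214090 0.4568960 0.3905581     0.4541358
#> 2   D0001_OCC 0.09957892 0.4386794 0.3812154     0.4318525
#> 3 D0002_DLPFC 0.04893983 0.2776164 0.4117123     0.4111293

# 3. Cross-cortex EWAS with donor random intercepts
pheno <- attach_covariates(cohort$pheno, props, pc1)
ewas <- run_ewas(qc$beta, pheno, ewas_model_spec(predictors = "braak_nft"),
                 method = "wald")
head(ewas[, c("probe_id", "effect", "se", "p_value", "significant")], 3)
#>    probe_id    effect         se      p_value significant
#> 1 cg0000078 0.5654653 0.08507370 2.995953e-11        TRUE
#> 2 cg0000328 0.6507895 0.09922683 5.431386e-11        TRUE
#> 3 cg0000688 0.5192575 0.08007333 8.886494e-11        TRUE
mean(ewas$effect[match(targets, ewas$probe_id)])
#> [1] 0.4241997
```

The planted cell-level effect is 4 percentage points per Braak stage in a
population mixing at ~10%, so the expected *bulk* effect is ~0.4 pp/stage —
and the EWAS recovers 0.42 pp/stage averaged over the target probes.

```r
# 4. Empirical-null adjustment of the z-statistics
null_params <- estimate_empirical_null(ewas$statistic)
c(bias = null_params$bias, inflation = null_params$inflation)
#>       bias  inflation
#> -0.2302638  0.9263124
ewas_adj <- adjust_statistics(ewas, null_params)

# 5. Purified-fraction amplification of the DN-confined signal
study <- make_sorted_fraction_study(profiles, n_low = 60, n_high = 60,
                                    effect_spec = signal, seed = 15)
bulk_res <- high_low_group_ewas(study$fractions$total, study$labels)
dn_res <- high_low_group_ewas(study$fractions$DN, study$labels)
concordance_report(bulk_res, dn_res, targets)
#> Concordance over 40 sites: 40 concordant (100.0%), sign-test p = 9.09e-13
#> Mean fold-change in |effect| = 15.9 (0 zero-reference sites excluded)
```

Every target site changes in the same direction in bulk and in the purified
DN fraction, and the fraction effects are an order of magnitude larger. A
single simulated study scatters around the theoretical ~10x amplification
(here 15.9, because a chance imbalance in total nuclei mass between groups
offsets the small bulk denominators); averaged over 20 independent studies
the fold-change concentrates near 10 (see below).

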