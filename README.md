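# phenopred

Genomic and phenomic prediction for structured plant-breeding populations.

Breeding programs predict complex traits of selection candidates either
from genome-wide SNP markers (genomic selection) or — much more cheaply —
from near-infrared reflectance spectra of harvested material (phenomic
selection), using the same statistical machinery in both cases. How the two
approaches compare depends strongly on population structure: a panel made
of distinct material groups (heterotic pools, landraces) can make
marker-based prediction look far better than it is, because markers predict
group membership, not within-group merit. `phenopred` implements the whole
analysis chain needed to study this, end to end, for people working on
prediction methodology in breeding: multi-environment mixed models, SNP
quality control, NIRS preprocessing, a ridge-BLUP core that is agnostic to
the predictor type, the evaluation designs that expose structure artifacts,
and a synthetic-data generator that reproduces the relevant population
structure so everything is testable without field data.

## The models

**Plot model.** Plot-level trait values from multi-environment trials
follow

```
y_ijkl = mu + g_i + e_j + (ge)_ij + r_jk + b_jkl + eps_ijkl
```

with genotype g, environment (location-year) e, their interaction,
replicates r and incomplete blocks b nested in environments, and
homogeneous plot error. Fitting all factors as random (REML, via lme4)
gives variance components and the entry-mean broad-sense heritability

```
H2 = s2_g / (s2_g + s2_gxe / n_e + s2_eps / (n_e * n_r))
```

overall or per material group. Fitting genotype as fixed gives one best
linear unbiased estimate (BLUE) per genotype, the phenotype used for all
prediction steps. A Holm-corrected outlier screen on standardized residuals
precedes the fits.

**Prediction model.** For a training set with BLUEs `y` and a predictor
matrix `Z` (SNP dosages or preprocessed spectra),

```
y = 1 mu + Z u + eps,   u ~ iid N(0, V_u),   eps ~ N(0, V_e I)
```

is ridge-regression BLUP: all predictors kept, effects shrunk uniformly.
The single variance ratio `lambda = V_e / V_u` is estimated by REML,
profiled on the eigenvalues of `Z Z'` and maximized by Brent search on
`log(lambda)`. The algebraically equivalent kernel (GBLUP) path is
implemented separately and serves as a numerical oracle. Predictive
ability is the Pearson correlation between predictions and BLUEs of a
prediction set; `structure_decomposition()` contrasts the pooled
correlation with within-subgroup correlations to expose structure
artifacts.

**Supporting stages.** Marker QC (strict thresholds: all-missing, >50%
missing, >5% heterozygous, monomorphic; per-group monomorphic/MAF < 3%
filters with het set to missing; mean imputation; MAF < 5% filter and
merge on the intersection), NIRS preprocessing (18 nm edge trim,
Savitzky-Golay smoothing and first derivative built from first principles,
per-wavelength BLUEs and heritabilities, column standardization), k-fold
cross-validation with proportional subgroup stratification, among-group
and composite-training-set designs, and DAPC group discrimination.

## A worked example

```r
library(phenopred)

# a small synthetic study: two elite pools, two landraces, 160 genotypes,
# 3 environments x 2 replicates, markers and seed spectra
study <- simulate_study(seed = 42,
                        group_sizes = c(ED = 50, EF = 50, SM = 30, WA = 30),
                        n_markers = 300, wl_range = c(1250L, 1329L))

h2 <- heritability(fit_plot_model(study$plots, "trait")$vc)
sprintf("entry-mean heritability: %.2f", h2)
#> entry-mean heritability: 0.96

ed <- study$groups$genotype[study$groups$major_group == "ED"]
cv_g <- run_within_cv(study$y[ed], study$Z_genomic,  n_runs = 25, seed = 7)
cv_p <- run_within_cv(study$y[ed], study$Z_phenomic, n_runs = 25, seed = 7)
sprintf("within-ED predictive ability: genomic %.2f, phenomic %.2f",
        cv_g$mean_r, cv_p$mean_r)
#> within-ED predictive ability: genomic 0.60, phenomic 0.44

lr <- study$groups$genotype[study$groups$major_group == "LR"]
r_g <- run_among(study$y, study$Z_genomic,  lr, ed)
r_p <- run_among(study$y, study$Z_phenomic, lr, ed)
sprintf("landraces -> ED: genomic %.2f, phenomic %.2f", r_g, r_p)
#> landraces -> ED: genomic 0.31, phenomic 0.45
```

The pattern is the central phenomenon the package is built around: within a
group, marker-based prediction profits from relatedness between training
and prediction sets and wins; predicting one group from another, that
relatedness is gone and the spectra — which carry trait signal through seed
chemistry rather than ancestry — transfer better.

The packaged scenarios `scenario_confounded()` and `scenario_transfer()`
are larger, fixed-parameter versions of this experiment (the full
eight-subgroup panel, 400 genotypes, 2,400 plots) used throughout the test
suite; the methods vignette (`vignettes/phenomic-prediction.Rmd`)
documents every default and the reasoning behind it.

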