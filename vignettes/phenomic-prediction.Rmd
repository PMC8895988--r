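---
title: "Genomic and phenomic prediction under population structure: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic and phenomic prediction under population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the tunable parameters with their
defaults and units, what the synthetic-data generator does and does not
emulate, the numerical choices, and the places where the design was
genuinely open and a decision had to be made. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The plot-level mixed model

Plot values from multi-environment trials are modeled as

$$y_{ijkl} = \mu + g_i + e_j + (ge)_{ij} + r_{jk} + b_{jkl} +
\varepsilon_{ijkl},$$

with genotype $g_i$, environment (location–year combination) $e_j$, their
interaction, replicates $r_{jk}$ and incomplete blocks $b_{jkl}$ nested in
environments, and a homogeneous error variance. `fit_plot_model()` fits
this by REML through `lme4::lmer` (bobyqa, `rhoend = 1e-10`; the tight
tolerance matters because balanced-design tests compare REML against
closed-form ANOVA estimators at $10^{-6}$). Negative variance components
are handled by lme4's boundary constraint, i.e. set to zero. Terms that the
design at hand cannot support — a single environment, a single replicate,
one block per replicate — are dropped and recorded in the returned fit, and
a design with no random terms at all falls back to ordinary least squares.

Two fitting modes exist. With all factors random, the variance components
feed the entry-mean broad-sense heritability

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{g\times e}/n_e +
\sigma^2_\varepsilon/(n_e n_r)},$$

where $n_e$ and $n_r$ are counted from the observed data per trait (traits
measured in fewer environments get their own $n_e$). With genotype fixed,
the fit yields one BLUE per genotype; these BLUEs are the phenotypes for
every downstream prediction step. Components that a degenerate design
leaves inestimable enter the formula as zero, with a warning — what cannot
be separated from the genotype signal is not charged against it.

**Group-specific heritabilities** are obtained by refitting the all-random
model on each group's subset. For disjoint groups this is equivalent to a
dummy-variable fit with group-specific genotypic and interaction variances,
and it is simpler to implement and to test.

**BLUEs at scale.** A genotype-fixed REML fit carries a dense fixed-effect
block of one column per genotype, which is slow when repeated over a
thousand wavelengths that share one field design. `fit_plot_model(...,
vc_method = "random")` therefore estimates the variance components once
from the fast all-random fit and solves the genotype-fixed GLS problem
exactly through sparse mixed-model equations. In balanced orthogonal
designs both routes return the arithmetic genotype means exactly; under
unbalancedness they differ only through the variance weighting. The
per-trait BLUEs use the full genotype-fixed REML (`vc_method = "reml"`,
the default); the per-wavelength spectral BLUEs use the plug-in route.

**Outlier screening.** `detect_outliers()` standardizes the conditional
residuals of the all-random fit by the rescaled median absolute deviation
(robust against the very outliers being sought), converts them to
two-sided normal p-values, applies the Holm step-down correction at
family-wise level $\alpha = 0.05$ (the level is a convention of the
method's common use in trial analysis; the procedure itself does not fix
one), sets flagged plots to missing, and refits once.

## 2. Marker quality control

`qc_overall()` removes, in order: markers with only missing calls; markers
with a missing fraction strictly above 50%; markers with a heterozygous
fraction (over non-missing calls) strictly above 5%; and monomorphic
markers among the remaining. All thresholds are strict inequalities.
"Monomorphic" means one allele among the non-missing calls; a heterozygous
call carries both alleles, so het-only markers count as polymorphic.
Afterwards every genotype is checked against the complementary criteria
(>20% missing, >5% heterozygous over the surviving markers); failing
genotypes are flagged in the report, never silently dropped. The report is
additive (removed counts sum to the difference between input and output)
and re-running QC on its own output removes nothing — both are asserted in
tests.

`qc_per_group()` splits by material group and, per group: recodes
heterozygous calls to missing *first* (het information is kept as missing
rather than discarded as a marker; the order het-recode-then-filter is our
convention where the procedure's description leaves it open), then drops
all-missing markers, monomorphic markers, and markers with minor allele
frequency strictly below 3% (computed over non-missing calls). Marker sets
may differ between groups afterwards. `impute_naive()` codes dosages 0/1/2
and replaces missing values by the within-group marker mean — a
deliberately simple, fully documented imputer; haplotype-based imputation
is out of scope. `maf_filter_and_merge()` applies the final strict 5% MAF
filter per group and merges on the **intersection** of the surviving
marker sets: a union would leave blocks of structurally missing dosages in
the one common predictor matrix the ridge model needs, so intersection is
forced by the model contract.

## 3. NIRS processing

The pipeline order is fixed: trim, then smooth/derive, then per-wavelength
BLUE, then standardize. `trim_edges()` cuts 18 nm from each side of the
wavelength grid to exclude detector border effects. `savitzky_golay()` is
built from first principles as the local least-squares polynomial
convolution: the kernel weights come from the normal equations of the
window's Vandermonde design and reproduce the $m$-th derivative of any
polynomial of degree $\le p$ exactly at the center — the property the test
suite asserts across the supported $(w, p, m)$ grid, alongside agreement
with an independent reference filter. Defaults are window $w = 11$ points,
polynomial order $p = 2$, first derivative $m = 1$: common chemometrics
practice, recorded in the output metadata, and exposed as arguments.
Edge points whose window leaves the series are dropped rather than padded,
consistent with the deliberate edge trimming. Repeated cup measurements of
one sample are expected to be averaged to one spectrum per plot before
modeling — one value per plot is what the plot model is defined on.

Each retained wavelength is then treated as a trait: genotype-fixed fits
give the genotype × wavelength BLUE matrix, all-random fits (optional) a
per-wavelength heritability. Finally `standardize_columns()` centers and
scales each wavelength column to unit variance — required for the ridge
model's assumption of a common effect variance across predictors — and
drops constant columns with a warning. Standardization acts on the
genotype-level BLUE matrix, never on plot-level spectra; the type system
enforces the order (a standardized matrix is not a `spectra_table` and is
refused by `wavelength_blues()`).

## 4. The ridge (RR-BLUP) core

With per-genotype BLUEs $y$ and an $n \times p$ predictor matrix $Z$,

$$y = \mathbf{1}\mu + Zu + \varepsilon, \qquad u \sim N(0, V_u I_p),
\qquad \varepsilon \sim N(0, V_e I_n),$$

so $\mathrm{Var}(y) = V_u (ZZ' + \lambda I)$ with $\lambda = V_e / V_u$.
The restricted likelihood is profiled in $\lambda$ on the eigenvalues of
$S K S$, where $K = ZZ'$ and $S$ projects orthogonally to the fixed-effect
design, and maximized by Brent search on $\log\lambda$ over
$[10^{-5}, 10^5]$ with tolerance $10^{-9}$; the test suite checks the
optimum against a 1,001-point grid search. One numerical subtlety is worth
recording: when $p < n$ the kernel is rank-deficient and the zero-eigenvalue
block of $SKS$ mixes the fixed-effect direction with genuine kernel-null
directions, so the response must be projected through $S$ *before* rotating
onto the eigenbasis; rotating the raw response corrupts the profile
whenever the response mean is far from zero. The intercept is the only
fixed effect by default — the responses are BLUEs, so the design matrix of
the plot phase has already been absorbed. Dosage columns are not centered
(with an intercept the model is affine-invariant per column, which the
tests assert via the allele-flip invariance $d \to 2 - d$); spectral
predictors arrive standardized.

Effects are $u = Z'H^{-1}(y - \mathbf{1}\hat\mu)$ with
$H = K + \lambda I$, and predictions for new genotypes are
$\hat y = \hat\mu + Z_{new} u$, with the column identity and order of
$Z_{new}$ checked against the training features. `gblup_equiv()` fits the
same model through the kernel parameterization and predicts via
$K_{new} H^{-1}$; marker-effect and kernel predictions are algebraically
identical, and their agreement to $10^{-8}$ relative tolerance on random
instances is the module's central oracle. An exactly constant response
returns the boundary model ($V_u = 0$, all effects zero, prediction equal
to the mean) with a "no signal" warning rather than an error, so that
degenerate folds fail soft inside cross-validation loops.

## 5. Evaluation designs

`run_within_cv()` implements k-fold cross-validation (default $k = 5$)
with many random partitions per group; the predictive ability is the
Pearson correlation computed per prediction set (per fold), and fold-level
correlations are pooled across runs. For heterogeneous groups, folds are
stratified proportionally by subgroup with largest-remainder rounding —
every fold's count from subgroup $s$ is within one of $n_s/k$, subgroups
are processed in name order, and the whole partition is a deterministic
function of the seed (all property-tested). Groups under 30 members are
refused as standalone sets. `run_among()` is a single fit on one whole
group and a single correlation on another, disjointness enforced, negative
correlations reported as-is. `run_composite()` draws a random 80/20 split
of the target group, trains on the 80% plus whole other groups, and
evaluates on the 20%; with `compare_among = TRUE` it also evaluates an
others-only model on the *same* held-out set, making the
composite-vs-among contrast a paired comparison on identical prediction
sets. `structure_decomposition()` reports the pooled correlation, the
within-subgroup correlations, and their unweighted mean $\bar r$; no
ordering between the pooled value and $\bar r$ is assumed anywhere —
either can be larger, and the contrast between the two is precisely the
structure diagnostic. For display-style decompositions the predictions of
several runs are pooled before correlating (`keep_predictions = TRUE`);
summaries always use fold-level correlations.

`dapc()` is principal components followed by linear discriminant axes on
the retained scores, reporting per-axis discriminant variance, coordinates,
and the leave-one-out reassignment rate. The retained-PC default — the
smallest count explaining 90% of variance, capped at $n/3$ — is a
convention; a singular within-group scatter triggers automatic reduction.

## 6. The synthetic-data generator

The generator exists so that every stage — QC, mixed models, spectral
processing, prediction, evaluation — can be exercised end to end, with
known truth, at desk scale. It emulates a maize panel of two elite
heterotic pools and six landraces (subgroup sizes 100, 100, 11, 33, 14,
53, 30, 59; 400 genotypes), phenotyped in 3 environments × 2 replicates
(2,400 plots), genotyped, and measured by NIRS.

**Markers.** Subgroup allele frequencies follow the Balding–Nichols model,
$p_g \sim \mathrm{Beta}(p(1-F)/F,\, (1-p)(1-F)/F)$ with ancestral
$p \sim U(0.1, 0.9)$ — the standard single-parameter structure model. An
optional second Balding–Nichols layer nests families inside subgroups
(default in the packaged scenarios: families of 10 at $F_{fam} = 0.6$),
giving lines within a breeding group realistic marker kinship without
simulating pedigrees. Lines are doubled haploids (dosage 0/2), degraded
with 1% heterozygous and 3% missing calls so QC has realistic work.

**Traits.** A genetic value has three parts: a QTL component (dosage times
iid effects), a polygenic "chemistry" component expressed in the spectra,
and a subgroup mean offset of `delta_sd` within-group genetic standard
deviations that confounds performance with structure. Shares and the
heritability target are all defined on the pooled within-subgroup variance
— the basis on which group-specific heritabilities are reported; the
between-group part of the QTL component then rides on top as natural
genomic differentiation. Only a fraction of the causal loci
(`tagged_fraction`, scenario default 0.15) are genotyped markers; the rest
follow the same frequency hierarchy but are invisible to the array, so
marker-based prediction reaches them only through relationship. This is
the generator's stand-in for the fact that real arrays tag causal variation
through linkage disequilibrium whose phase is group-specific: effects
estimated in one group then transfer poorly to another even though the
trait is perfectly additive. Explicit LD simulation is deliberately out of
scope.

**Plots and spectra.** Plot data are generated exactly under the model of
Section 1 with independent normal effects; `vc_for_h2()` translates an
entry-mean heritability target (scenario default 0.9, within the range
typically reported for well-run maize trials) into interaction and error
variances at a fixed split. Spectra are a smooth shared baseline plus
Gaussian absorption bands (default 8 bands, 15 nm width) whose heights are
linear in latent chemistry scores, plus smooth environment-level shifts
(SD 0.005 reflectance units) and iid noise (SD 0.002, understood as the
residual after averaging ~24 repeated cup measurements). The first latent
component correlates 0.9 with the chemistry part of the genetic value;
group labels never enter the spectra directly. No quantitative spectral
noise model was available to copy, so these defaults are stated
conventions, chosen once at magnitudes a spectroscopist would call
plausible for ground grain samples, and exposed in the configuration. Band
centers are spread evenly (with jitter) across the usable window so that
distinct latent components keep distinguishable wavelength profiles.

**Packaged scenarios.** `scenario_confounded()` (trait shares 0.1 QTL /
0.9 chemistry, offsets of 3 SD) makes within-landrace trait variance
nearly invisible to markers while subgroup means separate strongly: pooled
genomic cross-validation correlations are then driven by structure and
collapse within single landraces, while spectral prediction shows no such
artifact. `scenario_transfer()` (defaults: 0.75/0.25 shares, offsets of
1.5 SD) is the training-set-composition scenario: spectral effects
transfer across groups, marker-based prediction relies on within-group
relationship and collapses among groups, and composite training sets
restore it. Scenario parameters were fixed during generator design by
validating the qualitative contrasts distributionally across many generic
dataset seeds, and are not tuned per seed; the desk-scale sizes (400
markers before QC, 80 causal loci, a 101 nm spectral window) keep the full
pipeline runs to tens of seconds while preserving the phenomena. The
reduced marker count also reflects that with independent loci the
effective dimensionality equals the marker count, whereas a 50K array with
LD has a far smaller effective dimension.

**What the generator does not emulate.** Linkage disequilibrium and
marker–QTL phase (replaced by the untagged-loci device), pedigree
structure beyond exchangeable families, dominance and epistasis,
heterogeneous error variances across environments, spatial field trends,
scatter effects in spectra (no SNV/MSC corrections are implemented), and
any vendor-specific instrument behavior. Passing tests therefore show that
the *machinery* is correct and that the structure phenomena arise under
the stated mechanisms — not that real maize data would yield the same
numbers.

## 7. Numerical choices and degenerate inputs

- REML (plot model): lme4 bobyqa, `rhoend = 1e-10`; singular fits
  accepted (boundary at zero).
- REML (ridge): Brent on $\log\lambda \in [\log 10^{-5}, \log 10^5]$,
  tolerance $10^{-9}$; the profile is evaluated on eigenvalues clipped at
  zero; responses are projected orthogonally to the fixed effects before
  rotation (see Section 4).
- GLS BLUEs via sparse mixed-model equations use a floor of
  $10^{-10}\,\mathrm{var}(y)$ on the residual variance so the equations
  stay nonsingular on noise-free toy data.
- Stratified fold allocation breaks remainder ties by subgroup name order,
  then RNG; all randomness flows from a single integer seed per call, and
  compound pipelines derive stage seeds by fixed offsets (`child_seed`),
  kept below $2^{31}$.
- Constant predictor columns are dropped (standardization), constant
  responses yield boundary models with warnings, zero-variance prediction
  sets raise errors rather than returning a correlation of zero.
- An exactly balanced design makes BLUEs equal genotype means to machine
  precision regardless of the variance components; this is the anchor the
  oracle tests use.

## 8. Known limitations

Group-specific variance components are obtained by subsetting rather than
a joint heteroscedastic fit, which is equivalent for disjoint groups but
does not share error information across groups. The naive imputer ignores
linkage information entirely; its cost is quantified in a paired test
(about 0.02–0.05 predictive-ability loss at 10% missingness) but it is not
a substitute for haplotype-based imputation on real data. The per-wavelength
plug-in GLS differs from full genotype-fixed REML under strong
unbalancedness. DAPC uses a simple retained-PC heuristic rather than
cross-validated selection. The acceptance quantities computed on packaged
scenarios are stochastic reproductions of qualitative phenomena, with seed
variability documented in the test tolerances, not point estimates of any
real dataset.
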