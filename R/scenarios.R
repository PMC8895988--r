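## Packaged seeded study scenarios: end-to-end synthetic datasets with the
## panel structure of the real study (two elite pools plus six landraces,
## 400 genotypes, three environments, two replicates, 2,400 plots) at desk
## scale for markers and wavelengths. Both expose the trait BLUEs and the
## genomic and phenomic predictor matrices that every evaluation design
## consumes.

#' Simulate a complete genomic-plus-phenomic study
#'
#' Chains the full pipeline: structured population, additive trait with a
#' configurable split between marker-QTL and spectra-borne chemistry
#' variance plus subgroup mean offsets, multi-environment plot data at a
#' target entry-mean heritability, plot-level spectra, trait BLUEs from the
#' genotype-fixed mixed model, marker QC / imputation / merge into the
#' genomic predictor matrix, and the NIRS pipeline (trim, Savitzky-Golay
#' first derivative, per-wavelength BLUEs, standardization) into the
#' phenomic predictor matrix.
#'
#' @param seed integer master seed (stage seeds are derived from it)
#' @param group_sizes named subgroup sizes (default: the study panel)
#' @param n_markers markers before QC
#' @param fst subgroup divergence
#' @param family_fst,family_size within-subgroup family layer (marker-based
#'   kinship inside breeding groups)
#' @param n_qtl causal markers
#' @param qtl_share,chem_share within-group genetic variance shares of the
#'   marker-QTL and chemistry components
#' @param tagged_fraction fraction of causal loci on the genotyped array
#'   (the rest act through genomic relationship only)
#' @param delta_sd subgroup offset SD in within-group genetic SD units
#' @param chem_cor chemistry / genetic-value correlation
#' @param h2 target entry-mean heritability of the trait
#' @param ne,nr environments and replicates
#' @param wl_range simulated wavelength window (nm)
#' @param spectra_h2 return per-wavelength heritabilities too?
#' @return list with pop, groups, trait, plots, y (named BLUE vector),
#'   Z_genomic, Z_phenomic, h2_wavelength, qc_report
#' @export
simulate_study <- function(seed = 1L,
                           group_sizes = panel_sizes(),
                           n_markers = 400L, fst = 0.4,
                           family_fst = 0.6, family_size = 10L,
                           n_qtl = 80L, qtl_share = 0.75, chem_share = 0.25,
                           tagged_fraction = 0.15,
                           delta_sd = 1.5, chem_cor = 0.9,
                           h2 = 0.9, ne = 3L, nr = 2L,
                           wl_range = c(1250L, 1350L),
                           spectra_h2 = FALSE) {
  pop <- simulate_population(group_sizes = group_sizes, n_markers = n_markers,
                             fst = fst, family_fst = family_fst,
                             family_size = family_size,
                             seed = child_seed(seed, 1L))
  tr <- simulate_trait(pop, n_qtl = n_qtl, qtl_share = qtl_share,
                       chem_share = chem_share, delta_sd = delta_sd,
                       chem_cor = chem_cor, tagged_fraction = tagged_fraction,
                       seed = child_seed(seed, 2L))
  # target h2 applies to the pooled within-subgroup genetic variance
  # (heritabilities are reported per material group); group offsets and the
  # between-group part of the QTL component sit on top of it
  gg <- tr$truth$g_mark + tr$truth$g_chem
  s2g_within <- stats::var(gg - stats::ave(gg, pop$groups$subgroup))
  vc <- vc_for_h2(s2g_within, h2, ne, nr)
  plots <- simulate_plots(tr$g, ne = ne, nr = nr, n_blocks = 10L, mu = 10,
                          vc = c(vc, sigma2_env = 1, sigma2_rep = 0.1,
                                 sigma2_block = 0.1),
                          trait = "trait", seed = child_seed(seed, 3L))
  spectra <- simulate_spectra(tr$chem, wl_range = wl_range, ne = ne, nr = nr,
                              seed = child_seed(seed, 4L))
  blues <- compute_blues(plots, "trait")
  y <- stats::setNames(blues$trait, rownames(blues))
  mp <- marker_pipeline(pop$geno, pop$groups)
  nir <- nirs_pipeline(spectra, h2 = spectra_h2)
  list(pop = pop, groups = pop$groups, trait = tr, plots = plots, y = y,
       Z_genomic = mp$dosage, Z_phenomic = nir$predictors,
       h2_wavelength = nir$h2, qc_report = mp$report,
       spectra = spectra, seed = seed)
}

#' The confounded-structure scenario
#'
#' Trait variance within subgroups is carried almost entirely by seed
#' chemistry (visible to the spectra) with only a small marker-QTL share,
#' while subgroup means differ by three within-group genetic SDs. Marker
#' data separate the subgroups cleanly, so genomic prediction in the pooled
#' landrace group attains a high overall correlation that collapses within
#' single landraces — the structure artifact — whereas spectral prediction
#' does not inherit group membership.
#'
#' @param seed integer seed
#' @return a [simulate_study()] result
#' @export
scenario_confounded <- function(seed = 11L) {
  simulate_study(seed = seed, qtl_share = 0.1, chem_share = 0.9, delta_sd = 3)
}

#' The training-set-transfer scenario
#'
#' Uses the study defaults: most causal variation untagged by the array
#' (visible to markers only through family and group relationship) plus a
#' spectra-borne chemistry component and moderate subgroup offsets. Spectral
#' effects transfer across groups, so phenomic among-group prediction
#' matches its within-group level; marker-based prediction relies on
#' relationship and collapses among groups, and re-adding 80% of the target
#' group to a composite training set restores it.
#'
#' @param seed integer seed
#' @return a [simulate_study()] result
#' @export
scenario_transfer <- function(seed = 21L) {
  simulate_study(seed = seed)
}
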