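## Synthetic-data generator: structured populations, additive traits with
## optional group-mean confounding, multi-environment plot data, and smooth
## NIR-like spectra carrying trait signal through latent seed chemistry.

#' Default subgroup sizes of the simulated maize panel
#'
#' Two elite heterotic pools (ED, EF; 100 lines each) and six landraces of
#' very unequal size, 400 genotypes in total. These sizes define the panel
#' every packaged scenario emulates.
#'
#' @return named integer vector of subgroup sizes
#' @export
panel_sizes <- function() {
  c(ED = 100L, EF = 100L, CG = 11L, GB = 33L, RT = 14L,
    SM = 53L, SF = 30L, WA = 59L)
}

#' Major-group assignment for the default panel subgroups
#'
#' @param subgroup character vector of subgroup codes
#' @return character vector: "ED", "EF" or "LR"
#' @export
major_group_of <- function(subgroup) {
  ifelse(subgroup %in% c("ED", "EF"), as.character(subgroup), "LR")
}

#' Simulate a structured biallelic population
#'
#' Draws ancestral allele frequencies p ~ Uniform(0.1, 0.9) and per-subgroup
#' frequencies from the Balding-Nichols model
#' Beta(p(1-F)/F, (1-p)(1-F)/F), then samples fully homozygous doubled-haploid
#' calls (dosage 0 or 2) per genotype, optionally degraded with heterozygous
#' calls and missing values so the marker-QC stage has realistic work to do.
#'
#' A second, optional Balding-Nichols layer nests families of size
#' `family_size` inside every subgroup (family frequencies drawn around the
#' subgroup frequencies with divergence `family_fst`). This gives lines
#' within a subgroup realistic marker-based kinship — the relatedness that
#' genomic prediction exploits inside breeding groups — without simulating
#' pedigrees. `family_fst = 0` (default) disables the layer.
#'
#' @param group_sizes named integer vector of subgroup sizes
#' @param n_markers number of biallelic markers
#' @param fst Balding-Nichols divergence parameter, strictly in (0, 1)
#' @param het_rate fraction of calls flipped to heterozygous
#' @param missing_rate fraction of calls set to missing
#' @param family_fst within-subgroup family divergence (0 = no families)
#' @param family_size lines per family when `family_fst > 0`
#' @param seed integer seed
#' @return list with elements `geno` (a [geno_matrix]), `groups` (a group
#'   map data frame: genotype, subgroup, major_group) and `truth` (ancestral
#'   and per-group allele frequencies)
#' @export
simulate_population <- function(group_sizes = panel_sizes(),
                                n_markers = 1000L,
                                fst = 0.2,
                                het_rate = 0.01,
                                missing_rate = 0.03,
                                family_fst = 0,
                                family_size = 10L,
                                seed = 1L) {
  stop_if_not_scalar_prob(fst, "fst")
  stopifnot(family_fst >= 0, family_fst < 1, family_size >= 2L)
  stopifnot(all(group_sizes >= 1L), n_markers >= 1L)
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- paste0("G", seq_along(group_sizes))
  }
  set.seed(seed)
  n <- sum(group_sizes)
  p_anc <- stats::runif(n_markers, 0.1, 0.9)
  a <- p_anc * (1 - fst) / fst
  b <- (1 - p_anc) * (1 - fst) / fst
  p_grp <- sapply(names(group_sizes), function(g) stats::rbeta(n_markers, a, b))
  # guard the open interval; rbeta can return exactly 0/1 for extreme shapes
  p_grp <- pmin(pmax(p_grp, 1e-6), 1 - 1e-6)

  subgroup <- rep(names(group_sizes), group_sizes)
  genotype_ids <- paste0(subgroup, "_", unlist(lapply(group_sizes, seq_len)))
  calls <- matrix(NA_integer_, n_markers, n,
                  dimnames = list(paste0("M", seq_len(n_markers)), genotype_ids))
  family <- integer(n)
  for (g in names(group_sizes)) {
    idx <- which(subgroup == g)
    if (family_fst > 0) {
      fam_of <- ((seq_along(idx) - 1L) %/% family_size) + 1L
      family[idx] <- fam_of
      for (f in unique(fam_of)) {
        af <- p_grp[, g] * (1 - family_fst) / family_fst
        bf <- (1 - p_grp[, g]) * (1 - family_fst) / family_fst
        p_fam <- pmin(pmax(stats::rbeta(n_markers, af, bf), 1e-6), 1 - 1e-6)
        members <- idx[fam_of == f]
        calls[, members] <- 2L * (matrix(stats::runif(n_markers * length(members)),
                                         n_markers) < p_fam)
      }
    } else {
      # doubled haploids: a line is hom-ALT with prob p, hom-REF otherwise
      calls[, idx] <- 2L * (matrix(stats::runif(n_markers * length(idx)),
                                   n_markers) < p_grp[, g])
    }
  }
  n_cells <- length(calls)
  if (het_rate > 0) {
    het <- which(stats::runif(n_cells) < het_rate)
    calls[het] <- 1L
  }
  if (missing_rate > 0) {
    mis <- which(stats::runif(n_cells) < missing_rate)
    calls[mis] <- NA_integer_
  }
  groups <- data.frame(genotype = genotype_ids,
                       subgroup = subgroup,
                       major_group = major_group_of(subgroup),
                       family = family,
                       stringsAsFactors = FALSE)
  list(geno = geno_matrix(calls),
       groups = groups,
       truth = list(p_ancestral = p_anc, p_group = p_grp, fst = fst,
                    family_fst = family_fst,
                    group_sizes = group_sizes, seed = seed))
}

#' Simulate an additive trait over a simulated population
#'
#' The genetic value of line i is the sum of three components:
#' a marker-QTL part (dosage times iid effects on `n_qtl` randomly chosen
#' markers), a polygenic "chemistry" part that is independent of the markers
#' but expressed in the seed spectra, and a subgroup mean offset of standard
#' deviation `delta_sd` (in units of the within-group genetic SD) that
#' confounds trait performance with population structure. The marker and
#' chemistry parts are scaled so their variances equal `qtl_share` and
#' `chem_share` (which should sum to 1).
#'
#' Latent chemistry scores returned alongside are correlated `chem_cor` with
#' the chemistry component; they, not the markers or group labels, drive the
#' simulated spectra, which is what makes spectral prediction
#' structure-robust here.
#'
#' @param pop population as returned by [simulate_population()]
#' With `tagged_fraction < 1`, only that fraction of the causal loci are
#' genotyped markers; the rest are hidden loci drawn from the same
#' population hierarchy (subgroup and, if present, family frequencies).
#' Hidden causal variation is visible to marker-based prediction only
#' through genomic relationship, emulating imperfect marker-QTL linkage on
#' real arrays without simulating linkage disequilibrium explicitly.
#'
#' @param n_qtl number of causal loci
#' @param qtl_share variance share of the QTL component, on the pooled
#'   within-subgroup basis
#' @param chem_share variance share of the chemistry component
#' @param delta_sd subgroup offset SD in within-group genetic SD units
#' @param chem_cor correlation between latent chemistry and the chemistry
#'   component of the genetic value
#' @param n_latent number of latent chemistry components (the first carries
#'   trait signal, the rest are nuisance variation)
#' @param tagged_fraction fraction of causal loci that are genotyped markers
#' @param seed integer seed
#' @return list with `g` (named genetic values), `chem` (n x n_latent latent
#'   scores), and `truth` (components, QTL indices and effects)
#' @export
simulate_trait <- function(pop, n_qtl = 100L, qtl_share = 0.5,
                           chem_share = 0.5, delta_sd = 0,
                           chem_cor = 0.9, n_latent = 2L,
                           tagged_fraction = 1, seed = 1L) {
  stopifnot(qtl_share >= 0, chem_share >= 0,
            delta_sd >= 0, chem_cor >= -1, chem_cor <= 1,
            tagged_fraction >= 0, tagged_fraction <= 1)
  set.seed(seed)
  n <- n_genotypes(pop$geno)
  dos <- dosages(pop$geno, impute = TRUE)        # genotypes x markers, no NA
  n_tagged <- round(tagged_fraction * n_qtl)
  n_hidden <- n_qtl - n_tagged
  stopifnot(n_tagged <= n_markers(pop$geno))
  qtl_idx <- if (n_tagged > 0) sample.int(ncol(dos), n_tagged) else integer(0)
  hidden <- if (n_hidden > 0) .draw_hidden_loci(pop, n_hidden) else
    matrix(0, n, 0)
  Q <- cbind(dos[, qtl_idx, drop = FALSE], hidden)
  eff <- stats::rnorm(n_qtl)
  g_mark <- drop(Q %*% eff)
  # scale the QTL component on the pooled within-subgroup variance, the same
  # basis on which the heritability target, the chemistry share and delta
  # are defined; its between-group part then rides on top, as genomic
  # differentiation does
  sub0 <- pop$groups$subgroup
  within_sd_mark <- stats::sd(g_mark - stats::ave(g_mark, sub0))
  if (within_sd_mark > 0 && qtl_share > 0) {
    sc <- sqrt(qtl_share) / within_sd_mark
    g_mark <- (g_mark - mean(g_mark)) * sc
    eff <- eff * sc
  } else {
    g_mark <- rep(0, n)
    eff <- rep(0, n_qtl)
  }
  g_chem <- if (chem_share > 0) stats::rnorm(n, sd = sqrt(chem_share)) else rep(0, n)
  within_sd <- sqrt(qtl_share + chem_share)
  sub <- pop$groups$subgroup
  offsets <- stats::rnorm(length(unique(sub)))
  if (stats::sd(offsets) > 0 && delta_sd > 0) {
    offsets <- (offsets - mean(offsets)) / stats::sd(offsets) * delta_sd * within_sd
  } else offsets <- offsets * 0
  names(offsets) <- unique(sub)
  g_delta <- offsets[sub]
  g <- g_mark + g_chem + g_delta
  names(g) <- pop$groups$genotype

  chem <- matrix(stats::rnorm(n * n_latent), n, n_latent,
                 dimnames = list(pop$groups$genotype,
                                 paste0("C", seq_len(n_latent))))
  if (chem_share > 0) {
    z <- (g_chem - mean(g_chem)) / stats::sd(g_chem)
    chem[, 1] <- chem_cor * z + sqrt(1 - chem_cor^2) * chem[, 1]
  }
  list(g = g, chem = chem,
       truth = list(g_mark = g_mark, g_chem = g_chem, g_delta = unname(g_delta),
                    qtl_idx = qtl_idx, n_hidden = n_hidden, qtl_effects = eff,
                    group_offsets = offsets,
                    qtl_share = qtl_share, chem_share = chem_share,
                    delta_sd = delta_sd, chem_cor = chem_cor, seed = seed))
}

# Draw dosages at non-genotyped causal loci from the same Balding-Nichols
# hierarchy as the markers (ancestral -> subgroup -> family frequencies),
# using the current RNG stream.
.draw_hidden_loci <- function(pop, n_loci) {
  sub <- pop$groups$subgroup
  fam <- pop$groups$family
  fst <- pop$truth$fst
  ffst <- pop$truth$family_fst %||% 0
  n <- length(sub)
  p_anc <- stats::runif(n_loci, 0.1, 0.9)
  a <- p_anc * (1 - fst) / fst
  b <- (1 - p_anc) * (1 - fst) / fst
  out <- matrix(0, n, n_loci)
  for (g in unique(sub)) {
    idx <- which(sub == g)
    p_g <- pmin(pmax(stats::rbeta(n_loci, a, b), 1e-6), 1 - 1e-6)
    if (ffst > 0) {
      for (f in unique(fam[idx])) {
        members <- idx[fam[idx] == f]
        af <- p_g * (1 - ffst) / ffst
        bf <- (1 - p_g) * (1 - ffst) / ffst
        p_f <- pmin(pmax(stats::rbeta(n_loci, af, bf), 1e-6), 1 - 1e-6)
        out[members, ] <- 2 * (matrix(stats::runif(length(members) * n_loci),
                                      length(members), n_loci, byrow = FALSE) <
                                 matrix(p_f, length(members), n_loci, byrow = TRUE))
      }
    } else {
      out[idx, ] <- 2 * (matrix(stats::runif(length(idx) * n_loci),
                                length(idx), n_loci) <
                           matrix(p_g, length(idx), n_loci, byrow = TRUE))
    }
  }
  out
}

#' Translate an entry-mean heritability target into plot variance components
#'
#' Given the genetic variance and the design (`ne` environments, `nr`
#' replicates), splits the non-genetic variance between genotype-by-environment
#' interaction and plot error at a fixed ratio so that
#' H2 = s2g / (s2g + s2gxe/ne + s2eps/(ne*nr)) equals `h2`.
#'
#' @param sigma2_g genetic variance
#' @param h2 target entry-mean heritability, in (0, 1)
#' @param ne,nr number of environments and replicates
#' @param gxe_fraction fraction of the H2 denominator's non-genetic part
#'   attributed to g-by-e (on the entry-mean scale)
#' @return named list of plot-level variance components
#' @export
vc_for_h2 <- function(sigma2_g, h2, ne = 3L, nr = 2L, gxe_fraction = 0.5) {
  stop_if_not_scalar_prob(h2, "h2")
  stopifnot(sigma2_g > 0, ne >= 1, nr >= 1)
  denom_extra <- sigma2_g * (1 - h2) / h2     # s2gxe/ne + s2eps/(ne*nr)
  list(sigma2_g = sigma2_g,
       sigma2_gxe = denom_extra * gxe_fraction * ne,
       sigma2_eps = denom_extra * (1 - gxe_fraction) * ne * nr)
}

#' Simulate plot-level phenotypes under the standard multi-environment model
#'
#' Generates y_ijkl = mu + g_i + e_j + (ge)_ij + r_jk + b_jkl + eps_ijkl with
#' independent normal effects at the supplied variances: environment main
#' effects, genotype-by-environment interactions, replicates nested in
#' environments, incomplete blocks nested in replicates, and homogeneous plot
#' error. Genotypes are assigned to blocks at random within each replicate
#' (an incomplete-block layout).
#'
#' @param g named vector of true genetic values
#' @param ne,nr number of environments and replicates per environment
#' @param n_blocks number of incomplete blocks per replicate
#' @param mu overall mean
#' @param vc named list/vector with sigma2_env, sigma2_gxe, sigma2_rep,
#'   sigma2_block, sigma2_eps (missing entries default to 0)
#' @param trait name of the trait column to create
#' @param seed integer seed
#' @return a `plot_table` data frame with one row per plot
#' @export
simulate_plots <- function(g, ne = 3L, nr = 2L, n_blocks = 10L, mu = 0,
                           vc = list(sigma2_env = 1, sigma2_gxe = 0.5,
                                     sigma2_rep = 0.1, sigma2_block = 0.1,
                                     sigma2_eps = 1),
                           trait = "trait", seed = 1L) {
  if (ne < 1 || nr < 1) stop("design error: ne and nr must be >= 1", call. = FALSE)
  v <- function(nm) { x <- vc[[nm]] %||% 0; stopifnot(x >= 0); x }
  set.seed(seed)
  n <- length(g)
  ids <- names(g) %||% paste0("g", seq_len(n))
  envs <- paste0("ENV", seq_len(ne))
  e_j  <- stats::rnorm(ne, sd = sqrt(v("sigma2_env")))
  ge   <- matrix(stats::rnorm(n * ne, sd = sqrt(v("sigma2_gxe"))), n, ne)
  rows <- vector("list", ne * nr)
  k <- 0L
  for (j in seq_len(ne)) {
    r_jk <- stats::rnorm(nr, sd = sqrt(v("sigma2_rep")))
    for (r in seq_len(nr)) {
      k <- k + 1L
      block <- ((sample.int(n) - 1L) %% n_blocks) + 1L
      b_jkl <- stats::rnorm(n_blocks, sd = sqrt(v("sigma2_block")))
      y <- mu + g + e_j[j] + ge[, j] + r_jk[r] + b_jkl[block] +
        stats::rnorm(n, sd = sqrt(v("sigma2_eps")))
      rows[[k]] <- data.frame(genotype = ids, environment = envs[j],
                              replicate = r, block = block, y = unname(y),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "y"] <- trait
  plot_table(out)
}

#' Simulate plot-level NIR reflectance spectra
#'
#' Each plot spectrum is a smooth shared baseline plus Gaussian absorption
#' bands whose heights are linear in the genotype's latent chemistry scores,
#' plus a smooth environment-specific shift and iid measurement noise (the
#' noise SD is meant as the residual after averaging repeated cup
#' measurements). Group labels never enter the spectra directly, so spectra
#' cluster by chemistry, not by ancestry.
#'
#' @param chem n x q matrix of latent chemistry scores (rownames = genotypes)
#' @param wl_range integer length-2 wavelength range in nm (unit step grid)
#' @param n_bands number of Gaussian absorption bands
#' @param band_sd band width in nm
#' @param loading_scale typical reflectance amplitude per latent SD
#' @param env_effect_sd SD of smooth environment-level spectral shifts
#' @param noise_sd iid per-wavelength noise SD
#' @param ne,nr environments and replicates (must match the trait design when
#'   both feed the same mixed-model machinery)
#' @param loadings optional n_bands x q loading matrix; random if NULL
#' @param seed integer seed
#' @return a `spectra_table`
#' @export
simulate_spectra <- function(chem, wl_range = c(1250L, 2400L),
                             n_bands = 8L, band_sd = 15,
                             loading_scale = 0.02,
                             env_effect_sd = 0.005, noise_sd = 0.002,
                             ne = 3L, nr = 2L, loadings = NULL, seed = 1L) {
  chem <- as.matrix(chem)
  n <- nrow(chem); q <- ncol(chem)
  wl <- seq.int(wl_range[1], wl_range[2])
  set.seed(seed)
  # spread bands across the usable window (evenly + jitter) so different
  # latent components keep distinguishable wavelength profiles
  lo <- wl_range[1] + 1.5 * band_sd
  hi <- wl_range[2] - 1.5 * band_sd
  if (hi < lo) stop("config error: band centers outside the wavelength grid",
                    call. = FALSE)
  centers <- seq(lo, hi, length.out = n_bands) +
    stats::runif(n_bands, -0.2, 0.2) * (hi - lo) / max(1L, n_bands - 1L)
  centers <- sort(pmin(pmax(centers, lo), hi))
  if (any(centers < min(wl)) || any(centers > max(wl)))
    stop("config error: band centers outside the wavelength grid", call. = FALSE)
  if (is.null(loadings)) {
    loadings <- matrix(stats::rnorm(n_bands * q, sd = loading_scale), n_bands, q)
  }
  stopifnot(nrow(loadings) == n_bands, ncol(loadings) == q)
  x01 <- (wl - wl_range[1]) / max(1L, diff(wl_range))
  baseline <- 0.55 + 0.1 * sin(2 * pi * x01) + 0.05 * x01
  bands <- sapply(centers, function(cc) exp(-0.5 * ((wl - cc) / band_sd)^2))
  # n x n_wl genotype signal
  signal <- (chem %*% t(loadings)) %*% t(bands)
  ids <- rownames(chem) %||% paste0("g", seq_len(n))
  meta <- expand.grid(replicate = seq_len(nr), environment = paste0("ENV", seq_len(ne)),
                      genotype = ids, stringsAsFactors = FALSE)[, c(3, 2, 1)]
  vals <- matrix(0, nrow(meta), length(wl))
  env_shift <- sapply(seq_len(ne), function(j) {
    co <- stats::rnorm(3, sd = env_effect_sd)
    co[1] + co[2] * x01 + co[3] * sin(2 * pi * x01 + stats::runif(1, 0, 2 * pi))
  })  # n_wl x ne
  env_idx <- as.integer(factor(meta$environment, levels = paste0("ENV", seq_len(ne))))
  gi <- match(meta$genotype, ids)
  for (r in seq_len(nrow(meta))) {
    vals[r, ] <- baseline + signal[gi[r], ] + env_shift[, env_idx[r]] +
      stats::rnorm(length(wl), sd = noise_sd)
  }
  spectra_table(wavelengths = wl, meta = meta, values = vals,
                info = list(centers = centers, band_sd = band_sd,
                            loadings = loadings, baseline = baseline,
                            seed = seed))
}

#' Hudson-type FST estimate between two groups from dosage data
#'
#' Method-of-moments estimator averaged over loci:
#' sum_l [ (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1) ] /
#' sum_l [ p1(1-p2) + p2(1-p1) ]. Used as an independent check that the
#' Balding-Nichols generator realises its nominal divergence.
#'
#' @param dos1,dos2 genotype x marker dosage matrices (0..2) for two groups
#' @return scalar FST estimate
#' @export
fst_hudson <- function(dos1, dos2) {
  p1 <- colMeans(dos1, na.rm = TRUE) / 2
  p2 <- colMeans(dos2, na.rm = TRUE) / 2
  n1 <- nrow(dos1); n2 <- nrow(dos2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
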