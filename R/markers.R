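## Stepwise marker quality control: overall filters (all-missing, missing
## fraction, heterozygosity, monomorphism), per-group filters (all-missing,
## monomorphic, MAF, het-to-missing recoding), naive mean imputation, and
## the final MAF-filter-and-merge into one predictor matrix. All thresholds
## are strict inequalities (> / <) as is conventional in SNP-array QC.

.marker_stats <- function(calls) {
  n <- ncol(calls)
  n_obs <- rowSums(!is.na(calls))
  list(n_obs = n_obs,
       miss_frac = 1 - n_obs / n,
       het_frac = ifelse(n_obs > 0, rowSums(calls == 1L, na.rm = TRUE) / n_obs, 0))
}

# monomorphic = a single allele among non-missing calls; a heterozygous call
# carries both alleles, so het-only markers count as polymorphic
.is_monomorphic <- function(calls) {
  has_ref <- rowSums(calls != 2L, na.rm = TRUE) > 0   # 0 or 1 present
  has_alt <- rowSums(calls != 0L, na.rm = TRUE) > 0   # 1 or 2 present
  n_obs <- rowSums(!is.na(calls))
  n_obs > 0 & !(has_ref & has_alt)
}

.maf <- function(calls) {
  n_obs <- rowSums(!is.na(calls))
  p <- rowSums(calls, na.rm = TRUE) / (2 * n_obs)
  ifelse(n_obs > 0, pmin(p, 1 - p), NA_real_)
}

#' Overall marker quality control
#'
#' Removes, in order: markers consisting only of missing values; markers
#' with missing fraction strictly above `miss_thr`; markers with
#' heterozygous fraction (over non-missing calls) strictly above `het_thr`;
#' and monomorphic markers among the remaining. Each step's detected and
#' newly removed counts are reported. Afterwards every genotype is checked
#' against the complementary criteria (> `geno_miss_thr` missing or
#' > `geno_het_thr` heterozygous over the surviving markers); failing
#' genotypes are flagged in the report but never silently dropped.
#'
#' @param gm a `geno_matrix`
#' @param miss_thr marker missing-fraction threshold (strict)
#' @param het_thr marker heterozygosity threshold (strict)
#' @param geno_miss_thr,geno_het_thr genotype-level check thresholds
#' @return list with `geno` (filtered `geno_matrix`) and `report`
#'   (a `qc_report`)
#' @export
qc_overall <- function(gm, miss_thr = 0.50, het_thr = 0.05,
                       geno_miss_thr = 0.20, geno_het_thr = 0.05) {
  calls <- gm$calls
  steps <- list()
  note <- function(name, detected, removed_idx) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = name, detected = detected, removed = length(removed_idx),
      remaining = nrow(calls) - length(removed_idx))
    if (length(removed_idx)) calls <<- calls[-removed_idx, , drop = FALSE]
  }
  st <- .marker_stats(calls)
  all_missing <- which(st$n_obs == 0L)
  note("all_missing", length(all_missing), all_missing)

  st <- .marker_stats(calls)
  high_miss <- which(st$miss_frac > miss_thr)
  note("missing_fraction", length(high_miss), high_miss)

  st <- .marker_stats(calls)
  high_het <- which(st$het_frac > het_thr)
  note("heterozygosity", length(high_het), high_het)

  mono <- which(.is_monomorphic(calls))
  note("monomorphic", length(mono), mono)

  # genotype-level complementary check over surviving markers
  flagged <- character(0)
  if (nrow(calls) > 0) {
    g_miss <- colMeans(is.na(calls))
    n_obs_g <- colSums(!is.na(calls))
    g_het <- ifelse(n_obs_g > 0, colSums(calls == 1L, na.rm = TRUE) / n_obs_g, 0)
    flagged <- colnames(calls)[g_miss > geno_miss_thr | g_het > geno_het_thr]
  }
  if (length(flagged)) {
    warning(sprintf("%d genotype(s) exceed missing/het criteria: %s",
                    length(flagged), paste(utils::head(flagged, 5), collapse = ", ")))
  }
  report <- qc_report(do.call(rbind, steps),
                      thresholds = list(miss_thr = miss_thr, het_thr = het_thr,
                                        geno_miss_thr = geno_miss_thr,
                                        geno_het_thr = geno_het_thr),
                      flagged_genotypes = flagged,
                      n_input = n_markers(gm))
  list(geno = geno_matrix(calls, chrom = NULL, pos = NULL), report = report)
}

#' Construct a marker-QC report
#'
#' @param steps data frame with step, detected, removed, remaining
#' @param thresholds named list of thresholds used
#' @param flagged_genotypes genotypes failing the individual-level check
#' @param n_input marker count before the first step
#' @return a `qc_report`
#' @export
qc_report <- function(steps, thresholds = list(), flagged_genotypes = character(0),
                      n_input = NA_integer_) {
  stopifnot(all(c("step", "detected", "removed", "remaining") %in% names(steps)))
  if (any(diff(steps$remaining) > 0)) {
    stop("qc_report: remaining counts must be non-increasing", call. = FALSE)
  }
  if (!is.na(n_input) && utils::tail(steps$remaining, 1) != n_input - sum(steps$removed)) {
    stop("qc_report: removed counts are not additive", call. = FALSE)
  }
  structure(list(steps = steps, thresholds = thresholds,
                 flagged_genotypes = flagged_genotypes, n_input = n_input),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d markers in\n", x$n_input))
  print(x$steps, row.names = FALSE)
  if (length(x$flagged_genotypes)) {
    cat("flagged genotypes:", paste(x$flagged_genotypes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-group marker quality control
#'
#' Splits the genotype matrix by the grouping column, recodes heterozygous
#' calls to missing within each group (het information is kept as missing,
#' not discarded as a marker), then removes per group: markers that are now
#' all-missing, monomorphic markers, and markers with minor allele frequency
#' strictly below `maf_thr` (computed over non-missing calls). Marker sets
#' may differ between groups afterwards.
#'
#' @param gm a `geno_matrix` (typically the [qc_overall()] output)
#' @param group_map data frame with genotype and the grouping column
#' @param maf_thr strict MAF threshold
#' @param group_col grouping column name (default "major_group")
#' @return named list of per-group `geno_matrix` objects
#' @export
qc_per_group <- function(gm, group_map, maf_thr = 0.03, group_col = "major_group") {
  grp <- stats::setNames(group_map[[group_col]], group_map$genotype)
  out <- list()
  for (g in unique(grp)) {
    ids <- intersect(colnames(gm$calls), names(grp)[grp == g])
    if (!length(ids)) stop(sprintf("empty group '%s'", g), call. = FALSE)
    calls <- gm$calls[, ids, drop = FALSE]
    calls[calls == 1L] <- NA_integer_
    st <- .marker_stats(calls)
    keep <- st$n_obs > 0L
    keep <- keep & !.is_monomorphic(calls)
    maf <- .maf(calls)
    keep <- keep & !is.na(maf) & maf >= maf_thr
    out[[g]] <- geno_matrix(calls[keep, , drop = FALSE])
  }
  out
}

#' Naive within-group mean imputation and numeric coding
#'
#' Codes calls as dosages (hom ref = 0, het = 1, hom alt = 2) and replaces
#' each missing value by the within-group marker mean dosage (non-integer
#' dosages allowed). A marker missing for an entire group cannot occur after
#' [qc_per_group()] and raises an assertion failure.
#'
#' @param group_matrices named list of per-group `geno_matrix` objects
#' @return named list of genotypes x markers numeric dosage matrices with no
#'   missing values (attribute `provenance` = "genomic")
#' @export
impute_naive <- function(group_matrices) {
  lapply(group_matrices, function(gm) {
    d <- dosages(gm, impute = FALSE)
    if (any(colSums(!is.na(d)) == 0L)) {
      stop("assertion failure: marker with no observed calls in a group", call. = FALSE)
    }
    d <- dosages(gm, impute = TRUE)
    attr(d, "provenance") <- "genomic"
    d
  })
}

#' Final MAF filter and merge of per-group dosage matrices
#'
#' Removes, per group, markers with MAF (from mean imputed dosage) strictly
#' below `maf_thr`, then merges the groups on the intersection of their
#' surviving marker sets into one genotypes x markers matrix.
#'
#' @param group_dosages named list of imputed per-group dosage matrices
#' @param maf_thr strict MAF threshold
#' @return genotypes x markers numeric matrix (attribute `provenance` =
#'   "genomic"); errors if the intersection is empty
#' @export
maf_filter_and_merge <- function(group_dosages, maf_thr = 0.05) {
  filtered <- lapply(group_dosages, function(d) {
    p <- colMeans(d) / 2
    d[, pmin(p, 1 - p) >= maf_thr, drop = FALSE]
  })
  common <- Reduce(intersect, lapply(filtered, colnames))
  if (!length(common)) {
    counts <- vapply(filtered, ncol, integer(1))
    stop(sprintf("no markers shared by all groups after MAF filter (survivors: %s)",
                 paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")),
         call. = FALSE)
  }
  merged <- do.call(rbind, lapply(filtered, function(d) d[, common, drop = FALSE]))
  attr(merged, "provenance") <- "genomic"
  merged
}

#' Run the complete marker pipeline
#'
#' [qc_overall()], [qc_per_group()], [impute_naive()] and
#' [maf_filter_and_merge()] chained with their default thresholds.
#'
#' @param gm a `geno_matrix`
#' @param group_map group map data frame
#' @param group_col grouping column used for the per-group stages
#' @return list with `dosage` (merged predictor matrix), `report` (overall
#'   QC report) and `per_group` (per-group marker counts)
#' @export
marker_pipeline <- function(gm, group_map, group_col = "major_group") {
  ov <- qc_overall(gm)
  per <- qc_per_group(ov$geno, group_map, group_col = group_col)
  imp <- impute_naive(per)
  merged <- maf_filter_and_merge(imp)
  list(dosage = merged, report = ov$report,
       per_group = vapply(per, n_markers, integer(1)))
}
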