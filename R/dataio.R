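## Data containers and text I/O: plot tables, genotype matrices (matrix TSV,
## HapMap, VCF), plot-level spectra tables, and group maps. Tab-separated
## text with a header is the canonical on-disk dialect; all readers validate
## on ingest and report what they kept.

# ---- genotype matrix ---------------------------------------------------

#' Construct a genotype matrix
#'
#' Calls are stored markers x genotypes as integers 0 (hom reference),
#' 1 (heterozygous), 2 (hom alternate) with NA for missing. Marker ids
#' (rownames) must be unique.
#'
#' @param calls integer matrix, markers in rows, genotypes in columns
#' @param chrom,pos optional per-marker metadata (1-based positions; carried,
#'   never used in computation)
#' @return an object of class `geno_matrix`
#' @export
geno_matrix <- function(calls, chrom = NULL, pos = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("call alphabet violation: values must be 0/1/2/NA", call. = FALSE)
  if (is.null(dimnames(calls))) dimnames(calls) <- list(NULL, NULL)
  if (is.null(rownames(calls))) rownames(calls) <- paste0("M", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("G", seq_len(ncol(calls)))
  if (anyDuplicated(rownames(calls))) stop("marker ids must be unique", call. = FALSE)
  structure(list(calls = calls, chrom = chrom, pos = pos), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d markers x %d genotypes (%.1f%% missing, %.1f%% het)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls)),
              100 * mean(x$calls == 1L, na.rm = TRUE)))
  invisible(x)
}

#' Number of markers / genotypes in a genotype matrix
#' @param gm a `geno_matrix`
#' @return integer count
#' @export
n_markers <- function(gm) nrow(gm$calls)

#' @rdname n_markers
#' @export
n_genotypes <- function(gm) ncol(gm$calls)

#' Numeric dosage view of a genotype matrix
#'
#' @param gm a `geno_matrix`
#' @param impute replace missing calls by the marker mean dosage?
#' @return genotypes x markers numeric matrix (counted-allele dosage 0..2)
#' @export
dosages <- function(gm, impute = FALSE) {
  d <- t(gm$calls) * 1.0
  if (impute && anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  d
}

.normalize_calls <- function(x) {
  # accepted missing symbols: "NN", "NA", "./.", "", "."
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("0")] <- 0L
  out[x %in% c("1")] <- 1L
  out[x %in% c("2")] <- 2L
  known <- x %in% c("0", "1", "2", "NN", "NA", "./.", "", ".", "N")
  if (!all(known)) {
    stop(sprintf("unknown call symbol(s): %s",
                 paste(utils::head(unique(x[!known]), 5), collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Read a genotype table from text
#'
#' Dialects: `matrix-tsv` (canonical; columns `marker_id`, optional `chrom`
#' and `pos`, then one column per genotype, calls 0/1/2 with NA-like symbols
#' for missing), `hapmap` (the 11 standard leading columns, letter-pair
#' calls), and `vcf` (read-only, GT field only; requires the vcfR package).
#' If a matrix-tsv file has genotypes in rows (first column `genotype_id`),
#' orientation is sniffed and the matrix transposed, with a message.
#'
#' @param path file path
#' @param dialect one of "matrix-tsv", "hapmap", "vcf"
#' @return a `geno_matrix`
#' @export
read_genotype_table <- function(path, dialect = c("matrix-tsv", "hapmap", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  gm <- switch(dialect,
               "matrix-tsv" = .read_geno_tsv(path),
               "hapmap" = .read_geno_hapmap(path),
               "vcf" = .read_geno_vcf(path))
  message(sprintf("read %d markers x %d genotypes from %s [%s]",
                  n_markers(gm), n_genotypes(gm), basename(path), dialect))
  gm
}

.read_fields <- function(path, comment = "") {
  lines <- readLines(path, warn = FALSE)
  if (nzchar(comment)) lines <- lines[!startsWith(lines, comment)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop(sprintf("parse error in %s: no data rows", path), call. = FALSE)
  strsplit(lines, "\t", fixed = TRUE)
}

.check_widths <- function(fields, path) {
  w <- lengths(fields)
  if (length(unique(w)) != 1L) {
    bad <- which(w != w[1])[1]
    stop(sprintf("dimension error in %s: line %d has %d fields, expected %d",
                 path, bad, w[bad], w[1]), call. = FALSE)
  }
}

.read_geno_tsv <- function(path) {
  fields <- .read_fields(path)
  .check_widths(fields, path)
  header <- fields[[1]]
  body <- do.call(rbind, fields[-1])
  if (identical(tolower(header[1]), "genotype_id")) {
    message("orientation sniff: genotypes in rows; transposing to markers x genotypes")
    ids <- body[, 1]
    m <- t(body[, -1, drop = FALSE])
    rownames(m) <- header[-1]
    colnames(m) <- ids
    calls <- apply(m, 2, .normalize_calls)
    rn <- rownames(m)
    calls <- matrix(as.integer(calls), nrow = nrow(m),
                    dimnames = list(rn, ids))
    return(geno_matrix(calls))
  }
  if (!identical(tolower(header[1]), "marker_id")) {
    stop(sprintf("parse error in %s: line 1 must start with 'marker_id' or 'genotype_id'",
                 path), call. = FALSE)
  }
  meta_cols <- intersect(c("chrom", "pos"), tolower(header))
  n_meta <- length(meta_cols)
  ids <- body[, 1]
  geno_ids <- header[-seq_len(1 + n_meta)]
  raw <- body[, -seq_len(1 + n_meta), drop = FALSE]
  calls <- matrix(.normalize_calls(raw), nrow = nrow(raw),
                  dimnames = list(ids, geno_ids))
  chrom <- if ("chrom" %in% meta_cols) body[, which(tolower(header) == "chrom")] else NULL
  pos <- if ("pos" %in% meta_cols) as.integer(body[, which(tolower(header) == "pos")]) else NULL
  geno_matrix(calls, chrom = chrom, pos = pos)
}

.HAPMAP_COLS <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                  "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

.read_geno_hapmap <- function(path) {
  fields <- .read_fields(path)
  .check_widths(fields, path)
  header <- fields[[1]]
  if (length(header) < 12L || !identical(header[1], "rs#")) {
    stop(sprintf("parse error in %s: line 1 is not a HapMap header (expected 'rs#' ...)",
                 path), call. = FALSE)
  }
  body <- do.call(rbind, fields[-1])
  ids <- body[, 1]
  alleles <- strsplit(body[, 2], "/", fixed = TRUE)
  geno_ids <- header[-(1:11)]
  raw <- body[, -(1:11), drop = FALSE]
  calls <- matrix(NA_integer_, nrow(raw), ncol(raw), dimnames = list(ids, geno_ids))
  for (i in seq_len(nrow(raw))) {
    ref <- alleles[[i]][1]; alt <- alleles[[i]][2]
    x <- raw[i, ]
    out <- rep(NA_integer_, length(x))
    out[x == paste0(ref, ref)] <- 0L
    out[x == paste0(alt, alt)] <- 2L
    out[x %in% c(paste0(ref, alt), paste0(alt, ref))] <- 1L
    known <- is.na(out)
    bad <- known & !(x %in% c("NN", "N", "--", ""))
    if (any(bad)) {
      stop(sprintf("unknown call symbol '%s' at marker %s in %s",
                   x[bad][1], ids[i], path), call. = FALSE)
    }
    calls[i, ] <- out
  }
  geno_matrix(calls, chrom = body[, 3], pos = suppressWarnings(as.integer(body[, 4])))
}

.read_geno_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  calls[gt %in% "0/0"] <- 0L
  calls[gt %in% c("0/1", "1/0")] <- 1L
  calls[gt %in% "1/1"] <- 2L
  fix <- vcfR::getFIX(v)
  rn <- fix[, "ID"]
  rn[is.na(rn) | rn == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(rn) | rn == "."]
  rownames(calls) <- rn
  geno_matrix(calls, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
}

#' Write a genotype matrix as canonical tab-separated text
#'
#' @param gm a `geno_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genotype_table <- function(gm, path) {
  m <- gm$calls
  out <- data.frame(marker_id = rownames(m), stringsAsFactors = FALSE)
  if (!is.null(gm$chrom)) {
    out$chrom <- gm$chrom
    out$pos <- gm$pos
  }
  out <- cbind(out, as.data.frame(m, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

# ---- plot table --------------------------------------------------------

#' Construct a plot-level phenotype table
#'
#' One row per field plot: genotype, environment (location-year), replicate,
#' block, then one column per trait. The key (genotype, environment,
#' replicate) must be unique.
#'
#' @param df data frame with the required design columns and >= 1 trait column
#' @return a `plot_table` (data frame subclass; trait names in
#'   `attr(, "traits")`)
#' @export
plot_table <- function(df) {
  req <- c("genotype", "environment", "replicate", "block")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  traits <- setdiff(names(df), req)
  if (!length(traits)) stop("schema error: no trait columns present", call. = FALSE)
  key <- paste(df$genotype, df$environment, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("integrity error: duplicated (genotype, environment, replicate) rows",
         call. = FALSE)
  }
  df$replicate <- as.integer(df$replicate)
  df$block <- as.integer(df$block)
  if (any(df$replicate < 1L) || any(df$block < 1L)) {
    stop("replicate and block must be integers >= 1", call. = FALSE)
  }
  structure(df, traits = traits, class = c("plot_table", "data.frame"))
}

#' List the trait columns of a plot table
#' @param plots a `plot_table`
#' @return character vector of trait names
#' @export
traits <- function(plots) attr(plots, "traits")

#' Read a plot-level phenotype table from tab-separated text
#'
#' Missing trait cells (empty or "NA") are preserved as missing, never zero.
#'
#' @param path file path
#' @return a `plot_table`
#' @export
read_plot_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), check.names = FALSE)
  pt <- plot_table(df)
  message(sprintf("read %d plots (%d trait%s) from %s; kept %d, rejected 0",
                  nrow(pt), length(traits(pt)),
                  if (length(traits(pt)) == 1) "" else "s",
                  basename(path), nrow(pt)))
  pt
}

#' Write a plot table as tab-separated text
#' @param plots a `plot_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_plot_table <- function(plots, path) {
  utils::write.table(as.data.frame(plots), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# ---- spectra table -----------------------------------------------------

#' Construct a plot-level spectra table
#'
#' @param wavelengths strictly increasing integer wavelength grid (nm)
#' @param meta data frame with genotype, environment, replicate (one row per
#'   plot, aligned with `values` rows)
#' @param values numeric plots x wavelengths reflectance matrix, finite
#' @param info free-form provenance list (processing steps append to it)
#' @return a `spectra_table`
#' @export
spectra_table <- function(wavelengths, meta, values, info = list()) {
  wavelengths <- as.integer(wavelengths)
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(wavelengths), nrow(values) == nrow(meta))
  if (!all(is.finite(values))) stop("reflectance values must be finite", call. = FALSE)
  req <- c("genotype", "environment", "replicate")
  if (!all(req %in% names(meta))) {
    stop("spectra metadata needs genotype, environment, replicate", call. = FALSE)
  }
  colnames(values) <- paste0("wl_", wavelengths)
  structure(list(wavelengths = wavelengths,
                 meta = as.data.frame(meta)[, req],
                 values = values, info = info),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d plots x %d wavelengths (%d-%d nm)\n",
              nrow(x$values), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Read a plot-level spectra table from tab-separated text
#'
#' Expects columns genotype, environment, replicate, then `wl_<nm>` columns.
#'
#' @param path file path
#' @return a `spectra_table`
#' @export
read_spectra_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  wl_cols <- grep("^wl_", names(df), value = TRUE)
  if (!length(wl_cols)) stop("schema error: no wl_<nm> columns found", call. = FALSE)
  wl <- as.integer(sub("^wl_", "", wl_cols))
  spectra_table(wl, df[c("genotype", "environment", "replicate")],
                as.matrix(df[wl_cols]))
}

#' Write a spectra table as tab-separated text
#' @param spectra a `spectra_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_spectra_table <- function(spectra, path) {
  df <- cbind(spectra$meta, as.data.frame(spectra$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- group map ---------------------------------------------------------

#' Read a genotype-to-group map from tab-separated text
#'
#' Columns: genotype, subgroup (e.g. ED, EF, CG, GB, RT, SM, SF, WA) and
#' optionally major_group (derived from the subgroup when absent).
#'
#' @param path file path
#' @return data frame with genotype, subgroup, major_group
#' @export
read_group_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("genotype", "subgroup") %in% names(df))) {
    stop("schema error: group map needs genotype and subgroup columns", call. = FALSE)
  }
  if (!"major_group" %in% names(df)) df$major_group <- major_group_of(df$subgroup)
  df[c("genotype", "subgroup", "major_group")]
}

#' Write a group map as tab-separated text
#' @param groups group map data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_group_map <- function(groups, path) {
  utils::write.table(groups, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
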