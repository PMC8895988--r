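## NIRS processing: edge trimming, Savitzky-Golay smoothing / derivatives
## built from first principles (local least-squares polynomial convolution),
## per-wavelength mixed-model BLUEs and heritabilities, and column
## standardization into the spectral predictor matrix. The pipeline order is
## trim -> smooth/derive -> per-wavelength BLUE -> standardize.

#' Savitzky-Golay convolution kernel
#'
#' Weights of the local least-squares polynomial filter: fitting a
#' polynomial of order `p` to `w` consecutive points and reading off the
#' `m`-th derivative at the center. Built from the normal equations of the
#' Vandermonde design; the weights reproduce the m-th derivative of any
#' polynomial of degree <= p exactly at the center point.
#'
#' @param w window length in points (odd)
#' @param p polynomial order (< w)
#' @param m derivative order (<= p); 0 = smoothing
#' @return numeric weight vector of length `w` with attributes w, p, m
#' @export
sg_kernel <- function(w, p = 2L, m = 0L) {
  if (w %% 2L != 1L) stop("parameter error: window w must be odd", call. = FALSE)
  if (p >= w) stop("parameter error: polynomial order p must be < w", call. = FALSE)
  if (m > p) stop("parameter error: derivative order m must be <= p", call. = FALSE)
  h <- (w - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:p, `^`)
  # row m+1 of (A'A)^{-1} A' gives the m-th polynomial coefficient at center
  coef_row <- solve(crossprod(A), t(A))[m + 1L, ]
  weights <- coef_row * factorial(m)
  structure(weights, w = w, p = p, m = m)
}

#' Apply a Savitzky-Golay filter (valid convolution)
#'
#' Points whose window would fall outside the series are dropped, so a
#' series of length n shrinks to n - w + 1 (consistent with deliberate edge
#' trimming rather than padding).
#'
#' @param x numeric vector, or a matrix filtered row-wise
#' @param w window length (odd), `p` polynomial order, `m` derivative order
#' @param p,m see [sg_kernel()]
#' @return filtered vector/matrix with attribute `offset` = (w-1)/2, the
#'   number of points dropped at each end
#' @export
savitzky_golay <- function(x, w = 11L, p = 2L, m = 1L) {
  k <- sg_kernel(w, p, m)
  if (is.matrix(x)) {
    if (ncol(x) < w) stop("series length must be >= w", call. = FALSE)
    nout <- ncol(x) - w + 1L
    out <- matrix(0, nrow(x), nout)
    for (j in seq_len(nout)) {
      out[, j] <- x[, j:(j + w - 1L), drop = FALSE] %*% k
    }
  } else {
    if (length(x) < w) stop("series length must be >= w", call. = FALSE)
    out <- as.numeric(stats::filter(x, rev(k), sides = 2))
    out <- out[!is.na(out)]
  }
  structure(out, offset = (w - 1L) %/% 2L)
}

#' Trim the edges of a spectra table
#'
#' Restricts the wavelength grid to `[min + nm, max - nm]` to exclude
#' detector border effects.
#'
#' @param spectra a `spectra_table` on a unit-step grid
#' @param nm nanometers to cut at each side
#' @return trimmed `spectra_table`
#' @export
trim_edges <- function(spectra, nm = 18L) {
  wl <- spectra$wavelengths
  if (any(diff(wl) != 1L)) stop("trim_edges expects a 1 nm step grid", call. = FALSE)
  if (2L * nm >= length(wl)) {
    stop("trim exceeds half the wavelength grid", call. = FALSE)
  }
  keep <- wl >= min(wl) + nm & wl <= max(wl) - nm
  info <- spectra$info
  info$trimmed_nm <- nm
  spectra_table(wl[keep], spectra$meta, spectra$values[, keep, drop = FALSE], info)
}

#' Savitzky-Golay smoothing / derivative of every plot spectrum
#'
#' Filters each plot's spectrum with the same kernel; the retained grid
#' shrinks by (w-1)/2 points at each end.
#'
#' @param spectra a `spectra_table`
#' @param w,p,m kernel parameters, see [sg_kernel()]
#' @return processed `spectra_table` (kernel recorded in `$info`)
#' @export
sg_process <- function(spectra, w = 11L, p = 2L, m = 1L) {
  vals <- savitzky_golay(spectra$values, w, p, m)
  h <- attr(vals, "offset")
  wl <- spectra$wavelengths[(h + 1L):(length(spectra$wavelengths) - h)]
  info <- spectra$info
  info$sg <- list(w = w, p = p, m = m)
  spectra_table(wl, spectra$meta, vals, info)
}

#' Per-wavelength BLUEs and heritabilities from plot-level spectra
#'
#' Treats each wavelength as a trait and applies the multi-environment plot
#' model independently: genotype-fixed fits yield one BLUE per genotype per
#' wavelength; all-random fits (optional) yield a per-wavelength entry-mean
#' heritability. With a single environment or single replicate the
#' interaction/error split is inestimable: BLUEs are still returned and the
#' heritabilities come back as NA with a warning.
#'
#' @param spectra processed plot-level `spectra_table`
#' @param h2 also fit the all-random model per wavelength?
#' @return list with `blues` (genotypes x wavelengths matrix, class
#'   `spectral_blue_matrix` via attributes: wavelengths, provenance
#'   "phenomic", standardized FALSE) and `h2` (named numeric or NULL)
#' @export
wavelength_blues <- function(spectra, h2 = FALSE) {
  if (!inherits(spectra, "spectra_table")) {
    stop("wavelength_blues expects plot-level spectra (a spectra_table); ",
         "standardization comes after this step", call. = FALSE)
  }
  meta <- spectra$meta
  nwl <- length(spectra$wavelengths)
  ids <- sort(unique(meta$genotype))
  blues <- matrix(NA_real_, length(ids), nwl,
                  dimnames = list(ids, colnames(spectra$values)))
  h2v <- if (h2) stats::setNames(rep(NA_real_, nwl), colnames(spectra$values))
  degenerate <- FALSE
  for (j in seq_len(nwl)) {
    df <- data.frame(meta, block = 1L, y = spectra$values[, j])
    names(df)[names(df) == "y"] <- "wl"
    pt <- plot_table(df)
    fit <- tryCatch(fit_plot_model(pt, "wl", genotype_fixed = TRUE,
                                   vc_method = "random"),
                    error = function(e) {
                      stop(sprintf("wavelength %d nm: %s",
                                   spectra$wavelengths[j], conditionMessage(e)),
                           call. = FALSE)
                    })
    blues[names(fit$blues), j] <- fit$blues
    if (h2) {
      fr <- fit_plot_model(pt, "wl", genotype_fixed = FALSE)
      if (is.na(fr$vc$sigma2_gxe) || fr$vc$ne < 2L) {
        degenerate <- TRUE
      } else {
        h2v[j] <- heritability(fr$vc)
      }
    }
  }
  if (degenerate) {
    warning("heritability inestimable for this design (single environment ",
            "or replicate); BLUEs returned, h2 set to NA")
  }
  attr(blues, "wavelengths") <- spectra$wavelengths
  attr(blues, "provenance") <- "phenomic"
  attr(blues, "standardized") <- FALSE
  list(blues = blues, h2 = h2v)
}

#' Center and scale the columns of a predictor matrix
#'
#' Column-wise zero mean and unit sample variance; constant columns are
#' dropped with a warning. Idempotent up to floating-point tolerance.
#'
#' @param m numeric matrix with no missing values
#' @return standardized matrix (attribute `standardized` = TRUE; dropped
#'   column count in attribute `n_dropped`)
#' @export
standardize_columns <- function(m) {
  stopifnot(is.matrix(m), !anyNA(m))
  sds <- apply(m, 2, stats::sd)
  drop <- sds == 0
  if (any(drop)) {
    warning(sprintf("dropped %d constant column(s)", sum(drop)))
    m <- m[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "wavelengths") <- attr(m, "wavelengths")
  attr(out, "provenance") <- attr(m, "provenance")
  attr(out, "standardized") <- TRUE
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Full NIRS preprocessing pipeline
#'
#' trim -> Savitzky-Golay (default first derivative) -> per-wavelength BLUE
#' -> column standardization, returning the phenomic predictor matrix.
#'
#' @param spectra raw plot-level `spectra_table`
#' @param trim_nm edge trim in nm
#' @param w,p,m Savitzky-Golay parameters
#' @param h2 also return per-wavelength heritabilities?
#' @return list with `predictors` (standardized genotype x wavelength
#'   matrix), `blues` (unstandardized) and `h2`
#' @export
nirs_pipeline <- function(spectra, trim_nm = 18L, w = 11L, p = 2L, m = 1L,
                          h2 = FALSE) {
  s <- trim_edges(spectra, trim_nm)
  s <- sg_process(s, w, p, m)
  wb <- wavelength_blues(s, h2 = h2)
  list(predictors = standardize_columns(wb$blues), blues = wb$blues, h2 = wb$h2)
}
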