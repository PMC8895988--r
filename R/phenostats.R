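## Plot-level mixed-model machinery: outlier screening, REML fits of the
## multi-environment model
##   y_ijkl = mu + g_i + e_j + (ge)_ij + r_jk + b_jkl + eps_ijkl,
## BLUE extraction with genotype fixed, and entry-mean heritabilities
## H2 = s2g / (s2g + s2gxe/ne + s2eps/(ne*nr)).

.model_data <- function(plots, trait) {
  if (!trait %in% traits(plots)) {
    stop(sprintf("unknown trait '%s'", trait), call. = FALSE)
  }
  d <- data.frame(y = plots[[trait]],
                  genotype = factor(plots$genotype),
                  environment = factor(plots$environment),
                  rep_in_env = factor(paste(plots$environment, plots$replicate, sep = ":")),
                  block_in_rep = factor(paste(plots$environment, plots$replicate,
                                              plots$block, sep = ":")))
  d$gxe <- factor(paste(d$genotype, d$environment, sep = ":"))
  d[!is.na(d$y), , drop = FALSE]
}

.random_terms <- function(d) {
  terms <- character(0)
  ne <- nlevels(droplevels(d$environment))
  if (ne > 1L) terms <- c(terms, "(1 | environment)", "(1 | gxe)")
  if (nlevels(droplevels(d$rep_in_env)) > ne) terms <- c(terms, "(1 | rep_in_env)")
  if (nlevels(droplevels(d$block_in_rep)) > nlevels(droplevels(d$rep_in_env))) {
    terms <- c(terms, "(1 | block_in_rep)")
  }
  terms
}

#' Fit the multi-environment plot model by REML
#'
#' Random factors: environment, genotype-by-environment, replicate nested in
#' environment, and block nested in replicate, with homogeneous plot error.
#' Genotype enters either as a random factor (`genotype_fixed = FALSE`; used
#' for variance components and heritability) or as a fixed factor
#' (`genotype_fixed = TRUE`; yields best linear unbiased estimates, BLUEs,
#' one per genotype). Terms that are not estimable from the design at hand
#' (single environment, single replicate, one block per replicate) are
#' dropped and recorded in the fit.
#'
#' In BLUE mode the variance components are estimated either by a full
#' genotype-fixed REML fit (`vc_method = "reml"`, the default) or taken from
#' the fast all-random fit and plugged into an exact sparse
#' mixed-model-equation GLS solve (`vc_method = "random"`). The latter is
#' used for the per-wavelength spectral fits, where thousands of responses
#' share one design; both give the arithmetic genotype means exactly in
#' balanced orthogonal designs and differ only through the variance
#' weighting under unbalancedness.
#'
#' @param plots a `plot_table`
#' @param trait trait column to model
#' @param genotype_fixed fit genotype as fixed (BLUE mode)?
#' @param vc_method variance-component source in BLUE mode ("reml" or
#'   "random"; see Details)
#' @return a `model_fit`: list with mode, mu, blues (BLUE mode only), vc
#'   (variance components incl. ne/nr), loglik, converged, dropped_terms
#' @export
fit_plot_model <- function(plots, trait, genotype_fixed = FALSE,
                           vc_method = c("reml", "random")) {
  vc_method <- match.arg(vc_method)
  if (genotype_fixed && vc_method == "random") {
    return(.fit_blues_mme(plots, trait))
  }
  d <- .model_data(plots, trait)
  if (nlevels(droplevels(d$genotype)) < 2L) stop("need >= 2 genotypes", call. = FALSE)
  d <- droplevels(d)
  ne <- nlevels(d$environment)
  nr_per_env <- tapply(as.character(d$rep_in_env), d$environment,
                       function(x) length(unique(x)))
  nr <- round(mean(nr_per_env))
  rterms <- .random_terms(d)
  dropped <- setdiff(c("(1 | environment)", "(1 | gxe)", "(1 | rep_in_env)",
                       "(1 | block_in_rep)"), rterms)

  if (genotype_fixed) {
    fixed <- "y ~ 0 + genotype"
  } else {
    fixed <- "y ~ 1"
    rterms <- c("(1 | genotype)", rterms)
  }

  if (length(rterms) == 0L) {
    # degenerate design: plain least squares
    fit <- stats::lm(stats::as.formula(fixed), data = d)
    vc <- list(sigma2_g = NA_real_, sigma2_gxe = NA_real_, sigma2_env = NA_real_,
               sigma2_rep = NA_real_, sigma2_block = NA_real_,
               sigma2_eps = stats::sigma(fit)^2, ne = ne, nr = nr)
    blues <- if (genotype_fixed) stats::setNames(stats::coef(fit),
                                                 sub("^genotype", "", names(stats::coef(fit))))
    return(structure(list(mode = if (genotype_fixed) "genotype-fixed" else "all-random",
                          mu = if (genotype_fixed) mean(blues) else unname(stats::coef(fit)[1]),
                          blues = blues, vc = vc,
                          loglik = as.numeric(stats::logLik(fit)),
                          converged = TRUE, dropped_terms = dropped,
                          residuals = stats::resid(fit), data = d, engine = "lm"),
                     class = "model_fit"))
  }

  form <- stats::as.formula(paste(fixed, "+", paste(rterms, collapse = " + ")))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE,
                            optimizer = "bobyqa",
                            optCtrl = list(rhoend = 1e-10))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = d, REML = TRUE, control = ctrl)))
  conv <- length(fit@optinfo$conv$lme4) == 0L
  vcl <- as.data.frame(lme4::VarCorr(fit))
  getvc <- function(grp) {
    v <- vcl$vcov[vcl$grp == grp]
    if (length(v)) v[1] else NA_real_
  }
  vc <- list(sigma2_g = if (genotype_fixed) NA_real_ else getvc("genotype"),
             sigma2_gxe = getvc("gxe"),
             sigma2_env = getvc("environment"),
             sigma2_rep = getvc("rep_in_env"),
             sigma2_block = getvc("block_in_rep"),
             sigma2_eps = getvc("Residual"),
             ne = ne, nr = nr)
  blues <- NULL
  mu <- NA_real_
  if (genotype_fixed) {
    b <- lme4::fixef(fit)
    blues <- stats::setNames(as.numeric(b), sub("^genotype", "", names(b)))
    mu <- mean(blues)
  } else {
    mu <- unname(lme4::fixef(fit)[1])
  }
  structure(list(mode = if (genotype_fixed) "genotype-fixed" else "all-random",
                 mu = mu, blues = blues, vc = vc,
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = conv, dropped_terms = dropped,
                 residuals = stats::resid(fit), data = d,
                 engine = "lmer", fit = fit),
            class = "model_fit")
}

# Exact GLS BLUEs at plugged-in variance components, solved through the
# sparse mixed-model equations [X'X, X'Z; Z'X, Z'Z + lambda_k I] — fast
# enough to repeat over thousands of wavelengths sharing one field design.
.fit_blues_mme <- function(plots, trait) {
  base <- fit_plot_model(plots, trait, genotype_fixed = FALSE)
  d <- base$data
  vc <- base$vc
  X <- Matrix::sparse.model.matrix(~ 0 + genotype, d)
  s2e <- max(vc$sigma2_eps, 1e-10 * stats::var(d$y))
  terms <- list(environment = vc$sigma2_env, gxe = vc$sigma2_gxe,
                rep_in_env = vc$sigma2_rep, block_in_rep = vc$sigma2_block)
  Zs <- list(); lam <- c()
  for (nm in names(terms)) {
    s2 <- terms[[nm]]
    if (is.na(s2) || s2 <= 0) next
    Zs[[nm]] <- Matrix::t(Matrix::fac2sparse(d[[nm]]))
    lam <- c(lam, rep(s2e / s2, nlevels(d[[nm]])))
  }
  W <- do.call(cbind, c(list(X), unname(Zs)))
  C <- Matrix::crossprod(W)
  if (length(lam)) {
    Matrix::diag(C)[-seq_len(ncol(X))] <- Matrix::diag(C)[-seq_len(ncol(X))] + lam
  }
  sol <- as.numeric(Matrix::solve(C, Matrix::crossprod(W, d$y)))
  blues <- stats::setNames(sol[seq_len(ncol(X))],
                           sub("^genotype", "", colnames(X)))
  vc$sigma2_g <- NA_real_
  structure(list(mode = "genotype-fixed", mu = mean(blues), blues = blues,
                 vc = vc, loglik = base$loglik, converged = base$converged,
                 dropped_terms = base$dropped_terms,
                 residuals = d$y - as.numeric(W %*% sol), data = d,
                 engine = "mme"),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> mode=%s, ne=%d, nr=%d, logLik=%.2f%s\n",
              x$mode, x$vc$ne, x$vc$nr, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  vc <- unlist(x$vc[c("sigma2_g", "sigma2_gxe", "sigma2_env",
                      "sigma2_rep", "sigma2_block", "sigma2_eps")])
  print(round(vc, 4))
  invisible(x)
}

#' Entry-mean broad-sense heritability from variance components
#'
#' H2 = s2g / (s2g + s2gxe/ne + s2eps/(ne*nr)). Inestimable interaction or
#' error components (NA) are treated as 0 with a warning, matching the
#' convention that what cannot be separated from the genotype signal in a
#' degenerate design is not charged against it.
#'
#' @param vc variance components (list with sigma2_g, sigma2_gxe, sigma2_eps,
#'   ne, nr), e.g. the `vc` element of an all-random [fit_plot_model()] fit
#' @param ne,nr overrides for the number of environments / replicates
#' @return heritability in `[0, 1]`
#' @export
heritability <- function(vc, ne = vc$ne, nr = vc$nr) {
  s2g <- vc$sigma2_g
  s2gxe <- vc$sigma2_gxe
  s2e <- vc$sigma2_eps
  if (is.na(s2g)) stop("sigma2_g is not available (genotype-fixed fit?)", call. = FALSE)
  if (is.na(s2gxe)) { warning("sigma2_gxe inestimable; treated as 0"); s2gxe <- 0 }
  if (is.na(s2e)) { warning("sigma2_eps inestimable; treated as 0"); s2e <- 0 }
  stopifnot(ne >= 1, nr >= 1, s2g >= 0, s2gxe >= 0, s2e >= 0)
  denom <- s2g + s2gxe / ne + s2e / (ne * nr)
  if (denom == 0) stop("heritability undefined: all variance components are zero",
                       call. = FALSE)
  s2g / denom
}

#' Per-group broad-sense heritabilities
#'
#' Fits the all-random plot model separately on each group's subset (for
#' disjoint groups this is equivalent to a dummy-variable fit with
#' group-specific genotypic and interaction variances) and applies the
#' entry-mean heritability formula with the group's own ne and nr. Groups
#' with fewer than two genotypes are skipped with a warning.
#'
#' @param plots a `plot_table`
#' @param trait trait column
#' @param group_map data frame with genotype and a grouping column
#' @param group_col name of the grouping column in `group_map`
#' @return named numeric vector of heritabilities (one per group)
#' @export
group_heritabilities <- function(plots, trait, group_map, group_col = "subgroup") {
  grp <- stats::setNames(group_map[[group_col]], group_map$genotype)
  out <- c()
  for (g in unique(grp)) {
    ids <- names(grp)[grp == g]
    sub <- plots[plots$genotype %in% ids, , drop = FALSE]
    if (length(unique(sub$genotype)) < 2L) {
      warning(sprintf("group '%s' has < 2 genotypes; skipped", g))
      next
    }
    f <- fit_plot_model(plot_table(as.data.frame(sub)), trait, genotype_fixed = FALSE)
    out[g] <- heritability(f$vc)
  }
  out
}

#' Outlier screening by Holm-corrected standardized residuals
#'
#' Fits the all-random plot model, standardizes the conditional residuals by
#' the rescaled median absolute deviation, converts them to two-sided normal
#' p-values, and applies the Holm step-down correction at family-wise level
#' `alpha`. Flagged plots are set to missing and the screen is re-run once on
#' the cleaned data.
#'
#' @param plots a `plot_table`
#' @param trait trait column
#' @param alpha family-wise error level in (0, 1)
#' @return list with `flags` (logical per input row), `plots` (cleaned table
#'   with flagged cells set to missing) and `n_flagged`
#' @export
detect_outliers <- function(plots, trait, alpha = 0.05) {
  stop_if_not_scalar_prob(alpha, "alpha")
  if (sum(!is.na(plots[[trait]])) < 10L) {
    stop("need >= 10 plots with non-missing trait values", call. = FALSE)
  }
  flags <- rep(FALSE, nrow(plots))
  current <- plots
  for (pass in 1:2) {
    fit <- fit_plot_model(current, trait, genotype_fixed = FALSE)
    res <- fit$residuals
    s <- stats::mad(res)
    if (s == 0) break
    p <- 2 * stats::pnorm(-abs(res / s))
    flag_fit <- stats::p.adjust(p, method = "holm") < alpha
    if (!any(flag_fit)) break
    obs_rows <- which(!is.na(current[[trait]]))
    hit <- obs_rows[flag_fit]
    flags[hit] <- TRUE
    current[[trait]][hit] <- NA
  }
  list(flags = flags, plots = current, n_flagged = sum(flags))
}

#' Compute per-genotype BLUEs for one or more traits
#'
#' For each trait, optionally screens outliers, then fits the plot model with
#' genotype fixed and extracts one best linear unbiased estimate per
#' genotype. In balanced orthogonal designs these equal the arithmetic
#' genotype means.
#'
#' @param plots a `plot_table`
#' @param traits trait columns (default: all)
#' @param screen_outliers apply [detect_outliers()] first?
#' @param alpha outlier family-wise level
#' @return genotype x trait data frame of BLUEs (rownames = genotype ids)
#' @export
compute_blues <- function(plots, traits = NULL, screen_outliers = FALSE,
                          alpha = 0.05) {
  trs <- traits %||% attr(plots, "traits")
  ids <- sort(unique(plots$genotype))
  out <- matrix(NA_real_, length(ids), length(trs),
                dimnames = list(ids, trs))
  for (tr in trs) {
    pl <- if (screen_outliers) detect_outliers(plots, tr, alpha)$plots else plots
    fit <- fit_plot_model(pl, tr, genotype_fixed = TRUE)
    out[names(fit$blues), tr] <- fit$blues
  }
  as.data.frame(out)
}
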