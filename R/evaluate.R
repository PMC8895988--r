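## Evaluation designs: k-fold cross-validation within groups (with
## proportional subgroup stratification), among-group prediction without
## cross-validation, composite training sets (80% of the target group plus
## whole other groups), the overall-vs-within-subgroup correlation
## decomposition, and DAPC group discrimination.

MIN_STANDALONE_GROUP <- 30L

#' Predictive ability: Pearson correlation of predictions and observations
#'
#' @param pred predicted values
#' @param obs observed values (BLUEs of the prediction set)
#' @return Pearson correlation; errors on fewer than 3 pairs or zero
#'   variance (never silently returns 0)
#' @export
predictive_ability <- function(pred, obs) {
  keep <- !is.na(pred) & !is.na(obs)
  pred <- pred[keep]; obs <- obs[keep]
  if (length(pred) < 3L) stop("need >= 3 paired values", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    stop("predictive ability undefined: zero variance in predictions or observations",
         call. = FALSE)
  }
  stats::cor(pred, obs)
}

#' Overall vs within-subgroup correlation decomposition
#'
#' The overall Pearson correlation over all pooled pairs, the correlation
#' within each subgroup, and their unweighted mean (rbar). When population
#' structure is confounded with trait means, the overall correlation can be
#' high while every within-subgroup correlation is near zero; this
#' decomposition makes that artifact visible. Subgroups with fewer than 3
#' members or zero variance are excluded from rbar and reported.
#'
#' @param pred,obs paired predicted and observed values
#' @param subgroups subgroup label per pair
#' @return list with overall_r, subgroup_r (named), rbar, excluded
#' @export
structure_decomposition <- function(pred, obs, subgroups) {
  stopifnot(length(pred) == length(obs), length(obs) == length(subgroups))
  overall <- predictive_ability(pred, obs)
  labs <- unique(as.character(subgroups))
  rs <- c(); excluded <- character(0)
  for (g in labs) {
    i <- which(subgroups == g)
    r <- tryCatch(predictive_ability(pred[i], obs[i]), error = function(e) NA_real_)
    if (is.na(r)) excluded <- c(excluded, g) else rs[g] <- r
  }
  if (length(rs) < 2L) warning("fewer than 2 subgroups contribute to rbar")
  list(overall_r = overall, subgroup_r = rs, rbar = mean(rs), excluded = excluded)
}

#' Partition genotypes into k folds, optionally stratified by subgroup
#'
#' Unstratified: a random equal-as-possible split. Stratified: proportional
#' sampling per subgroup with largest-remainder rounding, so each fold's
#' count from subgroup s differs from n_s/k by at most one and the folds
#' cover each subgroup exactly. Subgroups are processed in name order (then
#' RNG) so the partition is a deterministic function of the seed.
#'
#' @param ids genotype ids to partition
#' @param k number of folds
#' @param subgroups optional subgroup label per id (enables stratification)
#' @return list of k disjoint id vectors covering `ids`
#' @export
make_folds <- function(ids, k = 5L, subgroups = NULL) {
  stopifnot(k >= 2L, length(ids) >= k)
  folds <- vector("list", k)
  assign_group <- function(members) {
    n <- length(members)
    base <- n %/% k
    extra_folds <- if (n %% k) sample.int(k, n %% k) else integer(0)
    sizes <- rep(base, k)
    sizes[extra_folds] <- sizes[extra_folds] + 1L
    labels <- rep(seq_len(k), sizes)
    shuffled <- sample(members)
    for (f in seq_len(k)) folds[[f]] <<- c(folds[[f]], shuffled[labels == f])
  }
  if (is.null(subgroups)) {
    assign_group(ids)
  } else {
    stopifnot(length(subgroups) == length(ids))
    for (g in sort(unique(as.character(subgroups)))) {
      assign_group(ids[subgroups == g])
    }
  }
  folds
}

.cv_result <- function(results, scheme, predictions = NULL) {
  structure(list(results = results, scheme = scheme,
                 mean_r = mean(results$r, na.rm = TRUE),
                 sd_r = stats::sd(results$r, na.rm = TRUE),
                 predictions = predictions),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: %d fold-level r values, mean=%.3f, sd=%.3f\n",
              x$scheme$kind, nrow(x$results), x$mean_r, x$sd_r))
  invisible(x)
}

#' Within-group k-fold cross-validated prediction
#'
#' For each run, the group is randomly partitioned into k folds (stratified
#' proportionally by subgroup when labels are supplied); each fold is
#' predicted from a ridge model trained on the other k-1, and the predictive
#' ability is the Pearson correlation within that prediction set. Fold-level
#' correlations are pooled over runs. Groups below 30 members are refused as
#' standalone sets.
#'
#' @param y named response vector (BLUEs) for the group
#' @param Z predictor matrix (rows must cover `names(y)`)
#' @param subgroups optional subgroup label per genotype (stratification and
#'   decomposition)
#' @param k folds per run
#' @param n_runs number of random partitions
#' @param seed integer seed (fixes folds and results exactly)
#' @param keep_predictions also return the per-run predictions (pooled
#'   across runs, as used for the correlation decomposition display)?
#' @return a `cv_result`
#' @export
run_within_cv <- function(y, Z, subgroups = NULL, k = 5L, n_runs = 1000L,
                          seed = 1L, keep_predictions = FALSE) {
  ids <- names(y)
  stopifnot(!is.null(ids), !is.null(rownames(Z)))
  if (length(y) < MIN_STANDALONE_GROUP) {
    stop(sprintf("group of %d is below the minimum standalone size of %d",
                 length(y), MIN_STANDALONE_GROUP), call. = FALSE)
  }
  Z <- Z[ids, , drop = FALSE]
  set.seed(seed)
  res <- vector("list", n_runs * k)
  preds <- if (keep_predictions) vector("list", n_runs)
  idx <- 0L
  for (run in seq_len(n_runs)) {
    folds <- make_folds(ids, k, subgroups)
    run_pred <- c()
    for (f in seq_len(k)) {
      test <- folds[[f]]
      train <- setdiff(ids, test)
      fit <- solve_rrblup(y[train], Z[train, , drop = FALSE])
      p <- predict_new(fit, Z[test, , drop = FALSE])
      r <- tryCatch(predictive_ability(p, y[test]), error = function(e) NA_real_)
      idx <- idx + 1L
      res[[idx]] <- data.frame(run = run, fold = f, r = r)
      if (keep_predictions) run_pred <- c(run_pred, p)
    }
    if (keep_predictions) {
      preds[[run]] <- data.frame(run = run, genotype = names(run_pred),
                                 pred = unname(run_pred),
                                 obs = unname(y[names(run_pred)]))
    }
  }
  .cv_result(do.call(rbind, res),
             scheme = list(kind = "within", k = k, n_runs = n_runs, seed = seed,
                           stratified = !is.null(subgroups)),
             predictions = if (keep_predictions) do.call(rbind, preds))
}

#' Among-group prediction without cross-validation
#'
#' One ridge fit on the entire training group, one predictive ability on the
#' entire (disjoint) prediction group. Negative correlations are returned
#' as-is. Reciprocal predictions are obtained by swapping the arguments.
#'
#' @param y named response vector covering both groups
#' @param Z predictor matrix
#' @param train_ids,test_ids disjoint genotype id sets
#' @return predictive ability (scalar; predictions in attribute
#'   "predictions")
#' @export
run_among <- function(y, Z, train_ids, test_ids) {
  if (length(intersect(train_ids, test_ids))) {
    stop("training and prediction sets overlap", call. = FALSE)
  }
  stopifnot(all(train_ids %in% names(y)), all(test_ids %in% names(y)))
  fit <- solve_rrblup(y[train_ids], Z[train_ids, , drop = FALSE])
  p <- predict_new(fit, Z[test_ids, , drop = FALSE])
  r <- predictive_ability(p, y[test_ids])
  attr(r, "predictions") <- p
  r
}

#' Composite-training-set evaluation
#'
#' Per run: a random 80/20 split of the target group; the training set is
#' the 80% of the target plus the whole of every listed other group; the
#' predictive ability is measured on the held-out 20%. With no other groups
#' this reduces exactly to one 80/20 within-group cross-validation run.
#'
#' @param y named response vector
#' @param Z predictor matrix
#' @param target_ids genotypes of the group being predicted
#' @param other_ids genotypes of the added groups (may be empty)
#' @param n_runs number of random splits
#' @param train_frac fraction of the target group used for training
#' @param seed integer seed
#' @param compare_among also evaluate, on the same held-out set of each run,
#'   a model trained on the other groups alone (column `r_among`)? Requires
#'   non-empty `other_ids`.
#' @return a `cv_result` with one r per run (plus `r_among` when requested)
#' @export
run_composite <- function(y, Z, target_ids, other_ids = character(0),
                          n_runs = 100L, train_frac = 0.8, seed = 1L,
                          compare_among = FALSE) {
  if (compare_among && !length(other_ids)) {
    stop("compare_among requires non-empty other_ids", call. = FALSE)
  }
  stop_if_not_scalar_prob(train_frac, "train_frac")
  if (length(intersect(target_ids, other_ids))) {
    stop("target and other groups overlap", call. = FALSE)
  }
  fit_a <- if (compare_among) solve_rrblup(y[other_ids], Z[other_ids, , drop = FALSE])
  set.seed(seed)
  n_tr <- round(train_frac * length(target_ids))
  res <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    tr_target <- sample(target_ids, n_tr)
    test <- setdiff(target_ids, tr_target)
    train <- c(tr_target, other_ids)
    fit <- solve_rrblup(y[train], Z[train, , drop = FALSE])
    p <- predict_new(fit, Z[test, , drop = FALSE])
    row <- data.frame(run = run, fold = 1L,
                      r = predictive_ability(p, y[test]))
    if (compare_among) {
      p_a <- predict_new(fit_a, Z[test, , drop = FALSE])
      row$r_among <- predictive_ability(p_a, y[test])
    }
    res[[run]] <- row
  }
  .cv_result(do.call(rbind, res),
             scheme = list(kind = "composite", n_runs = n_runs,
                           train_frac = train_frac, seed = seed,
                           n_other = length(other_ids)))
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Projects the (column-centered) feature matrix onto its leading principal
#' components, then fits linear discriminant axes maximizing between-group
#' over within-group variance on the PC scores. Reports per-axis percent
#' discriminant variance, per-genotype discriminant coordinates, and the
#' leave-one-out reassignment rate. The default PC count is the smallest
#' explaining at least 90% of the variance, capped at n/3; if the
#' within-group scatter is singular the count is reduced automatically.
#'
#' @param X genotypes x features numeric matrix
#' @param groups group label per genotype
#' @param n_pc number of principal components to retain (NULL = automatic)
#' @return a `dapc_result`: list with n_pc, coords, percent_var,
#'   reassignment, assigned
#' @export
dapc <- function(X, groups, n_pc = NULL) {
  X <- as.matrix(X)
  groups <- factor(groups)
  n <- nrow(X)
  ng <- nlevels(groups)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (is.null(n_pc)) {
    n_pc <- min(which(cumsum(ev) / sum(ev) >= 0.9)[1], floor(n / 3))
  }
  n_pc <- max(2L, min(n_pc, n - ng - 1L))
  if (n_pc >= n - ng) stop("n_pc must be < n - n_groups", call. = FALSE)
  fit_lda <- function(npc) {
    scores <- pc$x[, seq_len(npc), drop = FALSE]
    list(lda = MASS::lda(scores, grouping = groups),
         cv = MASS::lda(scores, grouping = groups, CV = TRUE),
         scores = scores)
  }
  fit <- NULL
  while (is.null(fit) && n_pc >= 2L) {
    fit <- tryCatch(suppressWarnings(fit_lda(n_pc)), error = function(e) NULL)
    if (is.null(fit)) {
      message(sprintf("within-group scatter singular at %d PCs; reducing", n_pc))
      n_pc <- n_pc - 5L
    }
  }
  if (is.null(fit)) stop("DAPC failed: within-group scatter singular", call. = FALSE)
  coords <- stats::predict(fit$lda, fit$scores)$x
  pct <- 100 * fit$lda$svd^2 / sum(fit$lda$svd^2)
  structure(list(n_pc = n_pc, coords = coords,
                 percent_var = pct,
                 reassignment = mean(fit$cv$class == groups),
                 assigned = fit$cv$class),
            class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("<dapc_result> %d PCs, DA1=%.1f%%, DA2=%.1f%%, reassignment=%.1f%%\n",
              x$n_pc, x$percent_var[1],
              if (length(x$percent_var) > 1) x$percent_var[2] else NA,
              100 * x$reassignment))
  invisible(x)
}
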