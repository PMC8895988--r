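# Evaluation designs: predictive-ability arithmetic, the correlation
# decomposition, fold-partition properties, scheme determinism, among-group
# and composite contracts, and DAPC discrimination.

test_that("predictive ability matches hand-computed correlations and refuses degeneracy", {
  expect_equal(predictive_ability(1:5, 1:5), 1)
  expect_equal(predictive_ability(1:5, -(1:5)), -1)
  obs <- c(0, 1, 2, 10, 11, 12)
  pred <- c(2, 1, 0, 12, 11, 10)
  expect_equal(predictive_ability(pred, obs), 146 / 154, tolerance = 1e-12)
  expect_error(predictive_ability(c(1, 2), c(1, 2)), ">= 3")
  expect_error(predictive_ability(rep(1, 5), 1:5), "zero variance")
})

test_that("the structure decomposition separates overall and within-subgroup signal", {
  obs <- c(0, 1, 2, 10, 11, 12)
  pred <- c(2, 1, 0, 12, 11, 10)
  grp <- rep(c("lo", "hi"), each = 3)
  d <- structure_decomposition(pred, obs, grp)
  expect_equal(d$overall_r, 146 / 154, tolerance = 1e-12)
  expect_equal(unname(d$subgroup_r[c("lo", "hi")]), c(-1, -1))
  expect_equal(d$rbar, -1)

  set.seed(1)
  x <- rnorm(30)
  d2 <- structure_decomposition(x, x, rep(c("a", "b"), 15))
  expect_equal(d2$overall_r, 1)
  expect_equal(d2$rbar, 1)

  # zero-variance subgroup excluded and reported
  d3 <- structure_decomposition(c(x, rep(1, 5)), c(x, rep(2, 5)),
                                c(rep(c("a", "b"), 15), rep("c", 5)))
  expect_true("c" %in% d3$excluded)
  expect_false("c" %in% names(d3$subgroup_r))
})

test_that("fold partitions cover exactly, are disjoint, and respect stratification", {
  lr_sizes <- c(CG = 11, GB = 33, RT = 14, SM = 53, SF = 30, WA = 59)
  ids <- paste0(rep(names(lr_sizes), lr_sizes), "_", unlist(lapply(lr_sizes, seq_len)))
  sub <- rep(names(lr_sizes), lr_sizes)
  for (s in 1:25) {
    set.seed(s)
    folds <- make_folds(ids, k = 5, subgroups = sub)
    all_ids <- unlist(folds)
    expect_setequal(all_ids, ids)
    expect_equal(length(all_ids), length(ids))          # disjoint cover
    for (g in names(lr_sizes)) {
      counts <- vapply(folds, function(f) sum(startsWith(f, paste0(g, "_"))),
                       numeric(1))
      expect_lte(max(abs(counts - lr_sizes[g] / 5)), 1)  # proportional +/- 1
      expect_equal(sum(counts), unname(lr_sizes[g]))
    }
  }
  # unstratified: n=100, k=5 -> every fold exactly 20
  set.seed(3)
  f100 <- make_folds(paste0("g", 1:100), k = 5)
  expect_true(all(lengths(f100) == 20))
})

test_that("schemes are deterministic functions of their seed", {
  ids <- paste0("g", 1:50)
  set.seed(11); f1 <- make_folds(ids, 5)
  set.seed(11); f2 <- make_folds(ids, 5)
  expect_identical(f1, f2)

  set.seed(2)
  Z <- matrix(rnorm(60 * 40), 60, 40,
              dimnames = list(paste0("g", 1:60), paste0("f", 1:40)))
  y <- stats::setNames(rnorm(60), rownames(Z))
  cv1 <- run_within_cv(y, Z, n_runs = 3, seed = 5)
  cv2 <- run_within_cv(y, Z, n_runs = 3, seed = 5)
  expect_identical(cv1$results, cv2$results)
  cv3 <- run_within_cv(y, Z, n_runs = 3, seed = 6)
  expect_false(identical(cv1$results, cv3$results))
})

test_that("within-group cross-validation honours the size floor and tracks the kernel oracle", {
  set.seed(21)
  Z <- matrix(rnorm(25 * 30), 25, 30,
              dimnames = list(paste0("g", 1:25), paste0("f", 1:30)))
  y <- stats::setNames(rnorm(25), rownames(Z))
  expect_error(run_within_cv(y, Z, n_runs = 1), "below the minimum")

  pop <- small_pop()
  tr <- simulate_trait(pop, n_qtl = 60, qtl_share = 0.5, chem_share = 0,
                       delta_sd = 0, seed = 31)
  set.seed(32)
  yb <- tr$g + rnorm(120, sd = sqrt(0.5))
  names(yb) <- pop$groups$genotype
  Zb <- dosages(pop$geno)
  cv <- run_within_cv(yb, Zb, n_runs = 25, seed = 33)
  expect_equal(nrow(cv$results), 25 * 5)
  expect_true(all(abs(cv$results$r) <= 1, na.rm = TRUE))
  # paired kernel-path oracle under identical folds
  oracle_r <- c()
  set.seed(33)
  for (run in 1:25) {
    folds <- make_folds(names(yb), 5)
    for (f in seq_along(folds)) {
      test <- folds[[f]]; train <- setdiff(names(yb), test)
      p <- gblup_equiv(yb[train], Zb[train, ], Zb[test, ])
      oracle_r <- c(oracle_r, predictive_ability(p, yb[test]))
    }
  }
  expect_lt(abs(cv$mean_r - mean(oracle_r)), 0.07)
})

test_that("among-group prediction forbids overlap and reports reciprocal directions", {
  pop <- small_pop()
  tr <- simulate_trait(pop, n_qtl = 60, qtl_share = 0.6, chem_share = 0.4,
                       delta_sd = 1, seed = 41)
  set.seed(42)
  y <- tr$g + rnorm(120, sd = 0.5)
  names(y) <- pop$groups$genotype
  Z <- dosages(pop$geno)
  a_ids <- pop$groups$genotype[pop$groups$subgroup == "A"]
  b_ids <- pop$groups$genotype[pop$groups$subgroup == "B"]
  expect_error(run_among(y, Z, a_ids, c(b_ids, a_ids[1])), "overlap")
  r_ab <- run_among(y, Z, a_ids, b_ids)
  r_ba <- run_among(y, Z, b_ids, a_ids)
  expect_true(is.numeric(r_ab) && is.numeric(r_ba))
  expect_length(attr(r_ab, "predictions"), length(b_ids))
})

test_that("composite training sets degenerate to a within 80/20 split and pair with among", {
  pop <- small_pop()
  tr <- simulate_trait(pop, n_qtl = 60, qtl_share = 0.7, chem_share = 0.3,
                       delta_sd = 0, seed = 51)
  set.seed(52)
  y <- tr$g + rnorm(120, sd = 0.5)
  names(y) <- pop$groups$genotype
  Z <- dosages(pop$geno)
  a_ids <- pop$groups$genotype[pop$groups$subgroup == "A"]
  b_ids <- pop$groups$genotype[pop$groups$subgroup == "B"]
  solo <- run_composite(y, Z, a_ids, character(0), n_runs = 10, seed = 53)
  expect_equal(nrow(solo$results), 10L)
  expect_equal(solo$scheme$n_other, 0L)
  expect_error(run_composite(y, Z, a_ids, a_ids[1:3]), "overlap")
  expect_error(run_composite(y, Z, a_ids, character(0), compare_among = TRUE),
               "non-empty")
  both <- run_composite(y, Z, a_ids, b_ids, n_runs = 10, seed = 53,
                        compare_among = TRUE)
  expect_true(all(c("r", "r_among") %in% names(both$results)))
})

test_that("DAPC separates constructed groups and not permuted labels", {
  set.seed(61)
  X <- cbind(c(rnorm(40), rnorm(40, mean = 10)), matrix(rnorm(80 * 5), 80))
  grp <- rep(c("a", "b"), each = 40)
  res <- dapc(X, grp, n_pc = 3)
  expect_gte(res$percent_var[1], 99)
  expect_equal(res$reassignment, 1)

  perm <- sample(grp)
  res_p <- dapc(X, perm, n_pc = 3)
  # chance is 0.5; stay within a generous binomial envelope
  expect_lte(res_p$reassignment, 0.5 + 2.5 * sqrt(0.25 / 80))
})

test_that("marker DAPC separates the simulated subgroups while spectra do not", {
  sc <- get_confounded()
  grp <- sc$groups$subgroup
  res_g <- dapc(sc$Z_genomic[sc$groups$genotype, ], grp)
  expect_gte(res_g$reassignment, 0.90)
  res_p <- suppressMessages(dapc(sc$Z_phenomic[sc$groups$genotype, ], grp))
  chance <- max(table(grp)) / length(grp)
  expect_lte(res_p$reassignment, chance + 0.10)
})
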