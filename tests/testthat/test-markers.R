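# Stepwise marker QC: the hand-enumerated fixture, threshold semantics,
# per-group filters, mean imputation, the merge oracle, report invariants,
# and coding-orientation invariance of downstream predictions.

test_that("overall QC removes exactly the enumerated defects from the toy fixture", {
  res <- qc_overall(toy_qc_matrix())
  steps <- res$report$steps
  expect_equal(steps$step, c("all_missing", "missing_fraction",
                             "heterozygosity", "monomorphic"))
  expect_equal(steps$removed, c(1L, 1L, 1L, 1L))
  expect_equal(steps$remaining, c(5L, 4L, 3L, 2L))
  expect_identical(rownames(res$geno$calls), c("M5", "M6"))
})

test_that("a clean matrix passes QC untouched and re-running removes nothing", {
  pop <- small_pop()
  res1 <- qc_overall(pop$geno)
  res2 <- qc_overall(res1$geno)
  expect_equal(sum(res2$report$steps$removed), 0L)
  expect_identical(res2$geno$calls, res1$geno$calls)
  # report is additive and order-faithful
  st <- res1$report$steps
  expect_equal(st$remaining, n_markers(pop$geno) - cumsum(st$removed))
})

test_that("marker thresholds are strict and genotype-level checks flag, not drop", {
  # marker at exactly 50% missing must be kept (> is strict)
  calls <- rbind(M1 = c(0L, 2L, NA, NA),
                 M2 = c(0L, 2L, 0L, 2L))
  colnames(calls) <- paste0("G", 1:4)
  res <- suppressWarnings(qc_overall(geno_matrix(calls)))
  expect_equal(n_markers(res$geno), 2L)

  # genotype with >20% missing is flagged in the report but retained
  calls2 <- matrix(0L, 10, 4, dimnames = list(paste0("M", 1:10), paste0("G", 1:4)))
  calls2[, 2] <- 2L
  calls2[1:3, 4] <- NA  # 30% missing for G4
  expect_warning(res2 <- qc_overall(geno_matrix(calls2)), "G4")
  expect_equal(res2$report$flagged_genotypes, "G4")
  expect_equal(n_genotypes(res2$geno), 4L)
})

test_that("per-group QC recodes hets to missing and applies strict MAF semantics", {
  # 50 homozygous genotypes per group -> 1 and 2 alternate lines give
  # MAF 0.02 and 0.04 exactly
  set.seed(1)
  n <- 50
  calls <- rbind(
    maf02 = c(2L, rep(0L, n - 1), rep(0L, n)),      # MAF 0.02 in A
    maf04 = c(2L, 2L, rep(0L, n - 2), rep(0L, n)),  # MAF 0.04 in A
    monoA = c(rep(0L, n), rep(c(0L, 2L), n / 2)[1:n]),  # monomorphic in A only
    het_only = c(rep(1L, n), rep(c(0L, 2L), length.out = n)),
    clean = rep(c(0L, 2L), n))
  colnames(calls) <- paste0("G", 1:(2 * n))
  gmap <- data.frame(genotype = colnames(calls),
                     subgroup = rep(c("A", "B"), each = n),
                     major_group = rep(c("A", "B"), each = n))
  per <- qc_per_group(geno_matrix(calls), gmap, maf_thr = 0.03,
                      group_col = "major_group")
  expect_false("maf02" %in% rownames(per$A$calls))   # 0.02 < 0.03 removed
  expect_true("maf04" %in% rownames(per$A$calls))    # 0.04 >= 0.03 kept
  expect_false("monoA" %in% rownames(per$A$calls))   # monomorphic there...
  expect_true("monoA" %in% rownames(per$B$calls))    # ...kept elsewhere
  # het-only marker becomes all-missing after recoding, hence removed
  expect_false("het_only" %in% rownames(per$A$calls))
  expect_false(any(per$A$calls == 1L, na.rm = TRUE))
  expect_error(qc_per_group(geno_matrix(calls),
                            data.frame(genotype = "zzz", subgroup = "A",
                                       major_group = "A")),
               "empty group")
})

test_that("naive imputation fills missing calls with the group marker mean", {
  calls <- rbind(M1 = c(0L, 2L, NA, 2L),
                 M2 = c(0L, 2L, 0L, 2L))
  colnames(calls) <- paste0("G", 1:4)
  imp <- impute_naive(list(A = geno_matrix(calls)))$A
  expect_equal(unname(imp[, "M1"]), c(0, 2, 4 / 3, 2))
  expect_equal(unname(imp[, "M2"]), c(0, 2, 0, 2))  # complete data unchanged
  expect_false(anyNA(imp))
  all_na <- rbind(M1 = c(NA_integer_, NA_integer_))
  colnames(all_na) <- c("G1", "G2")
  expect_error(impute_naive(list(A = geno_matrix(all_na))), "assertion")
})

test_that("the merge keeps the intersection of per-group survivors", {
  mk <- function(ids, n = 20, maf = 0.5) {
    m <- t(sapply(ids, function(i) rbinom(n, 1, maf) * 2L))
    rownames(m) <- ids
    m
  }
  set.seed(2)
  dA <- t(mk(c("M1", "M2", "M3"))); dB <- t(mk(c("M2", "M3", "M4")))
  rownames(dA) <- paste0("a", 1:20); rownames(dB) <- paste0("b", 1:20)
  merged <- maf_filter_and_merge(list(A = dA, B = dB), maf_thr = 0.05)
  expect_setequal(colnames(merged), c("M2", "M3"))
  expect_equal(nrow(merged), 40L)

  # independent set-operation oracle on a simulated three-group split
  pop <- simulate_population(c(A = 40, B = 40, C = 40), n_markers = 300,
                             fst = 0.35, seed = 77)
  per <- qc_per_group(pop$geno, pop$groups, group_col = "subgroup")
  imp <- impute_naive(per)
  merged2 <- maf_filter_and_merge(imp, maf_thr = 0.05)
  oracle <- Reduce(intersect, lapply(imp, function(d) {
    p <- colMeans(d) / 2
    colnames(d)[pmin(p, 1 - p) >= 0.05]
  }))
  expect_setequal(colnames(merged2), oracle)

  # a marker surviving in only some groups is absent from the merge
  dC <- dB[, c("M4"), drop = FALSE]
  expect_error(maf_filter_and_merge(list(A = dA[, "M1", drop = FALSE], C = dC)),
               "no markers shared")
})

test_that("flipping the counted allele leaves ridge predictions unchanged", {
  pop <- small_pop()
  set.seed(3)
  Z <- dosages(pop$geno)[1:60, 1:150]
  y <- stats::setNames(rnorm(50), rownames(Z)[1:50])
  fit1 <- solve_rrblup(y, Z[1:50, ])
  fit2 <- solve_rrblup(y, 2 - Z[1:50, ])
  p1 <- predict_new(fit1, Z[51:60, ])
  p2 <- predict_new(fit2, 2 - Z[51:60, ])
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("mean imputation degrades predictive ability only mildly under MCAR", {
  degr <- vapply(1:10, function(s) {
    pop <- simulate_population(c(A = 300), n_markers = 250, fst = 0.2,
                               het_rate = 0, missing_rate = 0, seed = 40 + s)
    tr <- simulate_trait(pop, n_qtl = 50, qtl_share = 0.5, chem_share = 0.5,
                         seed = 50 + s)
    set.seed(60 + s)
    y <- tr$g + rnorm(300, sd = 0.5)
    names(y) <- pop$groups$genotype
    Z_full <- dosages(pop$geno)
    Z_miss <- Z_full
    Z_miss[runif(length(Z_miss)) < 0.10] <- NA
    mu <- colMeans(Z_miss, na.rm = TRUE)
    idx <- which(is.na(Z_miss), arr.ind = TRUE)
    Z_miss[idx] <- mu[idx[, 2]]
    tr_ids <- names(y)[1:240]; te_ids <- names(y)[241:300]
    r_full <- predictive_ability(
      predict_new(solve_rrblup(y[tr_ids], Z_full[tr_ids, ]), Z_full[te_ids, ]),
      y[te_ids])
    r_imp <- predictive_ability(
      predict_new(solve_rrblup(y[tr_ids], Z_miss[tr_ids, ]), Z_miss[te_ids, ]),
      y[te_ids])
    r_full - r_imp
  }, numeric(1))
  expect_lte(mean(degr), 0.05)
})
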