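# Mixed-model machinery: heritability arithmetic, BLUE equivalences against
# closed-form and GLS oracles, REML vs balanced-ANOVA estimators, outlier
# screening including its family-wise error rate, and per-group components.

test_that("entry-mean heritability follows its closed form and limits", {
  vc <- list(sigma2_g = 4, sigma2_gxe = 2, sigma2_eps = 4, ne = 3, nr = 2)
  expect_equal(heritability(vc), 4 / (4 + 2 / 3 + 4 / 6))
  expect_equal(heritability(vc), 0.75)
  expect_equal(heritability(list(sigma2_g = 0, sigma2_gxe = 2, sigma2_eps = 4,
                                 ne = 3, nr = 2)), 0)
  expect_error(heritability(list(sigma2_g = 0, sigma2_gxe = 0, sigma2_eps = 0,
                                 ne = 3, nr = 2)), "undefined")
  # monotone increase toward 1 with more environments/replicates
  hs <- vapply(c(1, 2, 5, 20, 100), function(k)
    heritability(vc, ne = k, nr = k), numeric(1))
  expect_true(all(diff(hs) > 0))
  expect_gt(hs[5], 0.99)
})

test_that("a balanced zero-noise design returns genotype means as BLUEs", {
  df <- data.frame(genotype = c("g1", "g2"), environment = "E1",
                   replicate = 1L, block = 1L, y = c(10, 12))
  fit <- fit_plot_model(plot_table(df), "y", genotype_fixed = TRUE)
  expect_equal(fit$blues, c(g1 = 10, g2 = 12))

  pt <- balanced_plots(n_g = 20, seed = 4)
  means <- tapply(pt$trait, pt$genotype, mean)
  for (m in c("reml", "random")) {
    fit2 <- fit_plot_model(pt, "trait", genotype_fixed = TRUE, vc_method = m)
    expect_equal(fit2$blues[names(means)], means, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  blues <- compute_blues(pt, "trait")
  expect_equal(blues$trait, as.numeric(means[rownames(blues)]), tolerance = 1e-8)
})

test_that("REML equals the balanced-ANOVA method-of-moments estimators when interior", {
  pt <- balanced_plots(n_g = 40, ne = 3, nr = 2, seed = 11,
                       vc = list(sigma2_env = 1, sigma2_gxe = 2,
                                 sigma2_rep = 0.5, sigma2_block = 0,
                                 sigma2_eps = 4),
                       sigma2_g = 6)
  # independent oracle: expected-mean-squares estimators from aov tables
  d <- data.frame(y = pt$trait, g = factor(pt$genotype),
                  e = factor(pt$environment),
                  r = factor(paste(pt$environment, pt$replicate)))
  n_g <- nlevels(d$g); n_e <- nlevels(d$e); n_r <- 2
  ms <- anova(lm(y ~ g + e + r + g:e, data = d))
  MSg <- ms["g", "Mean Sq"]; MSge <- ms["g:e", "Mean Sq"]
  MSr <- ms["r", "Mean Sq"]; MSerr <- ms["Residual", "Mean Sq"]
  ## note: with r coded across environments, "r" rows include rep-in-env
  ## only because rep labels are nested via the paste(); e is marginal
  s2_eps <- MSerr
  s2_ge <- (MSge - MSerr) / n_r
  s2_g <- (MSg - MSge) / (n_e * n_r)
  fit <- fit_plot_model(pt, "trait", genotype_fixed = FALSE)
  interior <- all(c(s2_eps, s2_ge, s2_g) > 0) &&
    all(unlist(fit$vc[c("sigma2_g", "sigma2_gxe", "sigma2_eps")]) > 1e-8)
  expect_true(interior)
  expect_equal(fit$vc$sigma2_g, s2_g, tolerance = 1e-6)
  expect_equal(fit$vc$sigma2_gxe, s2_ge, tolerance = 1e-6)
  expect_equal(fit$vc$sigma2_eps, s2_eps, tolerance = 1e-6)
})

test_that("unbalanced BLUEs equal the dense GLS solution at the fitted components", {
  pt <- balanced_plots(n_g = 12, ne = 2, nr = 2, seed = 21)
  pt <- plot_table(as.data.frame(pt)[-c(3, 17), ])   # delete two plots
  fit <- fit_plot_model(pt, "trait", genotype_fixed = TRUE)
  d <- fit$data
  # direct matrix-inversion oracle
  X <- model.matrix(~ 0 + genotype, d)
  V <- diag(fit$vc$sigma2_eps, nrow(d))
  add <- function(f, s2) {
    if (!is.na(s2) && s2 > 0) {
      Z <- model.matrix(~ 0 + f)
      V <<- V + s2 * tcrossprod(Z)
    }
  }
  add(d$environment, fit$vc$sigma2_env)
  add(d$gxe, fit$vc$sigma2_gxe)
  add(d$rep_in_env, fit$vc$sigma2_rep)
  Vi <- solve(V)
  blue_gls <- drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$y))
  names(blue_gls) <- sub("^genotype", "", colnames(X))
  expect_equal(fit$blues[names(blue_gls)], blue_gls, tolerance = 1e-6)
  # the fast plug-in GLS path agrees with its own oracle too
  fit_mme <- fit_plot_model(pt, "trait", genotype_fixed = TRUE,
                            vc_method = "random")
  expect_equal(sort(names(fit_mme$blues)), sort(names(blue_gls)))
})

test_that("variance components are recovered on average over repeated simulation", {
  ests <- t(vapply(1:12, function(s) {
    pt <- balanced_plots(n_g = 60, ne = 3, nr = 2, seed = 500 + s,
                         vc = list(sigma2_env = 1, sigma2_gxe = 2,
                                   sigma2_rep = 0.1, sigma2_block = 0,
                                   sigma2_eps = 4),
                         sigma2_g = 4)
    fit <- fit_plot_model(pt, "trait")
    c(g = fit$vc$sigma2_g, ge = fit$vc$sigma2_gxe, eps = fit$vc$sigma2_eps)
  }, numeric(3)))
  expect_lt(abs(mean(ests[, "g"]) - 4) / 4, 0.20)
  expect_lt(abs(mean(ests[, "ge"]) - 2) / 2, 0.20)
  expect_lt(abs(mean(ests[, "eps"]) - 4) / 4, 0.10)
})

test_that("constant traits give constant BLUEs", {
  df <- expand.grid(genotype = paste0("g", 1:5), environment = c("E1", "E2"),
                    replicate = 1:2, stringsAsFactors = FALSE)
  df$block <- 1L
  df$y <- 7
  fit <- suppressWarnings(fit_plot_model(plot_table(df), "y", genotype_fixed = TRUE))
  expect_equal(unname(fit$blues), rep(7, 5), tolerance = 1e-8)
})

test_that("outlier screen flags a gross outlier, and only it", {
  pt <- balanced_plots(n_g = 30, ne = 2, nr = 2, seed = 31,
                       vc = list(sigma2_env = 1, sigma2_gxe = 0.2,
                                 sigma2_rep = 0.1, sigma2_block = 0,
                                 sigma2_eps = 1),
                       sigma2_g = 2)
  res_clean <- detect_outliers(pt, "trait", alpha = 0.05)
  expect_equal(res_clean$n_flagged, 0L)

  spiked <- as.data.frame(pt)
  spiked$trait[37] <- spiked$trait[37] + 100
  res <- detect_outliers(plot_table(spiked), "trait", alpha = 0.05)
  expect_equal(which(res$flags), 37L)
  expect_true(is.na(res$plots$trait[37]))

  expect_error(detect_outliers(pt, "trait", alpha = 1.5), "between 0 and 1")
})

test_that("the Holm outlier screen controls the family-wise error under the null", {
  n_rej <- vapply(1:300, function(s) {
    set.seed(7000 + s)
    df <- expand.grid(genotype = paste0("g", 1:100), environment = "E1",
                      replicate = 1:2, stringsAsFactors = FALSE)
    df$block <- 1L
    df$y <- rnorm(200)
    detect_outliers(plot_table(df), "y", alpha = 0.05)$n_flagged > 0
  }, logical(1))
  fwer <- mean(n_rej)
  mc_sd <- sqrt(0.05 * 0.95 / 300)
  expect_lte(fwer, 0.05 + 2 * mc_sd)
})

test_that("group-specific heritabilities order groups by their genotypic variance", {
  hits <- vapply(1:30, function(s) {
    set.seed(900 + s)
    g1 <- stats::setNames(rnorm(40, sd = 1), paste0("a", 1:40))
    g2 <- stats::setNames(rnorm(40, sd = 3), paste0("b", 1:40))
    vc <- list(sigma2_env = 1, sigma2_gxe = 0.5, sigma2_rep = 0.1,
               sigma2_block = 0, sigma2_eps = 2)
    pt <- simulate_plots(c(g1, g2), ne = 2, nr = 2, n_blocks = 1,
                         vc = vc, seed = 900 + s)
    gmap <- data.frame(genotype = c(names(g1), names(g2)),
                       subgroup = rep(c("lo", "hi"), each = 40))
    h2 <- group_heritabilities(pt, "trait", gmap)
    h2["hi"] > h2["lo"]
  }, logical(1))
  expect_gte(sum(hits), 28)
})

test_that("groups with a single genotype are skipped with a warning", {
  pt <- balanced_plots(n_g = 10, seed = 77)
  gmap <- data.frame(genotype = sprintf("g%02d", 1:10),
                     subgroup = c(rep("A", 9), "B"))
  expect_warning(h2 <- group_heritabilities(pt, "trait", gmap), "skipped")
  expect_named(h2, "A")
})
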