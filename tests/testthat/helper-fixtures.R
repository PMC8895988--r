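# Shared fixtures, all built in code. The two study scenarios are expensive
# (full marker + spectra pipelines), so they are built lazily once per test
# session and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

get_confounded <- function() {
  cached("confounded", function() suppressWarnings(suppressMessages(
    scenario_confounded(11))))
}

get_transfer <- function() {
  cached("transfer", function() suppressWarnings(suppressMessages(
    scenario_transfer(21))))
}

# small two-group population without call noise, for prediction tests
small_pop <- function() {
  cached("small_pop", function() {
    simulate_population(c(A = 60, B = 60), n_markers = 300, fst = 0.2,
                        het_rate = 0, missing_rate = 0, seed = 42)
  })
}

# balanced plot data with known variance components
balanced_plots <- function(n_g = 40, ne = 3, nr = 2, seed = 1,
                           vc = list(sigma2_env = 1, sigma2_gxe = 2,
                                     sigma2_rep = 0.5, sigma2_block = 0,
                                     sigma2_eps = 4),
                           sigma2_g = 4) {
  set.seed(seed)
  g <- stats::setNames(rnorm(n_g, sd = sqrt(sigma2_g)), sprintf("g%02d", 1:n_g))
  simulate_plots(g, ne = ne, nr = nr, n_blocks = 1, mu = 10, vc = vc,
                 seed = seed + 1000)
}

# the hand-enumerated 6-marker x 4-genotype QC fixture:
# M1 all-missing; M2 3/4 missing; M3 2/4 het; M4 monomorphic; M5, M6 clean
toy_qc_matrix <- function() {
  calls <- rbind(
    M1 = c(NA, NA, NA, NA),
    M2 = c(0L, NA, NA, NA),
    M3 = c(1L, 1L, 0L, 2L),
    M4 = c(0L, 0L, 0L, 0L),
    M5 = c(0L, 2L, 0L, 2L),
    M6 = c(2L, 0L, 2L, 2L))
  colnames(calls) <- paste0("G", 1:4)
  geno_matrix(calls)
}

expect_same_folds <- function(f1, f2) {
  expect_identical(lapply(f1, sort), lapply(f2, sort))
}
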