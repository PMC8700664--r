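# Shared in-code fixtures; everything is generated, nothing stored.

# tiny reflectance set: 3 samples x 4 wavelengths
tiny_spectra <- function(mode = "reflectance") {
  spectra_set(c(950, 952, 954, 956),
              matrix(c(0.5, 0.4, 0.3, 0.2,
                       0.6, 0.5, 0.4, 0.3,
                       0.7, 0.6, 0.5, 0.4), 3, 4, byrow = TRUE),
              sample_ids = c("a", "b", "c"), mode = mode)
}

# spectra-shaped toy where the target is a noiseless linear function of
# exactly `informative` columns and every column is iid noise
toy_selection_problem <- function(n = 40L, p = 24L, informative = c(3L, 9L, 15L, 21L),
                                  seed = 1L) {
  grid <- seq(900, by = 2, length.out = p)
  X <- nirfruit:::with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  y <- as.numeric(X[, informative] %*% rep(1, length(informative)))
  s <- spectra_set(grid, X, mode = "absorbance")
  list(s = s, y = y, informative = informative, grid = grid)
}

# the fixed selector-network structure used as the SA objective net
table1_ann <- function() {
  ann_config(n_layers = 2L, neurons = c(13L, 23L),
             transfer = c("radbas", "logsig"),
             train_method = "trains", learn_method = "learnh")
}

expect_rows_standardized <- function(M, tol = 1e-12) {
  expect_true(max(abs(rowMeans(M))) < tol)
  expect_true(max(abs(apply(M, 1, stats::sd) - 1)) < tol)
}
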