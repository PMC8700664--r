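# a 5-slot mixed space and a planted-optimum mismatch cost
mixed_space <- function() {
  list(a = dim_int(1L, 5L), b = dim_int(1L, 10L),
       c = dim_cat(letters[1:6]), d = dim_cat(c("x", "y", "z")),
       e = dim_int(0L, 4L))
}
planted <- list(a = 3L, b = 7L, c = "d", d = "y", e = 2L)
mismatch_cost <- function(pos) {
  sum(vapply(names(planted), function(k) !identical(pos[[k]], planted[[k]]), logical(1L)))
}

test_that("ica_config validates its invariants", {
  expect_error(ica_config(n_countries = 5, n_imperialists = 5), "n_imperialists")
  expect_error(ica_config(revolution_rate = 1.5), "revolution_rate")
  expect_error(ica_config(beta = 0), "beta")
  expect_error(ica_config(zeta = 2), "zeta")
})

test_that("planted optimum is found and bookkeeping invariants hold", {
  found <- 0L
  for (sd in 1:3) {
    res <- ica_optimize(mismatch_cost, mixed_space(),
                        ica_config(n_countries = 40L, n_imperialists = 5L,
                                   max_decades = 100L, seed = sd))
    expect_true(all(diff(res$history$best_cost) <= 0))
    expect_true(all(res$history$n_empires >= 1L & res$history$n_empires <= 5L))
    expect_true(all(diff(res$history$n_empires) <= 0))
    if (res$best_cost == 0) found <- found + 1L
  }
  expect_gte(found, 2L)
})

test_that("degenerate one-colony population runs and returns the best evaluated", {
  res <- ica_optimize(mismatch_cost, mixed_space(),
                      ica_config(n_countries = 2L, n_imperialists = 1L,
                                 max_decades = 5L, seed = 1))
  expect_true(is.finite(res$best_cost))
  expect_equal(res$best_cost, mismatch_cost(res$best))
})

test_that("revolution_rate = 1 degrades to seeded random search, still monotone", {
  res <- ica_optimize(mismatch_cost, mixed_space(),
                      ica_config(n_countries = 20L, n_imperialists = 3L,
                                 max_decades = 30L, revolution_rate = 1,
                                 seed = 4))
  expect_true(all(diff(res$history$best_cost) <= 0))
  res2 <- ica_optimize(mismatch_cost, mixed_space(),
                       ica_config(n_countries = 20L, n_imperialists = 3L,
                                  max_decades = 30L, revolution_rate = 1,
                                  seed = 4))
  expect_identical(res$best, res2$best)
})

test_that("continuous sanity: the 5-d sphere is minimized to 1e-3", {
  space <- rep(list(dim_real(-3, 3)), 5L)
  names(space) <- paste0("x", 1:5)
  sphere <- function(pos) sum(unlist(pos)^2)
  ok <- 0L
  for (sd in 1:10) {
    res <- ica_optimize(sphere, space,
                        ica_config(n_countries = 40L, n_imperialists = 4L,
                                   max_decades = 120L, revolution_rate = 0.1,
                                   seed = sd))
    expect_lte(res$n_eval, 5000L)
    if (res$best_cost <= 1e-3) ok <- ok + 1L
  }
  expect_equal(ok, 10L)
})

test_that("network decoding ignores inactive layer slots", {
  pos <- list(n_layers = 2L, neurons1 = 4L, transfer1 = "logsig",
              neurons2 = 7L, transfer2 = "tansig",
              neurons3 = 25L, transfer3 = "netinv",
              train_method = "traincgb", learn_method = "learnh")
  cfg <- decode_ann_position(pos)
  expect_equal(cfg$n_layers, 2L)
  expect_equal(cfg$neurons, c(4L, 7L))
  expect_equal(cfg$transfer, c("logsig", "tansig"))
})

test_that("tune_ann honours degenerate spaces, seeding, and a baseline bar", {
  nirfruit:::with_seed(8, {
    X <- matrix(stats::rnorm(400), 100, 4)
    y <- as.numeric(X %*% c(2, -1, 0.5, 1)) + 0.3 * stats::rnorm(100)
  })
  # space collapsed to a single point returns that config unchanged
  point <- list(n_layers = dim_int(1L, 1L), neurons1 = dim_int(9L, 9L),
                transfer1 = dim_cat("tansig"),
                train_method = dim_cat("traincgb"), learn_method = dim_cat("learnh"))
  res <- tune_ann(X, y, ica_config(n_countries = 4L, n_imperialists = 1L,
                                   max_decades = 2L, seed = 1),
                  space = point, max_epochs = 30L)
  expect_equal(res$config$neurons, 9L)
  expect_equal(res$config$transfer, "tansig")

  small_ica <- ica_config(n_countries = 15L, n_imperialists = 3L,
                          max_decades = 10L, seed = 7)
  t1 <- tune_ann(X, y, small_ica, max_epochs = 40L)
  t2 <- tune_ann(X, y, small_ica, max_epochs = 40L)
  expect_identical(t1$config, t2$config)

  # tuned config validates at no worse than 1.2x a fixed default structure
  baseline <- nirfruit:::ann_cv_objective(X, y, ann_config(1, 10L, "logsig"),
                                          max_epochs = 40L)
  expect_lte(t1$best_cost, 1.2 * baseline)
})
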