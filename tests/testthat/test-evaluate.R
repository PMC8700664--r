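test_that("splits follow largest-remainder rounding and are reproducible", {
  p <- split_data(150, seed = 1)
  expect_equal(lengths(p[c("train", "validation", "test")]),
               c(train = 90L, validation = 15L, test = 45L))
  p10 <- split_data(10, seed = 1)
  expect_equal(lengths(p10[c("train", "validation", "test")]),
               c(train = 6L, validation = 1L, test = 3L))
  # disjoint and exhaustive
  all_idx <- sort(c(p$train, p$validation, p$test))
  expect_identical(all_idx, 1:150)
  expect_identical(split_data(150, seed = 7), split_data(150, seed = 7))
  expect_false(identical(split_data(150, seed = 7), split_data(150, seed = 8)))
  expect_error(split_data(5, c(train = 0.9, validation = 0.02, test = 0.08)),
               "empty split")
  expect_error(split_data(10, c(train = 0.5, validation = 0.2, test = 0.2)),
               "sum to 1")
})

test_that("metrics implement the five criteria and their identities", {
  m <- metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(as.numeric(m[c("r", "r2", "mse", "rmse", "mae")]),
               c(1, 1, 0, 0, 0))
  m2 <- metrics(c(1, 2, 3), c(2, 3, 4))
  expect_equal(as.numeric(m2[c("r", "mse", "mae")]), c(1, 1, 1))
  m3 <- metrics(c(0, 0, 2, 2), c(1, 1, 1, 1.0000001))
  expect_equal(m3$mse, mean(c(1, 1, 1, (1 - 2.0000001)^2)), tolerance = 1e-6)
  # constant input: r flagged undefined with a warning
  expect_warning(mc <- metrics(c(0, 0, 2, 2), c(0, 0, 0, 0)), "undefined")
  expect_true(is.na(mc$r))
  expect_equal(mc$mse, 2)
  expect_equal(mc$rmse, sqrt(2))
  expect_equal(mc$mae, 1)
  expect_error(metrics(1:3, 1:4), "equal")

  # identities on random pairs: rmse^2 = mse, mae <= rmse, r in [-1,1],
  # r invariant to positive-slope affine maps of predictions
  nirfruit:::with_seed(12, {
    for (i in 1:10) {
      yt <- stats::rnorm(25)
      yp <- yt + stats::rnorm(25)
      mm <- metrics(yt, yp)
      expect_equal(mm$rmse^2, mm$mse, tolerance = 1e-12)
      expect_lte(mm$mae, mm$rmse)
      expect_true(mm$r >= -1 && mm$r <= 1)
      expect_equal(metrics(yt, 2.5 * yp + 1)$r, mm$r, tolerance = 1e-12)
    }
  })
})

test_that("repeated evaluation is seeded, tolerant of failures, and summarizable", {
  nirfruit:::with_seed(2, {
    X <- matrix(stats::rnorm(200), 50, 4)
    y <- as.numeric(X %*% c(1, 1, 1, 1) + stats::rnorm(50))
  })
  # near-mean pipeline: r should hover near zero
  mean_pipe <- function(X_train, y_train, X_val, y_val, seed) {
    mu <- mean(y_train)
    function(X_new) mu + 1e-6 * X_new[, 1]
  }
  d <- repeated_evaluation(X, y, mean_pipe, n_iter = 3L, base_seed = 10L)
  expect_equal(nrow(d$records), 3L)
  expect_true(all(is.finite(d$records$mse)))
  expect_lt(max(abs(d$records$r)), 0.6)

  d2 <- repeated_evaluation(X, y, mean_pipe, n_iter = 3L, base_seed = 10L)
  expect_identical(d$records, d2$records)

  # a failing iteration is excluded with a count, not fatal
  flaky <- function(X_train, y_train, X_val, y_val, seed) {
    if (seed %% 2 == 0) stop("boom")
    function(X_new) mean(y_train) + 1e-6 * X_new[, 1]
  }
  expect_message(df <- repeated_evaluation(X, y, flaky, n_iter = 4L, base_seed = 0L),
                 "failed")
  expect_equal(df$n_failed, 2L)
  expect_equal(nrow(df$records), 2L)
})

test_that("summaries expose mean/sd, quartiles and the best-training row", {
  nirfruit:::with_seed(3, {
    X <- matrix(stats::rnorm(400), 100, 4)
    y <- as.numeric(X %*% c(2, -1, 1, 0.5) + 0.5 * stats::rnorm(100))
  })
  pipe <- plsr_pipeline(max_components = 4L)
  d <- repeated_evaluation(X, y, pipe, n_iter = 8L, base_seed = 1L)
  s <- summarize_evaluation(d)
  expect_setequal(rownames(s),
                  c("mean", "sd", "min", "q1", "median", "q3", "max", "best"))
  expect_true(all(s["q1", ] <= s["median", ] & s["median", ] <= s["q3", ]))
  expect_equal(s["best", "mse"], min(d$records$mse))
  expect_lte(s["best", "mse"], s["mean", "mse"])
  expect_equal(s["best", "rmse"]^2, s["best", "mse"], tolerance = 1e-12)
  # best seed attribution points at the minimal-MSE iteration
  bs <- attr(s, "best_seed")
  expect_equal(d$records$mse[d$records$seed == bs], min(d$records$mse))

  # identical records degenerate to sd 0 and best = the record
  done <- d
  done$records <- d$records[rep(1, 4), ]
  s0 <- summarize_evaluation(done)
  expect_equal(unname(unlist(s0["sd", ])), rep(0, 5))
  expect_equal(s0["best", "mse"], d$records$mse[1])

  # box-plot statistics export round trip
  path <- withr::local_tempfile(fileext = ".json")
  boxplot_stats(d, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$mse[["median"]], s["median", "mse"], tolerance = 1e-12)
})
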