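#' Random train/validation/test split
#'
#' Uniform random permutation partitioned by largest-remainder rounding of
#' the fractions (so part sizes always sum to \code{n}), reproducible per
#' seed.  Defaults mirror the repeated-evaluation design: 60\% train,
#' 10\% validation, 30\% test.
#'
#' @param n sample count
#' @param fractions named numeric vector \code{c(train=, validation=, test=)}
#'   summing to 1
#' @param seed permutation seed
#' @return an object of class \code{split_plan}: list with integer index
#'   vectors \code{train}, \code{validation}, \code{test}
#' @export
split_data <- function(n, fractions = c(train = 0.60, validation = 0.10, test = 0.30),
                       seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  sizes <- floor(n * fractions)
  rem <- n * fractions - sizes
  short <- n - sum(sizes)
  if (short > 0L) {
    for (j in order(rem, decreasing = TRUE)[seq_len(short)]) sizes[j] <- sizes[j] + 1L
  }
  if (any(sizes < 1L)) {
    stop("empty split part: n = ", n, " gives sizes ",
         paste(sizes, collapse = "/"))
  }
  perm <- with_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  out <- list(train = sort(perm[seq_len(ends[1L])]),
              validation = sort(perm[(ends[1L] + 1L):ends[2L]]),
              test = sort(perm[(ends[2L] + 1L):ends[3L]]),
              fractions = fractions, seed = seed)
  class(out) <- "split_plan"
  out
}

#' Test-set performance metrics
#'
#' The five evaluation criteria: Pearson correlation R, coefficient of
#' determination R^2 (defined as R squared, consistent with paired R/R^2
#' reporting; the 1 - SSres/SStot variant is also returned as
#' \code{r2_ss}), MSE, RMSE and MAE, all in target units.
#'
#' @param y_true,y_pred equal-length numeric vectors
#' @return one-row data.frame with columns r, r2, mse, rmse, mae, r2_ss
#' @export
metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal nonzero lengths")
  }
  err <- y_pred - y_true
  mse <- mean(err^2)
  r <- if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    warning("correlation undefined for constant input; r reported as NA")
    NA_real_
  } else {
    stats::cor(y_true, y_pred)
  }
  sst <- sum((y_true - mean(y_true))^2)
  r2_ss <- if (sst == 0) NA_real_ else 1 - sum(err^2) / sst
  data.frame(r = r, r2 = r^2, mse = mse, rmse = sqrt(mse),
             mae = mean(abs(err)), r2_ss = r2_ss)
}

#' Repeated random-split evaluation
#'
#' Runs \code{n_iter} independent evaluations: iteration \code{i} splits
#' the data with seed \code{base_seed + i}, hands the pipeline the train
#' and validation parts, and scores its predictions on the test part.
#' Failed iterations are recorded and excluded from summaries with a
#' count, rather than aborting a long campaign.  The paper-scale design
#' is 500 iterations; tests use a scaled-down count.
#'
#' @param X predictor matrix
#' @param y target vector
#' @param pipeline function \code{(X_train, y_train, X_val, y_val, seed)}
#'   returning a prediction function \code{(X_new) -> numeric}
#' @param n_iter iteration count (paper scale: 500)
#' @param base_seed seed offset; iteration i uses seed base_seed + i
#' @param fractions passed to \code{\link{split_data}}
#' @param method label stored with the distribution (e.g. "ann-ica", "plsr")
#' @return an object of class \code{eval_distribution}: list with
#'   \code{records} (per-iteration metrics data.frame with iteration and
#'   seed columns), \code{n_failed}, \code{method}
#' @export
repeated_evaluation <- function(X, y, pipeline, n_iter = 500L, base_seed = 0L,
                                fractions = c(train = 0.60, validation = 0.10,
                                              test = 0.30),
                                method = "pipeline") {
  X <- as.matrix(X); y <- as.numeric(y)
  recs <- vector("list", n_iter)
  failed <- 0L
  for (i in seq_len(n_iter)) {
    seed <- base_seed + i
    plan <- split_data(nrow(X), fractions, seed = seed)
    rec <- tryCatch({
      pred_fn <- pipeline(X[plan$train, , drop = FALSE], y[plan$train],
                          X[plan$validation, , drop = FALSE], y[plan$validation],
                          seed)
      p <- pred_fn(X[plan$test, , drop = FALSE])
      m <- metrics(y[plan$test], p)
      if (!all(is.finite(as.numeric(m[1L, c("r", "mse", "rmse", "mae")])))) {
        stop("non-finite metrics")
      }
      cbind(iteration = i, seed = seed, m)
    }, error = function(e) NULL)
    if (is.null(rec)) failed <- failed + 1L else recs[[i]] <- rec
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1L))])
  if (failed > 0L) message(failed, " of ", n_iter, " iterations failed and were excluded")
  structure(list(records = records, n_iter = n_iter, n_failed = failed,
                 base_seed = base_seed, method = method),
            class = "eval_distribution")
}

#' Summarize a repeated-evaluation distribution
#'
#' Per metric: mean, SD, quartiles (box-plot statistics), and the "best
#' training" row, defined as the iteration with minimal test MSE.
#'
#' @param d an \code{eval_distribution}
#' @return data.frame with rows mean, sd, min, q1, median, q3, max, best;
#'   the best iteration's seed is attached as attribute \code{best_seed}
#' @export
summarize_evaluation <- function(d) {
  stopifnot(inherits(d, "eval_distribution"))
  recs <- d$records
  if (is.null(recs) || nrow(recs) == 0L) stop("no successful iterations to summarize")
  cols <- c("mse", "rmse", "mae", "r", "r2")
  M <- as.matrix(recs[, cols])
  stat <- function(f) apply(M, 2L, f)
  best_i <- which.min(recs$mse)
  out <- rbind(mean = stat(mean), sd = stat(stats::sd), min = stat(min),
               q1 = stat(function(x) stats::quantile(x, 0.25, names = FALSE)),
               median = stat(stats::median),
               q3 = stat(function(x) stats::quantile(x, 0.75, names = FALSE)),
               max = stat(max), best = M[best_i, ])
  out <- as.data.frame(out)
  attr(out, "best_seed") <- recs$seed[best_i]
  attr(out, "best_iteration") <- recs$iteration[best_i]
  out
}

#' @export
print.eval_distribution <- function(x, ...) {
  cat("eval_distribution:", x$method, "-",
      if (is.null(x$records)) 0L else nrow(x$records), "successful of",
      x$n_iter, "iterations\n")
  if (!is.null(x$records)) print(summarize_evaluation(x)[c("mean", "sd", "best"), ])
  invisible(x)
}

#' Export box-plot statistics
#'
#' @param d an \code{eval_distribution}
#' @param path JSON output path
#' @return the statistics list, invisibly
#' @export
boxplot_stats <- function(d, path = NULL) {
  s <- summarize_evaluation(d)
  rows <- c("min", "q1", "median", "q3", "max")
  out <- lapply(names(s), function(m) as.list(stats::setNames(s[rows, m], rows)))
  names(out) <- names(s)
  if (!is.null(path)) jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
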