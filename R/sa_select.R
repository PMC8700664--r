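#' Simulated-annealing configuration
#'
#' Metropolis acceptance with geometric cooling.  When \code{t_init} is
#' NULL it is set at run time to the standard deviation of the objective
#' over 20 random subsets (a common self-scaling rule), and \code{t_min}
#' to \code{t_init/100}.
#'
#' @param subset_size wavelengths to select (fixed at 4 by default,
#'   matching the four key wavelengths reported per property)
#' @param t_init initial temperature (NULL = auto-scale)
#' @param cooling geometric cooling factor in (0,1)
#' @param steps_per_temp proposals per temperature level
#' @param t_min stopping temperature (NULL = t_init/100)
#' @param seed RNG seed for the whole walk
#' @return an object of class \code{sa_config}
#' @export
sa_config <- function(subset_size = 4L, t_init = NULL, cooling = 0.95,
                      steps_per_temp = 20L, t_min = NULL, seed = 1L) {
  if (subset_size < 1L) stop("subset_size must be >= 1")
  if (cooling <= 0 || cooling >= 1) stop("cooling must be in (0, 1)")
  if (!is.null(t_init) && !is.null(t_min) &&
      !(t_init > t_min && t_min > 0)) {
    stop("need t_init > t_min > 0")
  }
  structure(list(subset_size = as.integer(subset_size), t_init = t_init,
                 cooling = cooling, steps_per_temp = as.integer(steps_per_temp),
                 t_min = t_min, seed = as.integer(seed)),
            class = "sa_config")
}

#' Metropolis acceptance probability
#'
#' 1 for improving moves, \eqn{e^{-\Delta/T}} for worsening ones.
#'
#' @param delta objective change (candidate minus current)
#' @param t temperature (> 0)
#' @return acceptance probability in [0, 1]
#' @export
acceptance_probability <- function(delta, t) {
  if (any(t <= 0)) stop("temperature must be positive")
  ifelse(delta <= 0, 1, exp(-delta / t))
}

#' Single-swap neighbour of a wavelength subset
#'
#' Swaps exactly one selected index for one unselected index, both chosen
#' uniformly; subset size is preserved.  Uses the caller's RNG stream.
#'
#' @param indices sorted integer indices of the current subset
#' @param grid_len total wavelength count
#' @return sorted integer indices of the neighbour
#' @export
propose_neighbor <- function(indices, grid_len) {
  if (length(indices) >= grid_len) stop("subset already covers the grid")
  out_pool <- setdiff(seq_len(grid_len), indices)
  drop <- indices[sample.int(length(indices), 1L)]
  add <- out_pool[sample.int(length(out_pool), 1L)]
  sort(c(setdiff(indices, drop), add))
}

# Generic SA core over fixed-size index subsets, memoized objective.
# Returns indices, objective, evaluation count and the accepted-move trace.
sa_optimize <- function(objective, grid_len, cfg, memo = NULL) {
  k <- cfg$subset_size
  if (k > grid_len) stop("subset_size exceeds grid length")
  if (is.null(memo)) memo <- new.env(parent = emptyenv())
  n_eval <- 0L
  score <- function(idx) {
    key <- paste(idx, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- objective(idx)
    n_eval <<- n_eval + 1L
    memo[[key]] <- v
    v
  }
  with_seed(cfg$seed, {
    if (k == grid_len) { # only one subset exists: no search
      idx <- seq_len(grid_len)
      return(list(indices = idx, objective = score(idx), n_eval = n_eval,
                  history = data.frame(step = 0L, t = NA_real_,
                                       current = score(idx), best = score(idx))))
    }
    current <- sort(sample.int(grid_len, k))
    cur_obj <- score(current)
    t_init <- cfg$t_init
    if (is.null(t_init)) {
      # auto-scale: sd of the objective over 20 random subsets; start the
      # walk from the best probe seen
      probe_sets <- lapply(seq_len(20L), function(i) sort(sample.int(grid_len, k)))
      probes <- vapply(probe_sets, score, numeric(1L))
      t_init <- stats::sd(probes)
      if (!is.finite(t_init) || t_init <= 0) t_init <- max(abs(cur_obj), 1e-6)
      if (min(probes) < cur_obj) {
        current <- probe_sets[[which.min(probes)]]
        cur_obj <- min(probes)
      }
    }
    t_min <- if (is.null(cfg$t_min)) t_init / 100 else cfg$t_min
    best <- current; best_obj <- cur_obj
    hist <- list()
    step <- 0L
    t <- t_init
    while (t > t_min) {
      for (i in seq_len(cfg$steps_per_temp)) {
        step <- step + 1L
        cand <- propose_neighbor(current, grid_len)
        cand_obj <- score(cand)
        if (stats::runif(1L) < acceptance_probability(cand_obj - cur_obj, t)) {
          current <- cand; cur_obj <- cand_obj
          if (cur_obj < best_obj) { best <- current; best_obj <- cur_obj }
          hist[[length(hist) + 1L]] <-
            data.frame(step = step, t = t, current = cur_obj, best = best_obj)
        }
      }
      t <- t * cfg$cooling
    }
    list(indices = best, objective = best_obj, n_eval = n_eval,
         history = do.call(rbind, hist))
  })
}

#' Select key wavelengths by simulated annealing
#'
#' Metropolis walk over fixed-size wavelength subsets with geometric
#' cooling.  The objective of a subset is the fixed-fold cross-validated
#' MSE of the fixed selector network (2 hidden layers of 13 and 23
#' neurons, radbas/logsig transfers, incremental \code{trains} training
#' with \code{learnh}) trained on the subset's columns; folds and
#' training seeds derive from one fixed seed and values are memoized, so
#' the objective is a deterministic function of the subset.  Ties are
#' broken by first arrival.  Returns the best-ever subset.
#'
#' @param s a preprocessed absorbance \code{\link{spectra_set}}
#' @param target numeric response (TSS or BrimA), one value per sample
#' @param sa an \code{\link{sa_config}}
#' @param ann the objective network structure; default is the fixed
#'   selector network described above
#' @param objective optional replacement objective
#'   \code{function(indices) -> value}, used by tests against exhaustive
#'   oracles; NULL means the ANN objective
#' @param max_epochs,lr training budget per objective evaluation
#' @param obj_seed fixed seed for the inner folds and network init
#' @param n_folds fixed CV folds of the objective
#' @param memo optional environment shared across runs to cache objective
#'   values (the objective is deterministic, so sharing only avoids
#'   recomputation)
#' @return an object of class \code{wavelength_subset}: sorted
#'   \code{indices}, \code{wavelengths} (nm), achieved \code{objective}
#'   (MSE), evaluation count and the accepted-move \code{history}
#' @export
sa_select_wavelengths <- function(s, target, sa = sa_config(),
                                  ann = ann_config(n_layers = 2L,
                                                   neurons = c(13L, 23L),
                                                   transfer = c("radbas", "logsig"),
                                                   train_method = "trains",
                                                   learn_method = "learnh"),
                                  objective = NULL,
                                  max_epochs = 40L, lr = 0.1,
                                  obj_seed = 101L, n_folds = 3L,
                                  memo = NULL) {
  stopifnot(inherits(s, "spectra_set"), inherits(sa, "sa_config"))
  X <- s$intensities
  target <- as.numeric(target)
  if (nrow(X) != length(target)) stop("target length must equal sample count")
  if (is.null(objective)) {
    objective <- function(idx) {
      ann_cv_objective(X[, idx, drop = FALSE], target, ann, seed = obj_seed,
                       n_folds = n_folds, max_epochs = max_epochs, lr = lr)
    }
  }
  res <- sa_optimize(objective, ncol(X), sa, memo = memo)
  structure(list(indices = res$indices, wavelengths = s$grid[res$indices],
                 objective = res$objective, n_eval = res$n_eval,
                 history = res$history, config = sa),
            class = "wavelength_subset")
}

#' @export
print.wavelength_subset <- function(x, ...) {
  cat("wavelength_subset:", paste(x$wavelengths, collapse = ", "),
      "nm\n  objective (MSE):", format(x$objective), " evaluations:", x$n_eval, "\n")
  invisible(x)
}

#' Save a wavelength subset as JSON
#' @param ws a \code{wavelength_subset}
#' @param path file path
#' @export
save_subset <- function(ws, path) {
  jsonlite::write_json(list(wavelengths_nm = ws$wavelengths, indices = ws$indices,
                            objective = ws$objective, config = unclass(ws$config)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
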