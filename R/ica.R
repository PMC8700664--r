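#' Imperialist-competitive-algorithm configuration
#'
#' Canonical defaults from the ICA literature: 50 countries, 5
#' imperialists, 100 decades, revolution rate 0.2, assimilation
#' coefficient beta = 2, colony-cost weight zeta = 0.05.
#'
#' @param n_countries population size
#' @param n_imperialists empire count (>= 1, < n_countries)
#' @param max_decades iteration budget
#' @param revolution_rate per-colony probability of re-randomization
#' @param beta assimilation coefficient (> 0)
#' @param zeta colony-cost weight in empire power, in [0, 1]
#' @param seed RNG seed
#' @param stop_at_unification classic ICA stops once a single empire
#'   remains; on discrete cost surfaces with many ties unification happens
#'   within a few decades, so by default the unified empire keeps
#'   assimilating and revolving until \code{max_decades} (see the methods
#'   vignette)
#' @return an object of class \code{ica_config}
#' @export
ica_config <- function(n_countries = 50L, n_imperialists = 5L,
                       max_decades = 100L, revolution_rate = 0.2,
                       beta = 2, zeta = 0.05, seed = 1L,
                       stop_at_unification = FALSE) {
  if (!(n_imperialists >= 1L && n_imperialists < n_countries)) {
    stop("need 1 <= n_imperialists < n_countries")
  }
  if (revolution_rate < 0 || revolution_rate > 1) stop("revolution_rate must be in [0, 1]")
  if (beta <= 0) stop("beta must be positive")
  if (zeta < 0 || zeta > 1) stop("zeta must be in [0, 1]")
  structure(list(n_countries = as.integer(n_countries),
                 n_imperialists = as.integer(n_imperialists),
                 max_decades = as.integer(max_decades),
                 revolution_rate = revolution_rate, beta = beta, zeta = zeta,
                 seed = as.integer(seed),
                 stop_at_unification = isTRUE(stop_at_unification)),
            class = "ica_config")
}

#' Search-space dimension constructors
#'
#' A search space is a named list of dimensions: integer ranges,
#' categorical sets, or real intervals (real dimensions exist for
#' continuous sanity checks; the network space is integer/categorical).
#'
#' @param lo,hi bounds
#' @param values categorical levels
#' @return a dimension descriptor
#' @export
dim_int <- function(lo, hi) {
  stopifnot(lo <= hi)
  list(type = "int", lo = as.integer(lo), hi = as.integer(hi))
}

#' @rdname dim_int
#' @export
dim_cat <- function(values) list(type = "cat", values = values)

#' @rdname dim_int
#' @export
dim_real <- function(lo, hi) {
  stopifnot(lo < hi)
  list(type = "real", lo = lo, hi = hi)
}

.space_sample <- function(space) {
  lapply(space, function(d) switch(d$type,
    int = d$lo + sample.int(d$hi - d$lo + 1L, 1L) - 1L,
    cat = d$values[[sample.int(length(d$values), 1L)]],
    real = stats::runif(1L, d$lo, d$hi)))
}

# mixed-space assimilation: each slot moves toward the imperialist's slot
# with probability min(1, beta*U); integers take the classic fractional
# move x + beta*U*(imp - x) rounded to the grid (a step toward, centred
# on the imperialist for beta = 2), categoricals copy, reals move
# fractionally without rounding
.assimilate <- function(pos, imp, space, beta) {
  for (nm in names(space)) {
    d <- space[[nm]]
    if (d$type == "real") {
      pos[[nm]] <- pos[[nm]] + beta * stats::runif(1L) * (imp[[nm]] - pos[[nm]])
      pos[[nm]] <- min(max(pos[[nm]], d$lo), d$hi)
    } else if (stats::runif(1L) < min(1, beta * stats::runif(1L))) {
      if (d$type == "int") {
        step <- as.integer(round(beta * stats::runif(1L) * (imp[[nm]] - pos[[nm]])))
        pos[[nm]] <- min(max(pos[[nm]] + step, d$lo), d$hi)
      } else {
        pos[[nm]] <- imp[[nm]]
      }
    }
  }
  pos
}

.pos_key <- function(pos) paste(vapply(pos, function(v) paste(format(v), collapse = ","),
                                       character(1L)), collapse = "|")

#' Imperialist competitive algorithm over a mixed search space
#'
#' Minimizes \code{cost} over integer/categorical/real dimensions.
#' Initialization draws countries uniformly; the lowest-cost
#' \code{n_imperialists} become imperialists and colonies are distributed
#' proportionally to normalized imperialist power.  Each decade applies
#' assimilation, revolution, colony/imperialist position exchange, and
#' imperialistic competition (the weakest empire's weakest colony moves
#' to a power-proportionally chosen winner; an empire that loses its last
#' colony collapses, its imperialist becoming a colony).  Stops at
#' \code{max_decades} or when a single empire remains.
#'
#' @param cost function of a position (named list over space dims)
#'   returning a finite value (or \code{Inf} for infeasible positions)
#' @param space named list of dimensions from \code{\link{dim_int}},
#'   \code{\link{dim_cat}}, \code{\link{dim_real}}
#' @param cfg an \code{\link{ica_config}}
#' @return list with \code{best} (position), \code{best_cost},
#'   \code{n_eval}, and a per-decade \code{history} data.frame
#'   (decade, best_cost, mean_cost, n_empires)
#' @export
ica_optimize <- function(cost, space, cfg = ica_config()) {
  stopifnot(inherits(cfg, "ica_config"), length(space) >= 1L)
  memo <- new.env(parent = emptyenv())
  n_eval <- 0L
  score <- function(pos) {
    key <- .pos_key(pos)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- cost(pos)
    n_eval <<- n_eval + 1L
    if (is.na(v)) stop("cost returned NA at position ", key)
    memo[[key]] <- v
    v
  }
  with_seed(cfg$seed, {
    positions <- lapply(seq_len(cfg$n_countries), function(i) .space_sample(space))
    costs <- vapply(positions, score, numeric(1L))
    ord <- order(costs)
    imp_idx <- ord[seq_len(cfg$n_imperialists)]
    col_idx <- ord[-seq_len(cfg$n_imperialists)]
    # colony shares proportional to normalized imperialist power
    imp_cost <- costs[imp_idx]
    # infeasible (Inf-cost) imperialists get zero share
    cap <- if (any(is.finite(imp_cost))) max(imp_cost[is.finite(imp_cost)]) else 1
    imp_cost[!is.finite(imp_cost)] <- cap
    power <- cap - imp_cost
    if (all(power == 0)) power <- rep(1, length(power))
    share <- power / sum(power)
    n_col <- length(col_idx)
    counts <- floor(share * n_col)
    left <- n_col - sum(counts)
    if (left > 0L) {
      extra <- order(share * n_col - counts, decreasing = TRUE)[seq_len(left)]
      counts[extra] <- counts[extra] + 1L
    }
    shuffled <- sample(col_idx)
    empire_of <- integer(cfg$n_countries)
    empire_of[imp_idx] <- seq_along(imp_idx)
    k <- 1L
    for (e in seq_along(imp_idx)) {
      if (counts[e] > 0L) {
        empire_of[shuffled[k:(k + counts[e] - 1L)]] <- e
        k <- k + counts[e]
      }
    }
    role <- ifelse(seq_len(cfg$n_countries) %in% imp_idx, "imperialist", "colony")
    imp_of_empire <- imp_idx  # country index of each empire's imperialist
    alive <- rep(TRUE, length(imp_of_empire))

    best_i <- which.min(costs)
    best <- positions[[best_i]]; best_cost <- costs[best_i]
    hist <- vector("list", cfg$max_decades)

    for (decade in seq_len(cfg$max_decades)) {
      for (e in which(alive)) {
        imp_c <- imp_of_empire[e]
        cols <- which(empire_of == e & role == "colony")
        for (ci in cols) {
          positions[[ci]] <- .assimilate(positions[[ci]], positions[[imp_c]],
                                         space, cfg$beta)
          # revolution, discrete adaptation: each slot re-randomized
          # independently (rate 1 = full re-randomization = random search)
          rev_slots <- stats::runif(length(space)) < cfg$revolution_rate
          if (any(rev_slots)) {
            fresh <- .space_sample(space)
            positions[[ci]][rev_slots] <- fresh[rev_slots]
          }
          costs[ci] <- score(positions[[ci]])
          if (costs[ci] < best_cost) { best <- positions[[ci]]; best_cost <- costs[ci] }
          if (costs[ci] < costs[imp_c]) { # colony overthrows its imperialist
            role[ci] <- "imperialist"; role[imp_c] <- "colony"
            imp_of_empire[e] <- ci
            imp_c <- ci
          }
        }
      }
      # imperialistic competition
      live <- which(alive)
      if (length(live) > 1L) {
        tc <- vapply(live, function(e) {
          cols <- which(empire_of == e & role == "colony")
          costs[imp_of_empire[e]] +
            cfg$zeta * (if (length(cols)) mean(costs[cols]) else 0)
        }, numeric(1L))
        if (any(!is.finite(tc))) { # infeasible empires are the weakest
          tc[!is.finite(tc)] <- (if (any(is.finite(tc))) max(tc[is.finite(tc)]) else 0) + 1
        }
        weakest <- live[which.max(tc)]
        others <- setdiff(live, weakest)
        bid <- max(tc) - tc[match(others, live)] + 1e-12
        winner <- others[sample.int(length(others), 1L, prob = bid / sum(bid))]
        wcols <- which(empire_of == weakest & role == "colony")
        if (length(wcols)) {
          moved <- wcols[which.max(costs[wcols])]
          empire_of[moved] <- winner
        } else { # empire collapses: imperialist absorbed as a colony
          fallen <- imp_of_empire[weakest]
          role[fallen] <- "colony"
          empire_of[fallen] <- winner
          alive[weakest] <- FALSE
        }
      }
      hist[[decade]] <- data.frame(decade = decade, best_cost = best_cost,
                                   mean_cost = mean(costs[is.finite(costs)]),
                                   n_empires = sum(alive))
      if (cfg$stop_at_unification && sum(alive) == 1L) break
    }
    list(best = best, best_cost = best_cost, n_eval = n_eval,
         history = do.call(rbind, hist))
  })
}

#' Search space of network structures
#'
#' The five tunable structural dimensions: hidden-layer count (1-3),
#' neurons per layer (1-\code{max_neurons}; the default 25 covers the
#' observed tuned structures), transfer function per layer (full
#' catalog), training function and learning function.
#'
#' @param max_layers most hidden layers considered
#' @param max_neurons largest per-layer neuron count
#' @return named list of dimensions for \code{\link{ica_optimize}}
#' @export
ann_search_space <- function(max_layers = 3L, max_neurons = 25L) {
  space <- list(n_layers = dim_int(1L, max_layers))
  for (l in seq_len(max_layers)) {
    space[[paste0("neurons", l)]] <- dim_int(1L, max_neurons)
    space[[paste0("transfer", l)]] <- dim_cat(transfer_catalog())
  }
  space$train_method <- dim_cat(.train_catalog)
  space$learn_method <- dim_cat(.learn_catalog)
  space
}

#' Decode an ICA position into a network configuration
#'
#' Slots of layers beyond \code{n_layers} are inactive and ignored.
#'
#' @param pos named position list over \code{\link{ann_search_space}}
#' @return an \code{\link{ann_config}}
#' @export
decode_ann_position <- function(pos) {
  nl <- pos$n_layers
  ann_config(n_layers = nl,
             neurons = vapply(seq_len(nl), function(l) as.integer(pos[[paste0("neurons", l)]]), integer(1L)),
             transfer = vapply(seq_len(nl), function(l) pos[[paste0("transfer", l)]], character(1L)),
             train_method = pos$train_method,
             learn_method = pos$learn_method)
}

#' Tune the network structure with the imperialist competitive algorithm
#'
#' The cost of a country is the fixed-fold cross-validated MSE of its
#' decoded structure (folds and training seeds derived from
#' \code{obj_seed}; memoized on the decoded configuration, so inactive
#' layer slots do not fragment the cache).  Averaging over folds keeps
#' the winner's-curse bias of minimizing a noisy single-split estimate in
#' check.  A country whose training diverges receives cost \code{Inf}
#' and is never selected.
#'
#' @param s a \code{\link{spectra_set}} restricted to the selected
#'   wavelengths, or a plain numeric matrix
#' @param target numeric response vector
#' @param cfg an \code{\link{ica_config}}
#' @param space search space (default \code{\link{ann_search_space}()})
#' @param max_epochs,lr training budget per cost evaluation
#' @param obj_seed fixed seed for the inner folds and network init
#' @param n_folds fixed CV folds of the cost
#' @return list with \code{config} (tuned \code{\link{ann_config}}),
#'   \code{best_cost} and the decade \code{history}
#' @export
tune_ann <- function(s, target, cfg = ica_config(),
                     space = ann_search_space(),
                     max_epochs = 150L, lr = 0.05, obj_seed = 101L,
                     n_folds = 3L) {
  X <- if (inherits(s, "spectra_set")) s$intensities else as.matrix(s)
  target <- as.numeric(target)
  if (nrow(X) != length(target)) stop("target length must equal sample count")
  memo <- new.env(parent = emptyenv())
  cost <- function(pos) {
    ann <- decode_ann_position(pos)
    key <- paste(ann$n_layers, paste(ann$neurons, collapse = ","),
                 paste(ann$transfer, collapse = ","), ann$train_method,
                 ann$learn_method, sep = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- ann_cv_objective(X, target, ann, seed = obj_seed, n_folds = n_folds,
                          max_epochs = max_epochs, lr = lr, patience = 15L)
    memo[[key]] <- v
    v
  }
  res <- ica_optimize(cost, space, cfg)
  list(config = decode_ann_position(res$best), best_cost = res$best_cost,
       n_eval = res$n_eval, history = res$history)
}
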