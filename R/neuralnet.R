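#' @useDynLib nirfruit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# MATLAB-style transfer-function catalog shared by the network and the
# ICA search space.  ids index the compiled implementations.
.transfer_catalog <- c(
  logsig = 0L, radbas = 1L, satlins = 2L, hardlim = 3L,
  tribas = 4L, netinv = 5L, tansig = 6L, purelin = 7L
)
.train_catalog <- c("traingd", "traincgb", "trains")
.learn_catalog <- c("learnh", "learnsom")

#' Transfer functions of the network catalog
#'
#' Applies one of the MATLAB-named transfer functions elementwise:
#' \code{logsig} \eqn{1/(1+e^{-x})}, \code{radbas} \eqn{e^{-x^2}},
#' \code{satlins} (clamp to \eqn{[-1,1]}), \code{hardlim} (step at 0),
#' \code{tribas} \eqn{\max(0, 1-|x|)}, \code{netinv} \eqn{1/x} (guarded
#' at 0 by a sign-preserving \eqn{1/\epsilon}, \eqn{\epsilon=10^{-12}}),
#' \code{tansig} (hyperbolic tangent sigmoid), \code{purelin} (identity).
#' The names follow the MATLAB conventions they come from; this is a
#' semantic contract, not a bit-level compatibility promise.
#'
#' @param name one of \code{names(transfer_catalog())}
#' @param x numeric vector
#' @return numeric vector of the same length
#' @export
#' @examples
#' transfer("logsig", 0)   # 0.5
#' transfer("radbas", 0)   # 1
transfer <- function(name, x) {
  id <- .transfer_catalog[name]
  if (length(id) != 1L || is.na(id)) {
    stop("unknown transfer function '", name, "'; catalog: ",
         paste(names(.transfer_catalog), collapse = ", "))
  }
  out <- cpp_transfer(id, as.numeric(x))
  names(out) <- names(x)
  out
}

#' @rdname transfer
#' @export
transfer_catalog <- function() names(.transfer_catalog)

#' Network structure configuration
#'
#' The five structural parameters the imperialist competitive algorithm
#' tunes: hidden-layer count, neurons per hidden layer, transfer function
#' per hidden layer, the back-propagation training function and the
#' weight/bias learning function.  The output layer is always a single
#' linear (\code{purelin}) unit, as usual for regression.
#'
#' @param n_layers number of hidden layers (>= 1)
#' @param neurons integer vector of per-layer neuron counts, length \code{n_layers}
#' @param transfer character vector of per-layer transfer names, length \code{n_layers}
#' @param train_method one of \code{"traingd"} (batch gradient descent),
#'   \code{"traincgb"} (conjugate gradient with Powell-Beale restarts),
#'   \code{"trains"} (random-order incremental updates)
#' @param learn_method \code{"learnh"} or \code{"learnsom"}; applied only
#'   under \code{trains} as the per-sample update flavour, recorded but
#'   inert under the batch methods (see the methods vignette)
#' @return an object of class \code{ann_config}
#' @export
ann_config <- function(n_layers = length(neurons), neurons = 10L,
                       transfer = "logsig", train_method = "traincgb",
                       learn_method = "learnh") {
  neurons <- as.integer(neurons)
  if (length(transfer) == 1L && n_layers > 1L) transfer <- rep(transfer, n_layers)
  if (length(neurons) == 1L && n_layers > 1L) neurons <- rep(neurons, n_layers)
  if (length(neurons) != n_layers || length(transfer) != n_layers) {
    stop("neurons and transfer must each have length n_layers = ", n_layers)
  }
  if (any(neurons < 1L)) stop("every layer needs at least one neuron")
  bad <- setdiff(transfer, names(.transfer_catalog))
  if (length(bad)) stop("unknown transfer function(s): ", paste(bad, collapse = ", "))
  train_method <- match.arg(train_method, .train_catalog)
  learn_method <- match.arg(learn_method, .learn_catalog)
  structure(list(n_layers = as.integer(n_layers), neurons = neurons,
                 transfer = transfer, train_method = train_method,
                 learn_method = learn_method),
            class = "ann_config")
}

#' @export
print.ann_config <- function(x, ...) {
  cat("ANN structure:", x$n_layers, "hidden layer(s)\n")
  cat("  neurons:  ", paste(x$neurons, collapse = ", "), "\n")
  cat("  transfer: ", paste(x$transfer, collapse = ", "), "\n")
  cat("  training: ", x$train_method, " / ", x$learn_method, "\n", sep = "")
  invisible(x)
}

#' Initialize a network
#'
#' Reproducible uniform weight initialization scaled by fan-in.  Input and
#' target scaling parameters are fitted later, at training time, on the
#' training split only.
#'
#' @param cfg an \code{\link{ann_config}}
#' @param n_in,n_out input/output dimensions
#' @param seed integer seed; the same seed always yields identical weights
#' @return an object of class \code{ann_network}
#' @export
init_network <- function(cfg, n_in, n_out = 1L, seed = 1L) {
  stopifnot(inherits(cfg, "ann_config"), n_in >= 1L, n_out >= 1L)
  dims <- c(n_in, cfg$neurons, n_out)
  with_seed(seed, {
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(W)) {
      r <- 1 / sqrt(dims[l])
      W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -r, r), dims[l], dims[l + 1L])
      b[[l]] <- stats::runif(dims[l + 1L], -r, r)
    }
    structure(list(config = cfg, W = W, b = b,
                   n_in = as.integer(n_in), n_out = as.integer(n_out),
                   scaling = NULL, trained = FALSE),
              class = "ann_network")
  })
}

# transfer ids for all layers incl. the purelin output layer
.net_tf_ids <- function(net) {
  unname(c(.transfer_catalog[net$config$transfer], .transfer_catalog[["purelin"]]))
}

# min-max scaling to [-1, 1]; constant columns map to 0
.fit_scale <- function(M) {
  lo <- apply(M, 2L, min)
  hi <- apply(M, 2L, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, span = span)
}
.apply_scale <- function(M, s) {
  sweep(sweep(M, 2L, s$lo, "-"), 2L, s$span, "/") * 2 - 1
}
.invert_scale <- function(M, s) {
  sweep(sweep((M + 1) / 2, 2L, s$span, "*"), 2L, s$lo, "+")
}

#' Train a network
#'
#' Inputs and targets are min-max scaled to \eqn{[-1,1]} internally, with
#' the scaling fitted on the training split only.  Training stops at
#' \code{max_epochs} or when the monitored MSE (validation when a
#' validation split is given, otherwise training) fails to improve for
#' \code{patience} epochs; the best-monitored weights are returned.
#'
#' @param net an \code{\link{ann_network}}
#' @param X numeric matrix, samples x features
#' @param y numeric target vector, \code{nrow(X)} long
#' @param val optional list \code{list(X =, y =)} validation split
#' @param max_epochs epoch budget (0 returns \code{net} unchanged)
#' @param lr learning rate for \code{traingd}/\code{trains} (scaled space)
#' @param patience early-stopping window, epochs
#' @param seed seed for the sample-order shuffling of \code{trains}
#' @return list with elements \code{net} (trained \code{ann_network}) and
#'   \code{record} (epoch-wise train/validation MSE in scaled units, the
#'   stop reason and best epoch)
#' @export
train_network <- function(net, X, y, val = NULL, max_epochs = 1000L,
                          lr = 0.05, patience = 20L, seed = 1L) {
  stopifnot(inherits(net, "ann_network"))
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows must match y length")
  if (ncol(X) != net$n_in) stop("X has ", ncol(X), " columns; network expects ", net$n_in)
  if (max_epochs == 0L) {
    return(list(net = net, record = list(train_mse = numeric(0), val_mse = numeric(0),
                                         stop_reason = "zero_epochs", best_epoch = 0L)))
  }
  sx <- .fit_scale(X)
  sy <- .fit_scale(matrix(y, ncol = 1L))
  Xs <- .apply_scale(X, sx)
  Ys <- .apply_scale(matrix(y, ncol = 1L), sy)
  if (!is.null(val)) {
    Xv <- .apply_scale(as.matrix(val$X), sx)
    Yv <- .apply_scale(matrix(as.numeric(val$y), ncol = 1L), sy)
  } else {
    Xv <- matrix(0, 0L, ncol(X)); Yv <- matrix(0, 0L, 1L)
  }
  method <- match(net$config$train_method, .train_catalog) - 1L
  learn <- if (net$config$train_method == "trains") {
    match(net$config$learn_method, .learn_catalog)
  } else 0L
  fit <- cpp_mlp_train(net$W, net$b, .net_tf_ids(net), Xs, Ys, Xv, Yv,
                       method, learn, as.integer(max_epochs), lr,
                       as.integer(patience), as.integer(seed))
  if (grepl("^nonfinite_loss", fit$stop_reason)) {
    stop("training diverged (non-finite loss) at epoch ",
         sub("nonfinite_loss@", "", fit$stop_reason))
  }
  net$W <- fit$W
  net$b <- fit$b
  net$scaling <- list(x = sx, y = sy)
  net$trained <- TRUE
  record <- list(train_mse = fit$train_mse, val_mse = fit$val_mse,
                 stop_reason = fit$stop_reason, best_epoch = fit$best_epoch)
  list(net = net, record = record)
}

#' Predict from a trained network
#'
#' @param object an \code{ann_network} returned by \code{\link{train_network}}
#' @param X matrix with the same column count used at training
#' @param ... ignored
#' @return numeric vector of predictions in original target units
#' @export
predict.ann_network <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$n_in) stop("X has ", ncol(X), " columns; network expects ", object$n_in)
  if (is.null(object$scaling)) {
    # untrained network: raw forward pass (unscaled), mainly for testing
    return(as.numeric(cpp_mlp_forward(object$W, object$b, .net_tf_ids(object), X)))
  }
  Xs <- .apply_scale(X, object$scaling$x)
  P <- cpp_mlp_forward(object$W, object$b, .net_tf_ids(object), Xs)
  as.numeric(.invert_scale(P, object$scaling$y))
}

#' Network mean squared error in original units
#'
#' Same definition as \code{\link{metrics}()$mse}: mean of squared
#' prediction errors on the given data.
#'
#' @inheritParams predict.ann_network
#' @param net trained \code{ann_network}
#' @param y true targets
#' @return scalar MSE
#' @export
network_mse <- function(net, X, y) {
  p <- predict(net, X)
  mean((p - as.numeric(y))^2)
}

#' Save / load a network as JSON
#'
#' @param net an \code{ann_network}
#' @param path file path
#' @export
save_network <- function(net, path) {
  doc <- list(config = unclass(net$config),
              W = lapply(net$W, function(m) list(dim = dim(m), values = as.numeric(m))),
              b = net$b, n_in = net$n_in, n_out = net$n_out,
              scaling = net$scaling, trained = net$trained)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- ann_config(n_layers = doc$config$n_layers, neurons = doc$config$neurons,
                    transfer = doc$config$transfer,
                    train_method = doc$config$train_method,
                    learn_method = doc$config$learn_method)
  W <- if (is.data.frame(doc$W)) {
    lapply(seq_len(nrow(doc$W)), function(i) {
      matrix(doc$W$values[[i]], doc$W$dim[[i]][1], doc$W$dim[[i]][2])
    })
  } else {
    lapply(doc$W, function(w) matrix(w$values, w$dim[1], w$dim[2]))
  }
  scaling <- NULL
  if (!is.null(doc$scaling)) {
    scaling <- list(x = list(lo = doc$scaling$x$lo, span = doc$scaling$x$span),
                    y = list(lo = doc$scaling$y$lo, span = doc$scaling$y$span))
  }
  structure(list(config = cfg, W = W, b = lapply(doc$b, as.numeric),
                 n_in = as.integer(doc$n_in), n_out = as.integer(doc$n_out),
                 scaling = scaling, trained = isTRUE(doc$trained)),
            class = "ann_network")
}

# Fixed-fold cross-validated MSE objective used by the wavelength
# selector: folds and per-fold init/shuffle seeds are all derived from
# one fixed seed, so the objective is a deterministic function of
# (X columns, cfg), while averaging over folds keeps its noise well below
# the quality differences it must rank (a single 20% split cannot).
ann_cv_objective <- function(X, y, cfg, seed = 101L, n_folds = 3L,
                             max_epochs = 40L, lr = 0.1, patience = 10L) {
  n <- nrow(X)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  sse <- 0
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    net <- init_network(cfg, ncol(X), 1L, seed = seed + f)
    fit <- tryCatch(
      train_network(net, X[tr, , drop = FALSE], y[tr],
                    max_epochs = max_epochs, lr = lr, patience = patience,
                    seed = seed + f),
      error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    p <- predict(fit$net, X[!tr, , drop = FALSE])
    sse <- sse + sum((p - y[!tr])^2)
  }
  out <- sse / n
  if (!is.finite(out)) Inf else out
}
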