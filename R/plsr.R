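#' Partial least squares regression (NIPALS)
#'
#' Single-response PLS1 fitted by NIPALS deflation.  X and y are centered
#' with training statistics; X columns are additionally unit-variance
#' scaled by default (common chemometrics practice for spectral columns).
#' The returned coefficients map raw (unscaled) X to y.
#'
#' @param X numeric matrix, samples x wavelengths
#' @param y numeric response vector
#' @param n_components latent-variable count,
#'   \code{<= min(nrow(X) - 1, ncol(X))}
#' @param scale unit-variance scale X columns (default TRUE); constant
#'   columns are left unscaled
#' @return an object of class \code{plsr_model} with per-component
#'   x-weights \code{W}, x-scores \code{Tt}, x-loadings \code{P},
#'   y-loadings \code{q}, plus \code{coefficients} and \code{intercept}
#' @export
fit_plsr <- function(X, y, n_components, scale = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop("X rows must match y length")
  if (n < 2L) stop("need at least 2 samples")
  if (stats::var(y) == 0) stop("degenerate target: y has zero variance")
  kmax <- min(n - 1L, p)
  if (n_components < 1L || n_components > kmax) {
    stop("n_components must be in [1, ", kmax, "]")
  }
  x_center <- colMeans(X)
  x_scale <- rep(1, p)
  if (scale) {
    sds <- apply(X, 2L, stats::sd)
    x_scale[sds > 0] <- sds[sds > 0]
  }
  y_center <- mean(y)
  Xc <- sweep(sweep(X, 2L, x_center, "-"), 2L, x_scale, "/")
  yc <- y - y_center

  W <- P <- matrix(0, p, n_components)
  Tt <- matrix(0, n, n_components)
  q <- numeric(n_components)
  Xd <- Xc; yd <- yc
  for (k in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { # residual X carries no covariance with y
      W <- W[, seq_len(k - 1L), drop = FALSE]
      P <- P[, seq_len(k - 1L), drop = FALSE]
      Tt <- Tt[, seq_len(k - 1L), drop = FALSE]
      q <- q[seq_len(k - 1L)]
      n_components <- k - 1L
      break
    }
    w <- w / nw
    tt <- Xd %*% w
    tt2 <- sum(tt^2)
    pp <- crossprod(Xd, tt) / tt2
    qq <- sum(yd * tt) / tt2
    Xd <- Xd - tt %*% t(pp)
    yd <- yd - qq * tt
    W[, k] <- w; P[, k] <- pp; Tt[, k] <- tt; q[k] <- qq
  }
  # B maps centered/scaled X to centered y; fold the scaling back in
  B <- W %*% solve(crossprod(P, W), q)
  coef_raw <- as.numeric(B) / x_scale
  intercept <- y_center - sum(coef_raw * x_center)
  structure(list(n_components = n_components, W = W, P = P, Tt = Tt, q = q,
                 coefficients = coef_raw, intercept = intercept,
                 x_center = x_center, x_scale = x_scale, y_center = y_center,
                 x_residual = Xd),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("PLSR model:", x$n_components, "component(s),",
      length(x$coefficients), "predictors\n")
  invisible(x)
}

#' Predict from a PLSR model
#'
#' @param object a \code{plsr_model}
#' @param X matrix with the column count used at fit time
#' @param ... ignored
#' @return numeric predictions \code{intercept + X \%*\% coefficients}
#' @export
predict.plsr_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$coefficients)) {
    stop("X has ", ncol(X), " columns; model expects ", length(object$coefficients))
  }
  as.numeric(object$intercept + X %*% object$coefficients)
}

#' Cross-validated choice of the latent-variable count
#'
#' Seeded k-fold cross-validation; returns the smallest component count
#' whose CV-RMSE is within \code{tol} (relative) of the global minimum, a
#' standard parsimony rule.
#'
#' @inheritParams fit_plsr
#' @param max_components largest count to try
#' @param n_folds folds (>= 2)
#' @param seed fold-assignment seed
#' @param tol relative closeness to the minimum CV-RMSE (default 0.02)
#' @return integer component count
#' @export
choose_components <- function(X, y, max_components, n_folds = 5L, seed = 1L,
                              tol = 0.02, scale = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  kmax <- min(n - ceiling(n / n_folds) - 1L, ncol(X))
  if (max_components > kmax) {
    stop("max_components exceeds the bound ", kmax, " for this fold layout")
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  sse <- numeric(max_components)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    m <- fit_plsr(X[tr, , drop = FALSE], y[tr], max_components, scale = scale)
    for (k in seq_len(max_components)) {
      mk <- .plsr_truncate(m, k)
      pred <- predict(mk, X[!tr, , drop = FALSE])
      sse[k] <- sse[k] + sum((pred - y[!tr])^2)
    }
  }
  rmse <- sqrt(sse / n)
  best <- min(rmse)
  which(rmse <= best * (1 + tol))[1L]
}

# re-derive the coefficient vector from the first k components of a fit
.plsr_truncate <- function(m, k) {
  if (k >= m$n_components) return(m)
  W <- m$W[, seq_len(k), drop = FALSE]
  P <- m$P[, seq_len(k), drop = FALSE]
  q <- m$q[seq_len(k)]
  B <- W %*% solve(crossprod(P, W), q)
  coef_raw <- as.numeric(B) / m$x_scale
  m$coefficients <- coef_raw
  m$intercept <- m$y_center - sum(coef_raw * m$x_center)
  m$n_components <- k
  m
}

#' Save / load a PLSR model as JSON
#' @param m a \code{plsr_model}
#' @param path file path
#' @export
save_plsr <- function(m, path) {
  doc <- unclass(m)
  doc$W <- list(dim = dim(m$W), values = as.numeric(m$W))
  doc$P <- list(dim = dim(m$P), values = as.numeric(m$P))
  doc$Tt <- NULL; doc$x_residual <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_plsr
#' @export
load_plsr <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$W <- matrix(doc$W$values, doc$W$dim[1], doc$W$dim[2])
  doc$P <- matrix(doc$P$values, doc$P$dim[1], doc$P$dim[2])
  doc$Tt <- NULL
  structure(doc, class = "plsr_model")
}
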