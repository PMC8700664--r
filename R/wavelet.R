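# Orthogonal discrete wavelet transform with periodized boundaries.
# No wavelet package ships with the target environment, so the transform
# is implemented here.  For an orthonormal filter pair the periodized
# analysis operator is orthogonal, so the synthesis step is its exact
# transpose: perfect reconstruction to machine precision (tested).

# sym4 analysis low-pass (Daubechies least-asymmetric, 8 taps); the db2
# and haar filters are closed-form.
.wavelet_filters <- function(family) {
  h <- switch(family,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    sym4 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
             0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
             -0.012603967262037833, 0.0322231006040427),
    stop("unsupported wavelet family '", family, "'; catalog: haar, db2, sym4")
  )
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror high-pass
  list(h = h, g = g)
}

#' @rdname smooth_wavelet
#' @export
wavelet_catalog <- function() c("haar", "db2", "sym4")

# one periodized analysis step: even-length x -> list(approx, detail)
.dwt_step <- function(x, f) {
  n <- length(x)
  half <- n %/% 2L
  a <- numeric(half); d <- numeric(half)
  base <- (seq_len(half) - 1L) * 2L
  for (k in seq_along(f$h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    a <- a + f$h[k] * x[idx]
    d <- d + f$g[k] * x[idx]
  }
  list(a = a, d = d)
}

# transpose (= inverse, orthonormal case) of .dwt_step
.idwt_step <- function(a, d, f) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  base <- (seq_len(half) - 1L) * 2L
  for (k in seq_along(f$h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    contrib <- f$h[k] * a + f$g[k] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

# full decomposition of a vector whose length is divisible by 2^level
.dwt <- function(x, family, level) {
  f <- .wavelet_filters(family)
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    s <- .dwt_step(a, f)
    a <- s$a
    details[[l]] <- s$d
  }
  list(approx = a, details = details, family = family, level = level)
}

.idwt <- function(dec) {
  f <- .wavelet_filters(dec$family)
  a <- dec$approx
  for (l in rev(seq_len(dec$level))) a <- .idwt_step(a, dec$details[[l]], f)
  a
}

# denoise one row: symmetric extension to a 2^level-compatible length,
# periodized DWT, optional universal soft threshold, inverse, trim
.denoise_row <- function(x, family, level, threshold_rule) {
  n <- length(x)
  m <- 2L^level
  pad <- (m - n %% m) %% m
  if (pad > 0L) x <- c(x, x[seq(n, by = -1L, length.out = pad)])
  dec <- .dwt(x, family, level)
  if (threshold_rule == "universal") {
    d1 <- dec$details[[1L]]
    sigma <- stats::median(abs(d1)) / 0.6745
    thr <- sigma * sqrt(2 * log(length(x)))
    if (thr > 0) {
      dec$details <- lapply(dec$details, function(d) sign(d) * pmax(abs(d) - thr, 0))
    }
  }
  .idwt(dec)[seq_len(n)]
}
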