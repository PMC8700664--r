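#' Preprocessing configuration
#'
#' Settings for the fixed three-step noise pipeline applied to raw
#' reflectance spectra: (1) absorbance transform, (2) row-wise scatter /
#' baseline correction, (3) per-row wavelet denoising.
#'
#' @param scatter_method \code{"snv"} (standard normal variate, default),
#'   \code{"msc"} (multiplicative scatter correction against the mean
#'   spectrum) or \code{"none"}
#' @param wavelet_family \code{"sym4"} (default), \code{"db2"} or \code{"haar"}
#' @param wavelet_level decomposition depth (>= 1)
#' @param threshold_rule \code{"universal"} (VisuShrink soft threshold,
#'   default) or \code{"none"} (pure decompose/reconstruct)
#' @return an object of class \code{preprocess_config}
#' @export
preprocess_config <- function(scatter_method = c("snv", "msc", "none"),
                              wavelet_family = "sym4",
                              wavelet_level = 3L,
                              threshold_rule = c("universal", "none")) {
  scatter_method <- match.arg(scatter_method)
  threshold_rule <- match.arg(threshold_rule)
  if (!wavelet_family %in% wavelet_catalog()) {
    stop("unsupported wavelet family '", wavelet_family, "'")
  }
  wavelet_level <- as.integer(wavelet_level)
  if (wavelet_level < 1L) stop("wavelet_level must be >= 1")
  structure(list(scatter_method = scatter_method,
                 wavelet_family = wavelet_family,
                 wavelet_level = wavelet_level,
                 threshold_rule = threshold_rule),
            class = "preprocess_config")
}

#' Scatter and baseline correction
#'
#' Row-wise correction of multiplicative scatter and additive baseline on
#' absorbance spectra.  \code{snv} standardizes each row to zero mean and
#' unit standard deviation; \code{msc} regresses each row on the mean
#' spectrum and returns \code{(row - intercept)/slope}; \code{none} is the
#' identity.
#'
#' @param s an absorbance-mode \code{\link{spectra_set}}
#' @param method \code{"snv"}, \code{"msc"} or \code{"none"}
#' @return corrected \code{\link{spectra_set}}
#' @export
correct_scatter <- function(s, method = c("snv", "msc", "none")) {
  stopifnot(inherits(s, "spectra_set"))
  method <- match.arg(method)
  if (method == "none") return(s)
  if (s$mode != "absorbance") stop("scatter correction expects absorbance-mode spectra")
  M <- s$intensities
  if (method == "snv") {
    sds <- apply(M, 1L, stats::sd)
    if (any(sds == 0)) {
      stop("constant row under snv (zero variance): sample '",
           s$sample_ids[which(sds == 0)[1L]], "'")
    }
    M <- (M - rowMeans(M)) / sds
  } else {
    if (nrow(M) < 2L) stop("msc needs at least 2 samples (reference = mean spectrum)")
    ref <- colMeans(M)
    rc <- ref - mean(ref)
    denom <- sum(rc^2)
    for (i in seq_len(nrow(M))) {
      slope <- sum((M[i, ] - mean(M[i, ])) * rc) / denom
      if (slope == 0) stop("msc degenerate slope for sample '", s$sample_ids[i], "'")
      intercept <- mean(M[i, ]) - slope * mean(ref)
      M[i, ] <- (M[i, ] - intercept) / slope
    }
  }
  spectra_set(s$grid, M, sample_ids = s$sample_ids, mode = s$mode,
              scan_of = s$scan_of)
}

#' Wavelet denoising of spectra
#'
#' Per-row discrete wavelet decomposition to \code{wavelet_level},
#' soft-thresholding of the detail coefficients under the universal
#' (VisuShrink) rule, and reconstruction.  Rows are symmetrically
#' extended to a dyadic-compatible length, transformed with periodized
#' orthogonal filters (exact perfect reconstruction), then trimmed.
#'
#' @param s a \code{\link{spectra_set}}
#' @param cfg a \code{\link{preprocess_config}}
#' @return smoothed \code{\link{spectra_set}} on the same grid
#' @export
smooth_wavelet <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "spectra_set"), inherits(cfg, "preprocess_config"))
  if (length(s$grid) < 2L^cfg$wavelet_level) {
    stop("grid length ", length(s$grid), " is too short for wavelet level ",
         cfg$wavelet_level)
  }
  M <- t(apply(s$intensities, 1L, .denoise_row, family = cfg$wavelet_family,
               level = cfg$wavelet_level, threshold_rule = cfg$threshold_rule))
  spectra_set(s$grid, M, sample_ids = s$sample_ids, mode = s$mode,
              scan_of = s$scan_of)
}

#' Full preprocessing pipeline
#'
#' Fixed order: scan averaging (if the set is scan-level), absorbance
#' transform, scatter correction, wavelet smoothing.
#'
#' @param s a \code{\link{spectra_set}}; reflectance sets are converted,
#'   absorbance sets skip the transform
#' @param cfg a \code{\link{preprocess_config}}
#' @param scans_per_sample passed to \code{\link{average_scans}} when the
#'   set is scan-level
#' @return preprocessed absorbance \code{\link{spectra_set}}, one row per sample
#' @export
preprocess_spectra <- function(s, cfg = preprocess_config(), scans_per_sample = 5L) {
  stopifnot(inherits(s, "spectra_set"))
  if (!is.null(s$scan_of)) s <- average_scans(s, scans_per_sample)
  if (s$mode == "reflectance") s <- to_absorbance(s)
  s <- correct_scatter(s, cfg$scatter_method)
  smooth_wavelet(s, cfg)
}
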