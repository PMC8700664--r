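#' Spectral data container
#'
#' A \code{spectra_set} holds a wavelength grid (nm, strictly increasing),
#' a samples-by-wavelengths intensity matrix, sample identifiers and a
#' mode flag: \code{"reflectance"} (raw instrument output, all values
#' must be positive) or \code{"absorbance"} (\eqn{A = \log_{10}(1/R)},
#' the working representation for modeling).  Scan-level sets carry a
#' \code{scan_of} map from scan id to parent sample id, consumed by
#' \code{\link{average_scans}}.
#'
#' @param grid numeric vector of wavelengths in nm, strictly increasing
#' @param intensities numeric matrix, one row per sample/scan, one column
#'   per wavelength
#' @param sample_ids character vector of row identifiers
#' @param mode \code{"reflectance"} or \code{"absorbance"}
#' @param scan_of optional character vector mapping each row to its parent
#'   sample (scan-level sets)
#' @param bounds allowed wavelength range, nm
#' @return an object of class \code{spectra_set}
#' @export
spectra_set <- function(grid, intensities, sample_ids = NULL,
                        mode = c("reflectance", "absorbance"),
                        scan_of = NULL, bounds = c(200, 1100)) {
  mode <- match.arg(mode)
  grid <- as.numeric(grid)
  intensities <- as.matrix(intensities)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(intensities)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(intensities)))
  }
  if (any(diff(grid) <= 0)) stop("wavelength grid must be strictly increasing")
  if (any(grid < bounds[1] | grid > bounds[2])) {
    stop("wavelengths outside [", bounds[1], ", ", bounds[2], "] nm")
  }
  if (ncol(intensities) != length(grid)) {
    stop("intensity columns (", ncol(intensities), ") must match grid length (",
         length(grid), ")")
  }
  if (length(sample_ids) != nrow(intensities)) stop("sample_ids length mismatch")
  if (mode == "reflectance" && any(intensities <= 0)) {
    bad <- which(intensities <= 0, arr.ind = TRUE)[1L, ]
    stop("non-positive reflectance at sample '", sample_ids[bad[1L]],
         "', wavelength ", grid[bad[2L]], " nm (required for the absorbance transform)")
  }
  if (!is.null(scan_of) && length(scan_of) != nrow(intensities)) {
    stop("scan_of must map every row")
  }
  dimnames(intensities) <- list(sample_ids, format(grid, trim = TRUE))
  structure(list(grid = grid, intensities = intensities,
                 sample_ids = as.character(sample_ids), mode = mode,
                 scan_of = scan_of),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set:", nrow(x$intensities), "rows x", length(x$grid),
      "wavelengths (", min(x$grid), "-", max(x$grid), "nm ), mode =", x$mode, "\n")
  if (!is.null(x$scan_of)) cat("  scan-level set (", length(unique(x$scan_of)), "parent samples )\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$intensities)

#' Read a wide spectral table
#'
#' Expects a UTF-8 CSV whose first column is the sample id and whose
#' remaining column headers parse as wavelengths in nm ("." decimal
#' separator).  Columns are sorted by wavelength; row order is preserved.
#'
#' @param path CSV file path
#' @param mode \code{"reflectance"} or \code{"absorbance"}
#' @return a \code{\link{spectra_set}}
#' @export
read_spectra_table <- function(path, mode = c("reflectance", "absorbance")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("spectral table needs an id column plus wavelength columns")
  ids <- df[[1L]]
  wl <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (anyNA(wl)) {
    stop("non-numeric wavelength header(s): ",
         paste(names(df)[-1L][is.na(wl)], collapse = ", "))
  }
  if (anyDuplicated(wl)) {
    stop("duplicate wavelength header(s): ",
         paste(unique(wl[duplicated(wl)]), collapse = ", "))
  }
  M <- matrix(NA_real_, nrow(df), length(wl))
  for (j in seq_along(wl)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop("non-numeric value at row '", ids[i], "', column ", names(df)[j + 1L])
    }
    M[, j] <- v
  }
  ord <- order(wl)
  spectra_set(wl[ord], M[, ord, drop = FALSE], sample_ids = ids, mode = mode)
}

#' Write a spectra_set as a wide CSV
#'
#' Full stored precision (17 significant digits), so a read-back round
#' trip reproduces values exactly.
#'
#' @param s a \code{\link{spectra_set}}
#' @param path output CSV path
#' @export
write_spectra_table <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  df <- data.frame(id = s$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(apply(s$intensities, 2L, function(col) {
    formatC(col, digits = 17, format = "g")
  }, simplify = FALSE), check.names = FALSE, optional = TRUE)
  names(vals) <- format(s$grid, trim = TRUE)
  utils::write.csv(cbind(df, vals), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average repeated scans into one spectrum per sample
#'
#' Each sample's spectrum becomes the arithmetic mean of its scans; the
#' mode flag is unchanged.  Grouping uses the set's \code{scan_of} map
#' when present, otherwise consecutive blocks of \code{scans_per_sample}
#' rows.
#'
#' @param scans a scan-level \code{\link{spectra_set}}
#' @param scans_per_sample block size when no \code{scan_of} map exists
#' @return a \code{\link{spectra_set}} with one row per sample
#' @export
average_scans <- function(scans, scans_per_sample = 5L) {
  stopifnot(inherits(scans, "spectra_set"))
  n <- nrow(scans$intensities)
  if (!is.null(scans$scan_of)) {
    group <- scans$scan_of
  } else {
    if (n %% scans_per_sample != 0L) {
      stop(n, " scans are not divisible by scans_per_sample = ", scans_per_sample,
           " and no scan_of map is present")
    }
    block <- rep(seq_len(n %/% scans_per_sample), each = scans_per_sample)
    # derive parent ids from a trailing scan suffix when that leaves them unique
    parents <- sub("_s[0-9]+$", "", scans$sample_ids[!duplicated(block)])
    if (anyDuplicated(parents)) parents <- scans$sample_ids[!duplicated(block)]
    group <- parents[block]
  }
  keys <- unique(group)
  M <- matrix(NA_real_, length(keys), length(scans$grid))
  for (k in seq_along(keys)) {
    M[k, ] <- colMeans(scans$intensities[group == keys[k], , drop = FALSE])
  }
  if (anyDuplicated(keys)) stop("sample ids not unique after scan averaging")
  spectra_set(scans$grid, M, sample_ids = keys, mode = scans$mode)
}

#' Reflectance to absorbance
#'
#' Elementwise \eqn{A = \log_{10}(1/R)} (the Beer-Lambert convention).
#' Scan averaging must happen first: the pipeline averages scans in
#' reflectance space, then converts.
#'
#' @param s a reflectance-mode \code{\link{spectra_set}} with all values > 0
#' @return the same set in absorbance mode
#' @export
to_absorbance <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  if (s$mode != "reflectance") stop("spectra are already in absorbance mode")
  if (any(s$intensities <= 0)) {
    bad <- which(s$intensities <= 0, arr.ind = TRUE)[1L, ]
    stop("non-positive reflectance at sample '", s$sample_ids[bad[1L]],
         "', wavelength ", s$grid[bad[2L]], " nm")
  }
  spectra_set(s$grid, -log10(s$intensities), sample_ids = s$sample_ids,
              mode = "absorbance", scan_of = s$scan_of)
}
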