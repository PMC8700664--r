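#' Titratable acidity from an NaOH titration
#'
#' \deqn{TA\ (\%) = \frac{V_{NaOH} \cdot N_{NaOH} \cdot meq \cdot 100}{V_{juice}}}
#' where \eqn{V_{NaOH}} is the titrant volume (mL), \eqn{N_{NaOH}} its
#' normality (eq/L), \eqn{meq} the milliequivalent factor of the dominant
#' acid (g/meq; 0.067 for malic acid, the apple convention) and
#' \eqn{V_{juice}} the juice volume (mL).
#'
#' @param naoh_volume titrant volume, mL (>= 0)
#' @param naoh_normality titrant normality, eq/L (>= 0)
#' @param acid_meq_factor acid milliequivalent factor, g/meq
#' @param juice_volume juice volume, mL (> 0)
#' @return titratable acidity in percent
#' @export
#' @examples
#' titratable_acidity(3.0, 0.1, 0.067, 5.0)  # 0.402
titratable_acidity <- function(naoh_volume, naoh_normality,
                               acid_meq_factor = 0.067, juice_volume) {
  if (any(juice_volume <= 0)) stop("juice_volume must be positive")
  if (any(c(naoh_volume, naoh_normality, acid_meq_factor) < 0)) {
    stop("titration quantities must be non-negative")
  }
  naoh_volume * naoh_normality * acid_meq_factor * 100 / juice_volume
}

#' BrimA taste index
#'
#' \deqn{BrimA = TSS - K \cdot TA}
#' with TSS the total soluble solids (°Brix), TA the titratable acidity
#' (\%), and K the tongue's acid-sensitivity constant, conventionally 5
#' for pome fruit.
#'
#' @param tss total soluble solids, °Brix
#' @param ta titratable acidity, percent
#' @param k acid-sensitivity constant (default 5)
#' @return BrimA in °Brix-equivalent units
#' @export
#' @examples
#' brima(12.0, 0.4)  # 10
brima <- function(tss, ta, k = 5) {
  if (any(ta < 0)) stop("titratable acidity cannot be negative")
  tss - k * ta
}

#' Read a per-sample chemistry table
#'
#' CSV with columns \code{sample_id}, \code{tss} and either \code{ta}
#' directly or the raw titration columns \code{naoh_volume},
#' \code{naoh_normality}, \code{juice_volume} (optionally
#' \code{acid_meq_factor}), from which TA is computed.  When \code{brima}
#' is present it is checked against \code{tss - k*ta} (tolerance 1e-9);
#' when absent it is computed.
#'
#' @param path CSV path
#' @param k BrimA constant used to recompute/check
#' @param acid_meq_factor used when TA is derived from titration columns
#'   that lack their own \code{acid_meq_factor}; 0.067 is the malic-acid
#'   (apple) convention
#' @return data.frame with sample_id, tss, ta, brima
#' @export
read_chemistry_table <- function(path, k = 5, acid_meq_factor = 0.067) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  titr <- c("naoh_volume", "naoh_normality", "juice_volume")
  if (!"ta" %in% names(df) && all(titr %in% names(df))) {
    meq <- if ("acid_meq_factor" %in% names(df)) df$acid_meq_factor else acid_meq_factor
    df$ta <- titratable_acidity(df$naoh_volume, df$naoh_normality, meq,
                                df$juice_volume)
  }
  need <- c("sample_id", "tss", "ta")
  if (!all(need %in% names(df))) {
    stop("chemistry table must contain columns: ", paste(need, collapse = ", "),
         " (ta may instead be given as ", paste(titr, collapse = ", "), ")")
  }
  expected <- brima(df$tss, df$ta, k)
  if ("brima" %in% names(df)) {
    if (any(abs(df$brima - expected) > 1e-9)) {
      stop("stored brima disagrees with tss - ", k, "*ta")
    }
  } else {
    df$brima <- expected
  }
  df[, c("sample_id", "tss", "ta", "brima")]
}
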