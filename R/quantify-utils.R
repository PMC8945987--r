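# Small quantification utilities: relative qPCR expression and
# loading-control-normalized densitometry ratios.

#' Relative qPCR expression by the 2^-ddCt method
#'
#' With target and reference Ct values for a sample and a calibrator,
#' computes `dCt = Ct_target - Ct_reference` within each group,
#' `ddCt = dCt_sample - dCt_calibrator`, and returns `2^-ddCt`, the
#' expression of the target gene relative to the calibrator after
#' normalization to the reference gene (e.g. beta-actin).
#'
#' @param sample,calibrator Numeric vectors `c(ct_target, ct_reference)` (or
#'   lists with `ct_target`/`ct_reference`); Ct values must be finite and
#'   positive.
#' @return Relative expression (fold, > 0).
#' @examples
#' ddct(c(21, 20), c(20, 20))  # 0.5
#' ddct(c(19, 20), c(20, 20))  # 2
#' @export
ddct <- function(sample, calibrator) {
  get_ct <- function(x) {
    if (is.list(x)) x <- c(x$ct_target, x$ct_reference)
    if (length(x) != 2L || !all(is.finite(x)) || any(x <= 0))
      stop("Ct values must be two finite positive numbers")
    x
  }
  s <- get_ct(sample); k <- get_ct(calibrator)
  2^-((s[1L] - s[2L]) - (k[1L] - k[2L]))
}

#' Loading-control-normalized densitometry ratio
#'
#' Each band intensity is first divided by its own loading-control signal
#' (e.g. beta-actin in the same lane); the function returns the ratio of the
#' two normalized signals.  Scaling all intensities by a common factor
#' leaves the result unchanged.
#'
#' @param numerator,denominator Numeric vectors
#'   `c(band_intensity, loading_control_intensity)` (or lists with those
#'   names); loading controls must be > 0.
#' @return Normalized ratio (real).
#' @examples
#' normalized_ratio(c(2, 1), c(1, 1))  # 2
#' @export
normalized_ratio <- function(numerator, denominator) {
  get_sig <- function(x) {
    if (is.list(x)) x <- c(x$band_intensity, x$loading_control_intensity)
    if (length(x) != 2L || !all(is.finite(x)))
      stop("signals must be two finite numbers")
    if (x[2L] <= 0) stop("loading-control intensity must be > 0")
    x
  }
  n <- get_sig(numerator); d <- get_sig(denominator)
  if (d[1L] == 0) stop("denominator band intensity is zero")
  (n[1L] / n[2L]) / (d[1L] / d[2L])
}
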