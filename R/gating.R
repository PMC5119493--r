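#' Fraction of GAL-ON cells by fluorescence threshold gating
#'
#' Classifies cytometry-style events as GAL-ON when their log10 fluorescence
#' lies strictly above a threshold. With `threshold = "auto"` the threshold
#' is placed at the density minimum between the two largest modes of a
#' Gaussian kernel density estimate (Silverman's bandwidth). Tables whose
#' KDE has a single mode — e.g. the low-level unimodal activation state that
#' straddles any fixed ON/OFF threshold — are flagged un-gateable and get
#' `fraction_on = NA`. Fixed thresholds are preferred inside pipelines for
#' comparability across samples.
#'
#' @param events A tibble with a `log10_yfp` column (see
#'   [read_event_table()]) or a numeric vector of log10 fluorescence values.
#' @param threshold Numeric log10-fluorescence threshold, or `"auto"`.
#' @return A one-row tibble: `fraction_on`, `threshold`, `n_events`,
#'   `gateable`.
#' @export
#' @examples
#' gate_fraction_on(c(1.0, 1.5, 3.0, 3.5), threshold = 2)
gate_fraction_on <- function(events, threshold = "auto") {
  x <- if (is.data.frame(events)) {
    if (!"log10_yfp" %in% names(events)) {
      abort("event table needs a log10_yfp column", class = "galgame_validation_error")
    }
    events$log10_yfp
  } else {
    as.numeric(events)
  }
  if (length(x) == 0 || all(is.na(x))) {
    abort("event table is empty", class = "galgame_validation_error")
  }
  x <- x[!is.na(x)]

  if (identical(threshold, "auto")) {
    kde <- density(x, bw = "nrd0")
    peaks <- which(diff(sign(diff(kde$y))) == -2) + 1
    peaks <- peaks[kde$y[peaks] >= 0.05 * max(kde$y)]
    if (length(peaks) < 2) {
      return(tibble(
        fraction_on = NA_real_, threshold = NA_real_,
        n_events = length(x), gateable = FALSE
      ))
    }
    top2 <- peaks[order(kde$y[peaks], decreasing = TRUE)[1:2]]
    lo <- min(top2)
    hi <- max(top2)
    valley <- lo + which.min(kde$y[lo:hi]) - 1
    thr <- kde$x[valley]
  } else {
    thr <- as.numeric(threshold)
  }
  tibble(
    fraction_on = mean(x > thr), threshold = thr,
    n_events = length(x), gateable = TRUE
  )
}
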