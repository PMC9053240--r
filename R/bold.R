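#' Construct a BOLD series object
#'
#' Wraps a regions x timepoints matrix with its repetition time, region
#' labels, and a processing-stage tag. The preprocessing operators enforce
#' the stage order raw -> trimmed -> detrended -> bandpassed -> zscored;
#' each operator accepts input at the immediately preceding stage or at its
#' own stage (so detrending and z-scoring are idempotent by re-application).
#'
#' @param values Numeric matrix, rows = regions, columns = timepoints.
#' @param tr Repetition time in seconds (2.0 in the study design this
#'   pipeline targets).
#' @param region_labels Region names; defaults to rownames of `values`.
#' @param subject_id Identifier.
#' @param stage Processing stage tag.
#' @return A `bold_series` object.
#' @export
bold_series <- function(values, tr = 2, region_labels = rownames(values),
                        subject_id = "subject", stage = "raw") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (!all(is.finite(values))) {
    abort("BOLD series contains non-finite values.",
          class = "boldband_error_nonfinite")
  }
  if (ncol(values) < 2) {
    abort("BOLD series must have at least 2 timepoints.",
          class = "boldband_error_dimension")
  }
  if (is.null(region_labels)) {
    region_labels <- sprintf("region_%02d", seq_len(nrow(values)))
  }
  if (length(region_labels) != nrow(values)) {
    abort("Region label count does not match the number of rows.",
          class = "boldband_error_dimension")
  }
  stage <- match.arg(stage, .bold_stages)
  rownames(values) <- region_labels
  structure(
    list(values = values, tr = tr, region_labels = as.character(region_labels),
         subject_id = subject_id, stage = stage),
    class = "bold_series"
  )
}

.bold_stages <- c("raw", "trimmed", "detrended", "bandpassed", "zscored")

.check_stage <- function(s, op, expected_prev) {
  if (!s$stage %in% expected_prev) {
    abort(sprintf(
      "%s expects a series at stage %s, got '%s' (pipeline order is %s).",
      op, paste(sQuote(expected_prev), collapse = " or "), s$stage,
      paste(.bold_stages, collapse = " -> ")),
      class = "boldband_error_stage")
  }
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> subject %s [%s]: %d regions x %d timepoints, TR %gs\n",
              x$subject_id, x$stage, nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

#' Discard initial scanner-transient frames
#'
#' Drops the first `floor(discard_seconds / tr)` frames to remove the
#' initialization transient (18 s, i.e. 9 frames at TR = 2 s, by default).
#'
#' @param s A `bold_series` at stage `"raw"`.
#' @param discard_seconds Seconds to discard from the start of the scan.
#' @return The trimmed `bold_series` (stage `"trimmed"`).
#' @export
trim_initial <- function(s, discard_seconds = 18) {
  stopifnot(inherits(s, "bold_series"))
  .check_stage(s, "trim_initial", "raw")
  total <- ncol(s$values) * s$tr
  if (discard_seconds < 0 || discard_seconds >= total) {
    abort(sprintf("discard_seconds = %g must lie in [0, %g).",
                  discard_seconds, total),
          class = "boldband_error_trim")
  }
  k <- floor(discard_seconds / s$tr)
  vals <- s$values[, (k + 1):ncol(s$values), drop = FALSE]
  bold_series(vals, tr = s$tr, region_labels = s$region_labels,
              subject_id = s$subject_id, stage = "trimmed")
}

#' Remove per-region linear trends and offsets
#'
#' Subtracts the least-squares line `a*t + b` from each region's series, so
#' the residuals have zero mean and zero covariance with time.
#'
#' @param s A `bold_series` at stage `"trimmed"` (or `"detrended"`:
#'   detrending is idempotent).
#' @return Detrended `bold_series`.
#' @export
detrend_bold <- function(s) {
  stopifnot(inherits(s, "bold_series"))
  .check_stage(s, "detrend_bold", c("trimmed", "detrended"))
  tt <- ncol(s$values)
  if (tt < 3) {
    abort("Detrending requires at least 3 timepoints.",
          class = "boldband_error_dimension")
  }
  x <- cbind(1, seq_len(tt))
  hat <- x %*% solve(crossprod(x), t(x))  # T x T projection onto [1, t]
  vals <- s$values - s$values %*% hat
  bold_series(vals, tr = s$tr, region_labels = s$region_labels,
              subject_id = s$subject_id, stage = "detrended")
}

#' Band-pass filter in the temporal frequency domain
#'
#' Applies a hard (brick-wall) DFT-bin mask per region: bins with frequency
#' `f_lo <= f <= f_hi` (inclusive) are retained, all others — including the
#' DC bin when `f_lo > 0` — are zeroed, and the series is transformed back.
#' Defaults retain the conventional resting-state band 0.009–0.1 Hz.
#'
#' @param s A `bold_series` at stage `"detrended"` (or `"bandpassed"`).
#' @param f_lo,f_hi Passband edges in Hz; must satisfy
#'   `0 <= f_lo < f_hi <= 1/(2*tr)`.
#' @return Band-passed `bold_series`.
#' @export
bandpass_bold <- function(s, f_lo = 0.009, f_hi = 0.1) {
  stopifnot(inherits(s, "bold_series"))
  .check_stage(s, "bandpass_bold", c("detrended", "bandpassed"))
  nyq <- 1 / (2 * s$tr)
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= nyq + 1e-12)) {
    abort(sprintf("Invalid band [%g, %g] Hz for Nyquist %g Hz.",
                  f_lo, f_hi, nyq),
          class = "boldband_error_band")
  }
  tt <- ncol(s$values)
  freqs <- pmin(0:(tt - 1), tt - 0:(tt - 1)) / (tt * s$tr)
  keep <- freqs >= f_lo & freqs <= f_hi
  xf <- mvfft(t(s$values))           # columns are regions
  xf[!keep, ] <- 0 + 0i
  vals <- t(Re(mvfft(xf, inverse = TRUE)) / tt)
  bold_series(vals, tr = s$tr, region_labels = s$region_labels,
              subject_id = s$subject_id, stage = "bandpassed")
}

#' Z-score each region's time series
#'
#' Centers and scales every region to mean 0 and sample standard deviation
#' (denominator T - 1) equal to 1, removing per-subject amplitude
#' differences of no neurophysiological interest.
#'
#' @param s A `bold_series` at stage `"bandpassed"` (or `"zscored"`).
#' @return Z-scored `bold_series`.
#' @export
zscore_bold <- function(s) {
  stopifnot(inherits(s, "bold_series"))
  .check_stage(s, "zscore_bold", c("bandpassed", "zscored"))
  mu <- rowMeans(s$values)
  sds <- apply(s$values, 1, sd)
  zero <- sds < .Machine$double.eps^0.5
  if (any(zero)) {
    abort(sprintf("Zero-variance region(s): %s.",
                  paste(s$region_labels[zero], collapse = ", ")),
          class = "boldband_error_zerovar")
  }
  vals <- (s$values - mu) / sds
  bold_series(vals, tr = s$tr, region_labels = s$region_labels,
              subject_id = s$subject_id, stage = "zscored")
}

#' Full BOLD preprocessing chain
#'
#' Convenience wrapper running trim -> detrend -> band-pass -> z-score with
#' the default parameters (18 s trim, 0.009–0.1 Hz band).
#'
#' @inheritParams trim_initial
#' @inheritParams bandpass_bold
#' @return A `bold_series` at stage `"zscored"`.
#' @export
preprocess_bold <- function(s, discard_seconds = 18, f_lo = 0.009, f_hi = 0.1) {
  s |>
    trim_initial(discard_seconds) |>
    detrend_bold() |>
    bandpass_bold(f_lo, f_hi) |>
    zscore_bold()
}
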