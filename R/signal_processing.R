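# Per-spectrum signal chain: normalization -> smoothing -> baseline
# correction, in that fixed order.

#' Signal-processing parameters
#'
#' Bundles the per-spectrum processing chain settings. The chain is applied
#' in the fixed order normalization, Savitzky-Golay smoothing, baseline
#' correction.
#'
#' @param normalization One of `"none"`, `"tic"`, `"median"`, `"infile"`.
#' @param sg_window Odd integer window (>= 3) for Savitzky-Golay smoothing,
#'   or `NULL` to disable. Default 9 samples.
#' @param sg_order Polynomial order, must be `< sg_window`. Default 2.
#' @param baseline One of `"none"`, `"tophat"`, `"running_median"`.
#' @param baseline_halfwidth Structuring-element / window half-width in
#'   array elements (>= 1). Default 50.
#' @return A list of class `signal_params`.
#' @export
signal_params <- function(normalization = c("none", "tic", "median", "infile"),
                          sg_window = NULL, sg_order = 2L,
                          baseline = c("none", "tophat", "running_median"),
                          baseline_halfwidth = 50L) {
  normalization <- match.arg(normalization)
  baseline <- match.arg(baseline)
  if (!is.null(sg_window)) {
    sg_window <- as.integer(sg_window)
    if (sg_window < 3L || sg_window %% 2L == 0L) {
      stop("sg_window must be an odd integer >= 3")
    }
    if (sg_order >= sg_window) stop("sg_order must be < sg_window")
  }
  baseline_halfwidth <- as.integer(baseline_halfwidth)
  if (baseline_halfwidth < 1L) stop("baseline_halfwidth must be >= 1")
  structure(list(normalization = normalization,
                 sg_window = sg_window, sg_order = as.integer(sg_order),
                 baseline = baseline,
                 baseline_halfwidth = baseline_halfwidth),
            class = "signal_params")
}

#' Per-spectrum normalization factor
#'
#' The scaling value f by which a spectrum's intensities are divided:
#' the total ion count (sum), the intensity median, an in-file factor
#' stored with the spectrum record, or 1 when normalization is disabled.
#'
#' @param spectrum An `msi_spectrum` (or any list with `intensity`).
#' @param method `"none"`, `"tic"`, `"median"`, or `"infile"`.
#' @param record Spectrum record row (needed for `"infile"`), with a
#'   `norm_factor` entry.
#' @return Positive scalar f.
#' @export
normalization_factor <- function(spectrum,
                                 method = c("none", "tic", "median",
                                            "infile"),
                                 record = NULL) {
  method <- match.arg(method)
  x <- spectrum$intensity
  if (!length(x)) stop("empty spectrum")
  f <- switch(method,
    none = 1,
    tic = sum(x),
    median = median(x),
    infile = {
      nf <- record$norm_factor
      if (is.null(nf) || is.na(nf)) {
        stop("missing-factor error: in-file normalization selected but ",
             "no factor is stored for this spectrum")
      }
      nf
    })
  if (method %in% c("tic", "median") && f <= 0) {
    stop("degenerate-spectrum error: ", method,
         " normalization factor is not positive")
  }
  f
}

#' Apply a normalization factor
#'
#' Divides every intensity by `f`; the m/z axis is untouched.
#' @param spectrum An `msi_spectrum`.
#' @param f Positive scalar.
#' @return The scaled spectrum.
#' @export
normalize_spectrum <- function(spectrum, f) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0) {
    stop("normalization factor must be a positive scalar")
  }
  spectrum$intensity <- spectrum$intensity / f
  spectrum
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing: each point is replaced by the value
#' at the centre of a degree-`order` polynomial fitted over a sliding
#' window. Edge points use the polynomial fitted to the first/last full
#' window, evaluated at their positions.
#'
#' @param spectrum An `msi_spectrum`.
#' @param window Odd window length, `3 <= window <= length(spectrum)`.
#' @param order Polynomial order `< window`.
#' @return The smoothed spectrum.
#' @export
smooth_savitzky_golay <- function(spectrum, window = 9L, order = 2L) {
  x <- spectrum$intensity
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L) {
    stop("parameter error: window must be odd and >= 3")
  }
  if (window > length(x)) {
    stop("parameter error: window larger than the spectrum")
  }
  if (order >= window) stop("parameter error: order must be < window")
  spectrum$intensity <- as.numeric(signal::sgolayfilt(x, p = order,
                                                      n = window))
  spectrum
}

# flat-structuring-element erosion/dilation with edge-clipped windows
.erode <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n),
         function(i) min(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}
.dilate <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n),
         function(i) max(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}
.running_median <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n),
         function(i) median(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

#' Baseline estimation and subtraction
#'
#' `tophat`: morphological opening (erosion then dilation) with a flat
#' structuring element of width `2 * halfwidth + 1` elements.
#' `running_median`: windowed median of the same width, with shrinking
#' windows at the edges. The corrected spectrum is
#' `max(intensity - baseline, 0)`.
#'
#' @param spectrum An `msi_spectrum`.
#' @param method `"tophat"` or `"running_median"`.
#' @param halfwidth Half-width in array elements (>= 1).
#' @return `list(baseline =, corrected =)` where `corrected` is a spectrum.
#' @export
baseline_correct <- function(spectrum,
                             method = c("tophat", "running_median"),
                             halfwidth = 50L) {
  method <- match.arg(method)
  halfwidth <- as.integer(halfwidth)
  if (halfwidth < 1L) stop("parameter error: halfwidth must be >= 1")
  x <- spectrum$intensity
  baseline <- switch(method,
    tophat = .dilate(.erode(x, halfwidth), halfwidth),
    running_median = .running_median(x, halfwidth))
  corrected <- spectrum
  corrected$intensity <- pmax(x - baseline, 0)
  list(baseline = baseline, corrected = corrected)
}

#' Apply the full signal chain to one spectrum
#'
#' Normalization (division by the factor f), then optional Savitzky-Golay
#' smoothing, then optional baseline correction, in that order.
#'
#' @param spectrum An `msi_spectrum`.
#' @param params A [signal_params()] object.
#' @param record Spectrum record row (for in-file normalization).
#' @return The processed spectrum; the applied factor is attached as
#'   attribute `"norm_factor"`.
#' @export
apply_signal_chain <- function(spectrum, params = signal_params(),
                               record = NULL) {
  f <- normalization_factor(spectrum, params$normalization, record)
  if (f != 1) spectrum <- normalize_spectrum(spectrum, f)
  if (!is.null(params$sg_window) &&
      params$sg_window <= length(spectrum$intensity)) {
    spectrum <- smooth_savitzky_golay(spectrum, params$sg_window,
                                      params$sg_order)
  }
  if (params$baseline != "none") {
    spectrum <- baseline_correct(spectrum, params$baseline,
                                 params$baseline_halfwidth)$corrected
  }
  attr(spectrum, "norm_factor") <- f
  spectrum
}
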