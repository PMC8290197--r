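# Peak detection and downstream peak-list operations. Noise is the
# Gaussian-consistent median absolute deviation; peaks are sliding-window
# local maxima above snr * noise; envelopes are resolved against a
# mass-parameterized Poisson isotope model.

#' Construct a peak list
#'
#' @param mz,intensity,snr Numeric vectors of equal length.
#' @param charge,isotope_group,is_monoisotopic Optional annotations.
#' @param provenance Optional source id.
#' @return A data frame of class `msi_peaks`, ordered by ascending m/z.
#' @export
peak_list <- function(mz, intensity, snr = rep(NA_real_, length(mz)),
                      charge = rep(NA_integer_, length(mz)),
                      isotope_group = rep(NA_integer_, length(mz)),
                      is_monoisotopic = rep(NA, length(mz)),
                      provenance = NULL) {
  df <- data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity),
                   snr = as.numeric(snr), charge = as.integer(charge),
                   isotope_group = as.integer(isotope_group),
                   is_monoisotopic = as.logical(is_monoisotopic))
  if (nrow(df) > 1L) {
    o <- order(df$mz)
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
    if (any(diff(df$mz) <= 0)) stop("peak list m/z must be strictly ascending")
  }
  if (any(df$mz <= 0)) stop("peak m/z must be positive")
  attr(df, "provenance") <- provenance
  class(df) <- c("msi_peaks", "data.frame")
  df
}

#' MAD noise estimate
#'
#' Robust noise scale: `1.4826 * median(|x - median(x)|)` (the constant
#' makes the estimator consistent with the standard deviation under a
#' Gaussian model).
#'
#' @param intensities Non-empty numeric vector.
#' @return Non-negative scalar noise level.
#' @export
estimate_noise_mad <- function(intensities) {
  if (!length(intensities)) stop("empty intensity vector")
  mad(intensities, constant = 1.4826)
}

#' Sliding-window peak picking
#'
#' Index i is a peak iff its intensity equals the maximum over the window
#' `[i - halfwindow, i + halfwindow]` (clipped at the spectrum edges),
#' exceeds `snr_threshold * noise`, and is the leftmost index of any
#' plateau of equal maxima. Noise is the MAD estimate over the whole
#' (processed) spectrum unless supplied.
#'
#' @param spectrum A processed `msi_spectrum`.
#' @param snr_threshold Positive signal-to-noise threshold.
#' @param halfwindow Window half-width in array elements (>= 1).
#' @param noise Optional externally supplied noise level.
#' @return An `msi_peaks` data frame (`mz`, `intensity`, `snr`).
#' @export
pick_peaks <- function(spectrum, snr_threshold = 4, halfwindow = 10L,
                       noise = NULL) {
  if (snr_threshold <= 0) stop("parameter error: snr_threshold must be > 0")
  halfwindow <- as.integer(halfwindow)
  if (halfwindow < 1L) stop("parameter error: halfwindow must be >= 1")
  x <- spectrum$intensity
  n <- length(x)
  noise <- noise %||% estimate_noise_mad(x)
  thr <- snr_threshold * noise

  # windowed scan (n is spectrum depth; O(n*h) is fine); a peak must also
  # dominate something in its window, so flat stretches yield no peaks
  cand <- logical(n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - halfwindow):min(n, i + halfwindow)]
    cand[i] <- x[i] >= max(w) && x[i] > min(w) && x[i] > thr
  }
  # leftmost-of-plateau: drop i when i-1 is an equal-valued candidate
  if (n > 1L) {
    drop <- c(FALSE, cand[-n] & cand[-1L] & x[-n] == x[-1L])
    cand <- cand & !drop
  }
  idx <- which(cand)
  pl <- peak_list(mz = spectrum$mz[idx], intensity = x[idx],
                  snr = if (noise > 0) x[idx] / noise else rep(Inf,
                                                               length(idx)),
                  provenance = spectrum$index)
  attr(pl, "noise") <- noise
  pl
}

#' Bin peaks across lists
#'
#' Pools all input peaks, sorts by m/z and groups them greedily: a new bin
#' starts whenever the gap to the previous peak exceeds `tolerance`
#' (single-linkage). Each bin reports the intensity-weighted mean m/z and
#' the maximum member intensity; member sets partition the pooled input.
#'
#' @param lists A single `msi_peaks` or a list of them.
#' @param tolerance Gap threshold in Da (or in m/z units generally); > 0.
#' @return An `msi_peaks` with one row per bin; member counts in
#'   attribute `"bin_sizes"`.
#' @export
bin_peaks <- function(lists, tolerance) {
  if (tolerance <= 0) stop("parameter error: tolerance must be > 0")
  if (inherits(lists, "msi_peaks")) lists <- list(lists)
  mz <- unlist(lapply(lists, function(p) p$mz))
  intensity <- unlist(lapply(lists, function(p) p$intensity))
  snr <- unlist(lapply(lists, function(p) p$snr))
  if (!length(mz)) return(peak_list(numeric(0), numeric(0)))
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]; snr <- snr[o]
  grp <- cumsum(c(1, diff(mz) > tolerance))
  w <- ifelse(intensity > 0, intensity, .Machine$double.eps)
  bin_mz <- vapply(split(seq_along(mz), grp),
                   function(i) sum(mz[i] * w[i]) / sum(w[i]), numeric(1))
  bin_int <- vapply(split(intensity, grp), max, numeric(1))
  # each bin inherits the snr of its most intense member
  bin_snr <- vapply(split(seq_along(mz), grp),
                    function(i) snr[i][which.max(intensity[i])],
                    numeric(1))
  sizes <- vapply(split(mz, grp), length, integer(1))
  pl <- peak_list(mz = bin_mz, intensity = bin_int, snr = bin_snr)
  attr(pl, "bin_sizes") <- unname(sizes)
  pl
}

#' Poisson monoisotopic peak harvesting
#'
#' Assembles isotope-envelope chains greedily from low m/z: for each charge
#' z, successive peaks spaced `1.00235 / z` (within `spacing_tolerance`)
#' are chained. Each chain's relative intensities are scored against
#' Poisson weights `p_k = exp(-lambda) * lambda^k / k!` with
#' `lambda = lambda_slope * monoisotopic m/z`, using the normalized dot
#' product (cosine). Chains
#' scoring at least `score_threshold` mark their first member
#' monoisotopic and flag the rest as isotopologues; everything else
#' passes through as a monoisotopic singleton.
#'
#' @param peaks An `msi_peaks`, ascending m/z.
#' @param charges Non-empty set of positive charge states to try.
#' @param spacing_tolerance Allowed deviation from the isotopic spacing
#'   (Da), default 0.01.
#' @param lambda_slope Poisson rate per Da of mass, default 0.000594
#'   (averagine-like).
#' @param score_threshold Minimum cosine score for accepting a chain.
#' @return The input peaks with `charge`, `isotope_group` and
#'   `is_monoisotopic` filled in.
#' @export
poisson_monoisotopic <- function(peaks, charges = c(1L, 2L),
                                 spacing_tolerance = 0.01,
                                 lambda_slope = 0.000594,
                                 score_threshold = 0.95) {
  if (!length(charges)) stop("parameter error: empty charge set")
  charges <- sort(unique(as.integer(charges)))
  if (any(charges < 1L)) stop("parameter error: charges must be positive")
  n <- nrow(peaks)
  peaks$is_monoisotopic <- rep(TRUE, n)
  peaks$isotope_group <- rep(NA_integer_, n)
  peaks$charge <- rep(NA_integer_, n)
  if (n < 2L) return(peaks)

  assigned <- logical(n)
  group <- 0L
  for (start in seq_len(n)) {
    if (assigned[start]) next
    best <- NULL
    for (z in charges) {
      step <- 1.00235 / z
      chain <- start
      cur <- start
      repeat {
        target <- peaks$mz[cur] + step
        j <- which(!assigned & peaks$mz > peaks$mz[cur] &
                     abs(peaks$mz - target) <= spacing_tolerance)
        if (!length(j)) break
        j <- j[which.min(abs(peaks$mz[j] - target))]
        chain <- c(chain, j)
        cur <- j
      }
      if (length(chain) < 2L) next
      lambda <- lambda_slope * peaks$mz[start]
      model <- dpois(seq_along(chain) - 1L, lambda)
      obs <- peaks$intensity[chain]
      score <- sum(obs * model) / sqrt(sum(obs^2) * sum(model^2))
      if (is.null(best) || score > best$score) {
        best <- list(chain = chain, z = z, score = score)
      }
    }
    if (!is.null(best) && best$score >= score_threshold) {
      group <- group + 1L
      ch <- best$chain
      assigned[ch] <- TRUE
      peaks$isotope_group[ch] <- group
      peaks$charge[ch] <- best$z
      peaks$is_monoisotopic[ch] <- FALSE
      peaks$is_monoisotopic[ch[1L]] <- TRUE
    }
  }
  peaks
}

#' Sample a spectrum at a common peak list
#'
#' For export to the continuous-centroid dialect: for every common peak,
#' the maximum spectrum intensity within `mz +/- tolerance` (0 when no
#' sample falls inside the window).
#'
#' @param spectrum An `msi_spectrum`.
#' @param common_peaks An `msi_peaks` (ascending).
#' @param tolerance Half-window in Da.
#' @return Numeric vector of length `nrow(common_peaks)`.
#' @export
sample_at_peaks <- function(spectrum, common_peaks, tolerance) {
  mz <- spectrum$mz
  x <- spectrum$intensity
  vapply(common_peaks$mz, function(m) {
    lo <- findInterval(m - tolerance, mz) + 1L
    hi <- findInterval(m + tolerance, mz)
    if (hi < lo) 0 else max(x[lo:hi])
  }, numeric(1))
}

#' Export a dataset as continuous-centroid imzML
#'
#' Samples every (signal-chain-processed) spectrum at a common peak list
#' and writes the result with a shared centroid axis.
#'
#' @param meta An `msi_dataset`.
#' @param common_peaks An `msi_peaks` defining the shared axis.
#' @param path Output `.imzML` path.
#' @param tolerance Sampling half-window in Da.
#' @param params [signal_params()] applied before sampling.
#' @return Invisibly, the written file paths.
#' @export
export_centroid <- function(meta, common_peaks, path, tolerance,
                            params = signal_params()) {
  coords <- as.matrix(meta$spectra[, c("x", "y", "z")])
  gen <- function(i) {
    s <- read_spectrum(meta, i)
    s <- apply_signal_chain(s, params, meta$spectra[i, ])
    list(mz = common_peaks$mz,
         intensity = sample_at_peaks(s, common_peaks, tolerance))
  }
  write_imzml(gen, coords, path, dialect = "continuous-centroid",
              pixel_size = meta$pixel_size)
}
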