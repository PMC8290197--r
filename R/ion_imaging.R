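# Ion-image generation: per-pixel reduction of intensities within a closed
# m/z window, after the configured signal chain, with lazy spectrum access.

#' Generate an ion image
#'
#' For every valid pixel the spectrum is loaded lazily, the signal chain is
#' applied, and the intensities whose m/z lie in the closed window
#' `[center_mz - tolerance, center_mz + tolerance]` are reduced to a single
#' value. Pixels without a spectrum, or excluded by `mask`, are 0. The
#' result is independent of the worker count.
#'
#' @param meta An `msi_dataset`.
#' @param center_mz Window centre (Da).
#' @param tolerance Half-width of the closed window (Da); > 0.
#' @param reducer One of `"mean"`, `"max"`, `"sum"`, `"median"`.
#' @param params [signal_params()] applied per spectrum.
#' @param mask Optional raster (same geometry); pixels with `mask == 0`
#'   are zeroed and their spectra skipped.
#' @param n_workers Chunked iteration workers.
#' @return A height x width numeric matrix (or array for multi-slice data).
#' @export
generate_ion_image <- function(meta, center_mz, tolerance,
                               reducer = c("mean", "max", "sum", "median"),
                               params = signal_params(), mask = NULL,
                               n_workers = 1L) {
  reducer <- match.arg(reducer)
  if (tolerance <= 0) stop("tolerance must be > 0")
  lo <- center_mz - tolerance
  hi <- center_mz + tolerance
  red_fn <- switch(reducer, mean = mean, max = max, sum = sum,
                   median = median)

  continuous <- meta$mode == "continuous"
  win_idx <- NULL
  if (continuous) {
    axis <- read_spectrum(meta, 1L)$mz
    win_idx <- which(axis >= lo & axis <= hi)
    if (!length(win_idx)) {
      stop("empty-window error: m/z window [", lo, ", ", hi,
           "] contains no samples of the dataset axis")
    }
  }

  dims <- c(meta$height, meta$width, meta$depth)
  img <- array(0, dims)
  df <- meta$spectra
  lin_of <- function(x, y, z) y + (x - 1L) * dims[1] + (z - 1L) * dims[1] * dims[2]

  keep <- rep(TRUE, meta$n_spectra)
  if (!is.null(mask)) {
    if (!identical(length(mask), prod(dims)) &&
        !identical(dim(mask)[1:2], dims[1:2])) {
      stop("geometry error: mask shape does not match the image")
    }
    keep <- mask[lin_of(df$x, df$y, df$z)] != 0
  }
  idx <- which(keep)
  if (length(idx)) {
    per <- function(s, i) {
      s <- apply_signal_chain(s, params, df[i, ])
      v <- if (continuous) s$intensity[win_idx] else {
        s$intensity[s$mz >= lo & s$mz <= hi]
      }
      val <- if (length(v)) red_fn(v) else 0
      list(i = i, val = val)
    }
    red <- function(a, b) list(i = c(a$i, b$i), val = c(a$val, b$val))
    acc <- iterate_spectra_chunked(meta, n_workers, per, red, indices = idx)
    img[lin_of(df$x[acc$i], df$y[acc$i], df$z[acc$i])] <- acc$val
  }
  if (dims[3] == 1L) dim(img) <- dims[1:2]
  img
}

#' Zero a raster outside a mask
#'
#' @param raster Numeric matrix/array.
#' @param mask Same-shape raster; entries equal to 0 zero the output.
#' @return The masked raster.
#' @export
apply_mask <- function(raster, mask) {
  if (!identical(dim(raster), dim(mask))) {
    stop("geometry error: raster and mask shapes differ")
  }
  raster * (mask != 0)
}
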