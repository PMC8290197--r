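# One-pass initialization of the in-memory artefacts: four same-geometry
# rasters (ion, normalization, index, mask) and three overview spectra
# (skyline, sum, mean), plus the closed-form memory model.

#' Memory model for the retained artefacts
#'
#' Closed-form estimate of the memory retained for one loaded MSI image:
#' four rasters of `n_pixels` each (two double, one int, one short) plus
#' three overview spectra of length `depth`, plus one spectrum buffer per
#' worker thread:
#' `n_pixels * (2*sizeof_double + sizeof_int + sizeof_short) +
#'  (3 + n_threads) * depth * sizeof_double`.
#'
#' @param n_pixels Total raster pixels |I| (width x height x depth slices).
#' @param depth Spectral depth |S| (samples per spectrum).
#' @param n_threads Number of worker threads T.
#' @param sizeof_double,sizeof_int,sizeof_short Byte sizes of the numeric
#'   types (defaults 8, 4, 2).
#' @return Estimated bytes (numeric scalar).
#' @export
estimate_memory <- function(n_pixels, depth, n_threads = 1,
                            sizeof_double = 8, sizeof_int = 4,
                            sizeof_short = 2) {
  stopifnot(n_pixels >= 0, depth >= 0, n_threads >= 0)
  n_pixels * (2 * sizeof_double + sizeof_int + sizeof_short) +
    (3 * depth + n_threads * depth) * sizeof_double
}

#' Initialize the image artefacts and overview spectra
#'
#' One chunked pass over all spectra computes, per pixel, the normalization
#' factor (stored in `I_norm`), the spectrum ordinal (`I_index`, -1 where
#' no spectrum exists) and the validity mask (`I_mask`), and accumulates
#' the three overview spectra: `skyline` (elementwise maximum), `sum`, and
#' `mean = sum / N`. Overviews are computed from spectra after the
#' configured signal chain unless `raw = TRUE`. Spectrum data are discarded
#' after processing; retained memory is proportional to the raster size
#' plus the spectral depth.
#'
#' For processed (per-spectrum axis) data a common axis must be supplied as
#' `axis_edges`: intensities are accumulated into those bins (bin maximum
#' feeds the skyline, bin sum the sum spectrum).
#'
#' @param meta An `msi_dataset`.
#' @param params A [signal_params()] object.
#' @param raw If `TRUE`, overview spectra are computed from unprocessed
#'   spectra (the normalization factors are still computed and stored).
#' @param n_workers Chunked iteration workers.
#' @param axis_edges Ascending bin edges (length depth+1) for processed
#'   data; ignored for continuous data.
#' @return `list(artefacts, overview, n_spectra)`; `artefacts` holds the
#'   rasters `I_ion`, `I_norm`, `I_index`, `I_mask` (height x width x depth
#'   arrays, dropped to matrices for single-slice data), `overview` holds
#'   `mz_axis`, `skyline`, `sum`, `mean`.
#' @export
initialize_artefacts <- function(meta, params = signal_params(),
                                 raw = FALSE, n_workers = 1L,
                                 axis_edges = NULL) {
  continuous <- meta$mode == "continuous"
  if (!continuous && is.null(axis_edges)) {
    stop("processed data: supply an explicit common axis via axis_edges")
  }
  if (!continuous) {
    if (is.unsorted(axis_edges, strictly = TRUE)) {
      stop("axis_edges must be strictly ascending")
    }
    mz_axis <- (head(axis_edges, -1) + tail(axis_edges, -1)) / 2
  } else {
    mz_axis <- read_spectrum(meta, 1L)$mz
  }
  depth_s <- length(mz_axis)

  per_spectrum <- function(s, i) {
    rec <- meta$spectra[i, ]
    f <- normalization_factor(
      s, if (params$normalization == "none") "none" else params$normalization,
      rec)
    v <- if (raw) s$intensity else {
      apply_signal_chain(s, params, rec)$intensity
    }
    if (continuous) {
      vals <- v
      vmax <- v
    } else {
      bin <- findInterval(s$mz, axis_edges, rightmost.closed = TRUE)
      keep <- bin >= 1L & bin <= depth_s
      vals <- numeric(depth_s)
      vmax <- numeric(depth_s)
      if (any(keep)) {
        b <- bin[keep]; vv <- v[keep]
        agg_sum <- vapply(split(vv, b), sum, numeric(1))
        agg_max <- vapply(split(vv, b), max, numeric(1))
        idx <- as.integer(names(agg_sum))
        vals[idx] <- agg_sum
        vmax[idx] <- agg_max
      }
    }
    list(skyline = vmax, total = vals, n = 1L,
         index = i, norm = f, pos = c(rec$x, rec$y, rec$z))
  }
  reducer <- function(a, b) {
    list(skyline = pmax(a$skyline, b$skyline),
         total = a$total + b$total,
         n = a$n + b$n,
         index = c(a$index, b$index),
         norm = c(a$norm, b$norm),
         pos = rbind(a$pos, b$pos))
  }
  acc <- iterate_spectra_chunked(meta, n_workers, per_spectrum, reducer)

  dims <- c(meta$height, meta$width, meta$depth)
  I_ion <- array(0, dims)
  I_norm <- array(0, dims)
  I_index <- array(-1L, dims)
  I_mask <- array(0L, dims)
  pos <- matrix(acc$pos, ncol = 3L)
  lin <- pos[, 2] + (pos[, 1] - 1L) * dims[1] + (pos[, 3] - 1L) * dims[1] * dims[2]
  if (anyDuplicated(lin)) {
    stop("integrity error: two spectra map to the same pixel")
  }
  I_index[lin] <- acc$index
  I_norm[lin] <- acc$norm
  I_mask[lin] <- 1L
  if (dims[3] == 1L) {
    dim(I_ion) <- dims[1:2]; dim(I_norm) <- dims[1:2]
    dim(I_index) <- dims[1:2]; dim(I_mask) <- dims[1:2]
  }

  list(
    artefacts = list(I_ion = I_ion, I_norm = I_norm,
                     I_index = I_index, I_mask = I_mask),
    overview = list(mz_axis = mz_axis,
                    skyline = acc$skyline,
                    sum = acc$total,
                    mean = acc$total / acc$n),
    n_spectra = acc$n
  )
}
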