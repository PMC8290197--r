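# Deterministic phantom MSI generation: profile spectra with Gaussian peak
# shapes, Poisson isotope envelopes, an exponential baseline, Gaussian
# noise and per-pixel intensity scaling; plus serial-section stacks related
# by known rigid transforms.

#' Phantom specification
#'
#' Describes a synthetic MSI image: geometry, m/z axis, analyte regions
#' and the signal model. Defaults describe a 128 x 128 pixel image at
#' 20 um lateral resolution with a 2,000-sample axis over m/z 600-1,800
#' and three circular regions of five analytes each.
#'
#' @param width,height Image size in pixels.
#' @param pixel_size Lateral resolution in micrometres.
#' @param mz_range Axis range `c(lo, hi)` in Da.
#' @param axis_depth Samples per spectrum (>= 16).
#' @param regions List of regions, each
#'   `list(center = c(fx, fy), radius = fr, masses =, abundances =)` with
#'   centre/radius as fractions of the image size; `NULL` builds the
#'   default three-region layout.
#' @param isotope_spacing Isotopologue spacing in Da (charge 1).
#' @param lambda_slope Poisson envelope rate per Da of mass.
#' @param peak_sigma Gaussian peak width (sd) in Da.
#' @param baseline `c(amplitude, decay)`: an exponential
#'   `amplitude * exp(-(mz - lo) / decay)` baseline.
#' @param noise_sigma Gaussian noise sd relative to the largest analyte
#'   abundance.
#' @param tic_variation Per-pixel multiplicative intensity factor range.
#' @param seed RNG seed; identical seeds give byte-identical files.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 128L, height = 128L, pixel_size = 20,
                         mz_range = c(600, 1800), axis_depth = 2000L,
                         regions = NULL,
                         isotope_spacing = 1.00235,
                         lambda_slope = 0.000594,
                         peak_sigma = 1.2,
                         baseline = c(20, 400),
                         noise_sigma = 0.02,
                         tic_variation = c(0.7, 1.3),
                         seed = 42L) {
  if (axis_depth < 16L) stop("axis_depth must be >= 16")
  stopifnot(peak_sigma > 0, all(tic_variation > 0), pixel_size > 0)
  if (is.null(regions)) {
    lo <- mz_range[1]; span <- diff(mz_range)
    centers <- list(c(0.30, 0.30), c(0.70, 0.40), c(0.45, 0.72))
    regions <- lapply(1:3, function(r) {
      list(center = centers[[r]], radius = 0.16,
           masses = lo + span * ((r - 1) * 5 + 1:5) / 16.5,
           abundances = c(100, 80, 120, 90, 110))
    })
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, mz_range = mz_range,
                 axis_depth = as.integer(axis_depth), regions = regions,
                 isotope_spacing = isotope_spacing,
                 lambda_slope = lambda_slope, peak_sigma = peak_sigma,
                 baseline = baseline, noise_sigma = noise_sigma,
                 tic_variation = tic_variation, seed = as.integer(seed)),
            class = "phantom_spec")
}

.region_mask <- function(spec, region) {
  w <- spec$width; h <- spec$height
  cx <- region$center[1] * (w - 1)
  cy <- region$center[2] * (h - 1)
  r <- region$radius * min(w, h)
  col <- matrix(rep(0:(w - 1), each = h), h, w)
  row <- matrix(rep(0:(h - 1), times = w), h, w)
  (col - cx)^2 + (row - cy)^2 <= r^2
}

.region_template <- function(spec, region, axis) {
  out <- numeric(length(axis))
  for (a in seq_along(region$masses)) {
    m <- region$masses[a]
    amp <- region$abundances[a]
    lambda <- spec$lambda_slope * m
    w <- dpois(0:4, lambda)
    w <- w / w[1]  # monoisotopic peak at the stated abundance
    for (k in 0:4) {
      mu <- m + k * spec$isotope_spacing
      out <- out + amp * w[k + 1] *
        exp(-(axis - mu)^2 / (2 * spec$peak_sigma^2))
    }
  }
  out
}

#' Generate a phantom imzML dataset with ground truth
#'
#' Writes a continuous-profile imzML file whose per-pixel spectra are the
#' sum of the covering regions' analyte signals (Gaussian peaks with
#' Poisson isotope envelopes), an exponential baseline and Gaussian noise,
#' all scaled by the pixel's intensity factor. Fully deterministic:
#' identical seeds give byte-identical files.
#'
#' @param spec A [phantom_spec()].
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return `list(imzml, ibd, axis, region_masks, masses, abundances,
#'   tic_factors, spec)`; `region_masks` are logical rasters,
#'   `tic_factors` the per-pixel scaling raster.
#' @export
make_phantom <- function(spec = phantom_spec(), dir = tempfile("phantom"),
                         name = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(spec$seed)

  axis <- seq(spec$mz_range[1], spec$mz_range[2],
              length.out = spec$axis_depth)
  masks <- lapply(spec$regions, .region_mask, spec = spec)
  templates <- lapply(spec$regions, .region_template, spec = spec,
                      axis = axis)
  base_curve <- spec$baseline[1] *
    exp(-(axis - spec$mz_range[1]) / spec$baseline[2])
  max_ab <- max(unlist(lapply(spec$regions, `[[`, "abundances")))
  noise_sd <- spec$noise_sigma * max_ab

  w <- spec$width; h <- spec$height
  tic <- matrix(runif(h * w, spec$tic_variation[1], spec$tic_variation[2]),
                h, w)
  coords <- cbind(x = rep(seq_len(w), each = h),
                  y = rep(seq_len(h), times = w))

  gen <- function(i) {
    x <- coords[i, 1]; y <- coords[i, 2]
    s <- base_curve
    for (r in seq_along(masks)) {
      if (masks[[r]][y, x]) s <- s + templates[[r]]
    }
    s <- (s + rnorm(spec$axis_depth, sd = noise_sd)) * tic[y, x]
    list(mz = axis, intensity = pmax(s, 0))
  }
  path <- file.path(dir, paste0(name, ".imzML"))
  files <- write_imzml(gen, coords, path, dialect = "continuous-profile",
                       pixel_size = c(spec$pixel_size, spec$pixel_size, 1))
  list(imzml = files$imzml, ibd = files$ibd, axis = axis,
       region_masks = masks,
       masses = lapply(spec$regions, `[[`, "masses"),
       abundances = lapply(spec$regions, `[[`, "abundances"),
       tic_factors = tic, spec = spec)
}

#' Structured anatomy raster for a phantom
#'
#' The region layout rendered as a smooth intensity image (region weights
#' plus a gentle gradient), suitable as a registration target.
#'
#' @param spec A [phantom_spec()].
#' @return A height x width numeric matrix.
#' @export
phantom_anatomy <- function(spec = phantom_spec()) {
  w <- spec$width; h <- spec$height
  masks <- lapply(spec$regions, .region_mask, spec = spec)
  img <- matrix(0, h, w)
  for (r in seq_along(masks)) img <- img + masks[[r]] * (40 + 25 * r)
  col <- matrix(rep(0:(w - 1), each = h), h, w)
  row <- matrix(rep(0:(h - 1), times = w), h, w)
  img <- img + 10 * col / max(1, w - 1) + 6 * row / max(1, h - 1)
  .gauss_blur(img, 1.5)
}

#' Generate a serial-section slice stack with known transforms
#'
#' Slice i is the phantom anatomy with a small smooth radial scaling
#' (morphology drift, <= 2%) resampled through the inverse of a known
#' rigid transform, so that applying the returned ground-truth chain
#' aligns it back to the reference. Landmark coordinates are transformed
#' consistently, so the landmark error of the ground-truth chain is zero
#' by construction.
#'
#' @param spec A [phantom_spec()] (geometry and seed).
#' @param n_slices Number of consecutive sections (default 10).
#' @param transforms `"random"` (rotations within +/-15 degrees, shifts
#'   within +/-10 pixels; slice 1 is identity) or a list of `msi_rigid`
#'   alignment transforms, one per slice.
#' @param landmarks_per_slice Reference points per slice (default 7).
#' @param drift Maximum radial scale deviation (default 0.02).
#' @return `list(slices, chains, landmarks_fixed, landmarks_moving,
#'   spacing)`: per-slice rasters, ground-truth `msi_chain`s mapping the
#'   reference space onto each slice, and per-slice fixed/moving landmark
#'   matrices (micrometres).
#' @export
make_slice_stack <- function(spec = phantom_spec(), n_slices = 10L,
                             transforms = "random",
                             landmarks_per_slice = 7L, drift = 0.02) {
  if (n_slices < 2L) stop("need at least 2 slices")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(spec$seed + 1L)

  sp <- c(spec$pixel_size, spec$pixel_size)
  base <- phantom_anatomy(spec)
  h <- nrow(base); w <- ncol(base)
  ctr <- c((w - 1) / 2 * sp[1], (h - 1) / 2 * sp[2])

  if (identical(transforms, "random")) {
    transforms <- c(list(rigid_transform(0, 0, 0, ctr)),
                    lapply(seq_len(n_slices - 1L), function(i) {
                      rigid_transform(runif(1, -15, 15) * pi / 180,
                                      runif(1, -10, 10) * sp[1],
                                      runif(1, -10, 10) * sp[2], ctr)
                    }))
  }
  stopifnot(length(transforms) == n_slices)

  # deterministic structured landmarks: region centres plus ring points
  centers <- do.call(rbind, lapply(spec$regions, function(r) {
    c(r$center[1] * (w - 1) * sp[1], r$center[2] * (h - 1) * sp[2])
  }))
  ang <- seq(0, 2 * pi, length.out = landmarks_per_slice + 1L)[-1]
  ring <- cbind(ctr[1] + 0.3 * (w - 1) * sp[1] * cos(ang) / 2,
                ctr[2] + 0.3 * (h - 1) * sp[2] * sin(ang) / 2)
  base_pts <- rbind(centers, ring)[seq_len(landmarks_per_slice), ,
                                   drop = FALSE]

  slices <- vector("list", n_slices)
  chains <- vector("list", n_slices)
  lm_fixed <- vector("list", n_slices)
  lm_moving <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    k <- 1 + drift * sin(pi * (i - 1) / max(1, n_slices - 1))
    # radial drift: drifted(q) = base(ctr + (q - ctr) / k)
    pts <- .grid_points(h, w, sp)
    dp <- sweep(sweep(pts, 2, ctr), 2, rep(1 / k, 2), `*`)
    dvals <- .sample_image(base, sweep(dp, 2, ctr, `+`), sp)
    dvals[is.na(dvals)] <- 0
    drifted <- matrix(dvals, h, w)
    A <- transforms[[i]]
    slices[[i]] <- apply_chain(drifted, rigid_inverse(A), "linear", sp)
    chains[[i]] <- transform_chain(A)
    pdrift <- sweep(sweep(sweep(base_pts, 2, ctr), 2, rep(k, 2), `*`),
                    2, ctr, `+`)
    lm_fixed[[i]] <- pdrift
    lm_moving[[i]] <- .map_points(A, pdrift)
  }
  list(slices = slices, chains = chains,
       landmarks_fixed = lm_fixed, landmarks_moving = lm_moving,
       spacing = sp)
}
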