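# Slice-to-slice registration of ion images. Rasters are numeric matrices
# (rows = y, cols = x); physical coordinates are pixel-centre positions
# (col-1)*sx, (row-1)*sy in micrometres. Transforms are pull maps: the
# value of the aligned image at fixed-space point p is the moving image
# interpolated at T(p).

#' 2D rigid (Euler) transform
#'
#' Rotation by `theta` about `center` plus translation, as a pull map:
#' `T(p) = R(p - c) + c + t`.
#'
#' @param theta Rotation angle in radians.
#' @param tx,ty Translation in physical units (micrometres when a pixel
#'   spacing is used, pixels otherwise).
#' @param center Rotation centre (physical coordinates).
#' @return An object of class `msi_rigid`.
#' @export
rigid_transform <- function(theta = 0, tx = 0, ty = 0, center = c(0, 0)) {
  structure(list(theta = theta, tx = tx, ty = ty,
                 center = as.numeric(center)),
            class = "msi_rigid")
}

#' Invert a rigid transform
#' @param transform An `msi_rigid`.
#' @return The inverse `msi_rigid` (same centre).
#' @export
rigid_inverse <- function(transform) {
  th <- transform$theta
  Rt <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)  # R^T
  t2 <- -as.numeric(Rt %*% c(transform$tx, transform$ty))
  rigid_transform(-th, t2[1], t2[2], transform$center)
}

#' Transform chain
#'
#' An ordered list of transforms; application order is list order (the
#' first entry is applied to the image first). An empty chain is the
#' identity.
#' @param ... Transforms (`msi_rigid` or `msi_bspline`).
#' @return An object of class `msi_chain`.
#' @export
transform_chain <- function(...) {
  structure(list(...), class = "msi_chain")
}

.map_points <- function(transform, pts) {
  UseMethod(".map_points")
}
#' @export
.map_points.msi_rigid <- function(transform, pts) {
  th <- transform$theta
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- transform$center
  out <- sweep(pts, 2, ctr) %*% t(R)
  sweep(out, 2, ctr + c(transform$tx, transform$ty), `+`)
}
#' @export
.map_points.msi_bspline <- function(transform, pts) {
  pts + .bspline_disp_at(transform, pts)
}

# composed pull map of a chain (first entry applied to the image first)
.chain_map <- function(chain, pts) {
  for (t in rev(unclass(chain))) pts <- .map_points(t, pts)
  pts
}

# moving -> fixed mapping (inverse of the pull map)
.chain_unmap <- function(chain, pts) {
  for (t in unclass(chain)) {
    if (inherits(t, "msi_rigid")) {
      pts <- .map_points(rigid_inverse(t), pts)
    } else {
      # fixed-point inversion of p + disp(p) = q
      p <- pts
      for (k in 1:20) p <- pts - .bspline_disp_at(t, p)
      pts <- p
    }
  }
  pts
}

# -- interpolation ------------------------------------------------------------

# sample img (matrix, rows=y) at physical points; NA outside the domain
.sample_image <- function(img, pts, spacing = c(1, 1),
                          interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  h <- nrow(img); w <- ncol(img)
  cx <- pts[, 1] / spacing[1]   # 0-based column position
  cy <- pts[, 2] / spacing[2]
  if (interpolation == "nearest") {
    ix <- round(cx); iy <- round(cy)
    ok <- ix >= 0 & ix <= w - 1 & iy >= 0 & iy <= h - 1
    out <- rep(NA_real_, length(cx))
    out[ok] <- img[cbind(iy[ok] + 1, ix[ok] + 1)]
    return(out)
  }
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0;  fy <- cy - y0
  ok <- x0 >= -1 & x0 <= w - 1 & y0 >= -1 & y0 <= h - 1 &
        cx >= 0 & cx <= w - 1 & cy >= 0 & cy <= h - 1
  out <- rep(NA_real_, length(cx))
  if (any(ok)) {
    x0k <- pmin(pmax(x0[ok], 0), w - 1)
    y0k <- pmin(pmax(y0[ok], 0), h - 1)
    x1k <- pmin(x0k + 1, w - 1)
    y1k <- pmin(y0k + 1, h - 1)
    fxk <- fx[ok]; fyk <- fy[ok]
    v00 <- img[cbind(y0k + 1, x0k + 1)]
    v01 <- img[cbind(y0k + 1, x1k + 1)]
    v10 <- img[cbind(y1k + 1, x0k + 1)]
    v11 <- img[cbind(y1k + 1, x1k + 1)]
    out[ok] <- (1 - fyk) * ((1 - fxk) * v00 + fxk * v01) +
               fyk * ((1 - fxk) * v10 + fxk * v11)
  }
  out
}

.grid_points <- function(h, w, spacing) {
  cbind(rep((0:(w - 1)) * spacing[1], each = h),
        rep((0:(h - 1)) * spacing[2], times = w))
}

#' Apply a transform chain to a raster
#'
#' Resamples in a single interpolation pass through the composed pull map.
#' Out-of-domain pixels are 0. Use nearest-neighbour interpolation for
#' masks so binary rasters stay binary.
#'
#' @param raster Numeric matrix (rows = y).
#' @param chain `msi_chain`, a single transform, or `NULL`/empty (identity).
#' @param interpolation `"linear"` or `"nearest"`.
#' @param spacing Pixel size `c(sx, sy)` in physical units.
#' @return The resampled raster.
#' @export
apply_chain <- function(raster, chain, interpolation = c("linear",
                                                         "nearest"),
                        spacing = c(1, 1)) {
  interpolation <- match.arg(interpolation)
  if (inherits(chain, "msi_rigid") || inherits(chain, "msi_bspline")) {
    chain <- transform_chain(chain)
  }
  if (is.null(chain) || !length(chain)) return(raster)
  h <- nrow(raster); w <- ncol(raster)
  pts <- .chain_map(chain, .grid_points(h, w, spacing))
  vals <- .sample_image(raster, pts, spacing, interpolation)
  vals[is.na(vals)] <- 0
  matrix(vals, nrow = h)
}

#' Rotate an image about its centre
#'
#' Interactive pre-alignment step for heavily rotated sections; the applied
#' transform is returned so it can be recorded in the slice's chain.
#'
#' @param image Numeric matrix.
#' @param theta_deg Rotation in degrees, `|theta_deg| <= 180`.
#' @param spacing Pixel size.
#' @return `list(image =, transform =)`.
#' @export
pre_rotate <- function(image, theta_deg, spacing = c(1, 1)) {
  if (abs(theta_deg) > 180) stop("rotation must be within +/-180 degrees")
  ctr <- c((ncol(image) - 1) / 2 * spacing[1],
           (nrow(image) - 1) / 2 * spacing[2])
  tr <- rigid_transform(theta_deg * pi / 180, 0, 0, ctr)
  list(image = apply_chain(image, tr, "linear", spacing), transform = tr)
}

# -- metric -------------------------------------------------------------------

#' Mattes-style mutual information between two rasters
#'
#' Joint-histogram mutual information (default 32 x 32 bins, dense
#' sampling) over the pixels where both images are defined.
#'
#' @param a,b Numeric vectors or matrices of equal length; `NA` marks
#'   out-of-domain samples, which are excluded pairwise.
#' @param bins Histogram bins per axis.
#' @return Mutual information in nats.
#' @export
mattes_mi <- function(a, b, bins = 32L) {
  ok <- !is.na(a) & !is.na(b)
  a <- as.numeric(a)[ok]; b <- as.numeric(b)[ok]
  if (length(a) < 8L) return(-Inf)
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2]) {
    stop("metric error: constant image has no intensity distribution")
  }
  ba <- pmin(floor((a - ra[1]) / (ra[2] - ra[1]) * bins) + 1L, bins)
  bb <- pmin(floor((b - rb[1]) / (rb[2] - rb[1]) * bins) + 1L, bins)
  joint <- tabulate((ba - 1L) * bins + bb, nbins = bins * bins)
  p <- joint / sum(joint)
  pj <- matrix(p, nrow = bins)         # rows: b bins, cols: a bins
  pa <- colSums(pj); pb <- rowSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(pb, pa)[nz]))
}

# out-of-domain moving samples count as background (0) so every fixed
# pixel participates: shrinking the valid domain cannot masquerade as an
# alignment gain (small-sample mutual information is biased upwards)
.metric_value <- function(fixed_vals, moving_vals, metric, bins) {
  moving_vals[is.na(moving_vals)] <- 0
  if (metric == "mattes_mi") {
    mattes_mi(fixed_vals, moving_vals, bins)
  } else {
    -mean((fixed_vals - moving_vals)^2)
  }
}

# -- pyramid ------------------------------------------------------------------

.gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv <- function(x) {
    n <- length(x)
    pad <- c(rep(x[1], r), x, rep(x[n], r))
    as.numeric(stats::filter(pad, k, sides = 2))[(r + 1):(r + n)]
  }
  img <- apply(img, 2, conv)
  t(apply(img, 1, conv))
}

.downsample <- function(img, factor) {
  if (factor <= 1) return(img)
  img <- .gauss_blur(img, sigma = factor / 2)
  img[seq(1, nrow(img), by = factor), seq(1, ncol(img), by = factor),
      drop = FALSE]
}

#' Registration parameters
#'
#' @param pyramid_levels Number of multi-resolution levels (default 3).
#' @param downsampling_factors Per-level factors, coarse to fine
#'   (default 4, 2, 1); length must equal `pyramid_levels`.
#' @param metric `"mattes_mi"` (default) or `"mean_squares"`.
#' @param iterations Optimizer budget per level for the rigid stage
#'   (default 250).
#' @param interpolation `"linear"` (registration always samples linearly;
#'   kept for interface symmetry).
#' @param bins Mutual-information histogram bins (default 32).
#' @param search_theta_deg,search_step_deg Initializer grid half-range and
#'   step for rotation, degrees (defaults 16 and 2).
#' @param search_trans Initializer grid half-range for translation in
#'   physical units; default 12 pixels at the working spacing.
#' @param deformable_iterations Metric-evaluation budget for the built-in
#'   B-spline stage (default 750).
#' @param grid_spacing_mm Final B-spline control grid spacing on the
#'   original resolution, millimetres (default 0.8).
#' @param grid_scaling Per-level grid-spacing scale factors
#'   (default 2, 1.5, 1; the built-in deformable stage uses the final
#'   level).
#' @param seed Seed for any stochastic component (the built-in metric uses
#'   dense sampling and is deterministic; the seed is recorded for
#'   external backends).
#' @return A list of class `registration_params`.
#' @export
registration_params <- function(pyramid_levels = 3L,
                                downsampling_factors = c(4L, 2L, 1L),
                                metric = c("mattes_mi", "mean_squares"),
                                iterations = 250L,
                                interpolation = c("linear", "bspline3"),
                                bins = 32L,
                                search_theta_deg = 16,
                                search_step_deg = 2,
                                search_trans = NULL,
                                deformable_iterations = 750L,
                                grid_spacing_mm = 0.8,
                                grid_scaling = c(2, 1.5, 1),
                                seed = 42L) {
  metric <- match.arg(metric)
  interpolation <- match.arg(interpolation)
  if (length(downsampling_factors) != pyramid_levels) {
    stop("downsampling_factors length must equal pyramid_levels")
  }
  structure(list(pyramid_levels = pyramid_levels,
                 downsampling_factors = downsampling_factors,
                 metric = metric, iterations = iterations,
                 interpolation = interpolation, bins = bins,
                 search_theta_deg = search_theta_deg,
                 search_step_deg = search_step_deg,
                 search_trans = search_trans,
                 deformable_iterations = deformable_iterations,
                 grid_spacing_mm = grid_spacing_mm,
                 grid_scaling = grid_scaling, seed = seed),
            class = "registration_params")
}

#' Rigid registration of two rasters
#'
#' Finds the Euler transform (rotation about the image centre plus
#' translation) that maps the moving image onto the fixed image by
#' maximizing the similarity metric under a Gaussian multi-resolution
#' pyramid. The coarsest level is initialized by an exhaustive grid search
#' over rotation and translation; each level then refines the estimate
#' with a derivative-free simplex search bounded by the iteration budget.
#' Deterministic for fixed inputs and parameters.
#'
#' @param fixed,moving Numeric matrices of equal size.
#' @param params A [registration_params()] object.
#' @param spacing Pixel size `c(sx, sy)` in physical units.
#' @return An `msi_rigid` pull map (apply with [apply_chain()]); the final
#'   metric value is attached as attribute `"metric"`.
#' @export
register_rigid <- function(fixed, moving, params = registration_params(),
                           spacing = c(1, 1)) {
  if (!all(dim(fixed) > 1L) || !all(dim(moving) > 1L)) {
    stop("rasters must have positive size")
  }
  if (sd(fixed) == 0 || sd(moving) == 0) {
    stop("metric error: constant image cannot drive registration")
  }
  h <- nrow(fixed); w <- ncol(fixed)
  ctr <- c((w - 1) / 2 * spacing[1], (h - 1) / 2 * spacing[2])

  factors <- sort(params$downsampling_factors, decreasing = TRUE)
  make_obj <- function(f) {
    fx <- .downsample(fixed, f)
    mv <- .downsample(moving, f)
    sp <- spacing * f
    pts <- .grid_points(nrow(fx), ncol(fx), sp)
    fvals <- as.numeric(fx)
    # joint histograms need several samples per occupied bin, so the bin
    # count shrinks with the level's pixel count
    bins <- max(8L, min(params$bins, floor(sqrt(length(fvals) / 4))))
    list(sp = sp, fn = function(p) {
      tr <- rigid_transform(p[1], p[2], p[3], ctr)
      mvals <- .sample_image(mv, .map_points(tr, pts), sp)
      -.metric_value(fvals, mvals, params$metric, bins)
    })
  }
  refine <- function(obj, par, sp) {
    optim(par, obj, method = "Nelder-Mead",
          control = list(maxit = params$iterations, reltol = 1e-10,
                         parscale = c(0.05, 2 * sp[1], 2 * sp[2])))
  }

  # coarsest level: exhaustive grid, then refine the best few candidates
  # (the low-resolution metric can mis-rank nearby basins)
  o1 <- make_obj(factors[1])
  thetas <- seq(-params$search_theta_deg, params$search_theta_deg,
                by = params$search_step_deg) * pi / 180
  tmax <- params$search_trans %||% (12 * max(spacing))
  txs <- seq(-tmax, tmax, by = max(o1$sp))
  grid <- as.matrix(expand.grid(theta = c(0, thetas), tx = c(0, txs),
                                ty = c(0, txs)))
  vals <- apply(grid, 1L, o1$fn)
  top <- grid[order(vals)[seq_len(min(5L, nrow(grid)))], , drop = FALSE]
  starts <- lapply(seq_len(nrow(top)), function(k) {
    refine(o1$fn, top[k, ], o1$sp)
  })

  # rank the refined candidates at the next level before committing
  o2 <- if (length(factors) > 1L) make_obj(factors[2]) else o1
  scores <- vapply(starts, function(s) o2$fn(s$par), numeric(1))
  par <- starts[[which.min(scores)]]$par

  fit <- NULL
  for (f in factors[-1L]) {
    ol <- make_obj(f)
    fit <- refine(ol$fn, par, ol$sp)
    par <- fit$par
  }
  if (is.null(fit)) fit <- refine(o1$fn, par, o1$sp)
  out <- rigid_transform(fit$par[1], fit$par[2], fit$par[3], ctr)
  attr(out, "metric") <- -fit$value
  out
}

# -- built-in B-spline deformable stage ---------------------------------------

.bspline_kernel <- function(t) {
  at <- abs(t)
  ifelse(at < 1, (4 - 6 * at^2 + 3 * at^3) / 6,
         ifelse(at < 2, (2 - at)^3 / 6, 0))
}

# basis matrix: positions (physical, 1D) x control nodes at spacing g
.bspline_basis <- function(coords, g, n_ctrl) {
  u <- coords / g
  B <- matrix(0, length(coords), n_ctrl)
  for (k in seq_len(n_ctrl)) {
    node <- k - 2  # node index range -1 .. n_ctrl - 2
    B[, k] <- .bspline_kernel(u - node)
  }
  B
}

.make_bspline <- function(Dx, Dy, g, extent, spacing) {
  structure(list(Dx = Dx, Dy = Dy, grid_spacing = g, extent = extent,
                 spacing = spacing),
            class = "msi_bspline")
}

.bspline_disp_at <- function(tr, pts) {
  Bx <- .bspline_basis(pts[, 1], tr$grid_spacing, ncol(tr$Dx))
  By <- .bspline_basis(pts[, 2], tr$grid_spacing, nrow(tr$Dx))
  dx <- rowSums((By %*% tr$Dx) * Bx)
  dy <- rowSums((By %*% tr$Dy) * Bx)
  cbind(dx, dy)
}

#' Deformable (B-spline) refinement of a rigid alignment
#'
#' Built-in minimal implementation: cubic B-spline control-point
#' displacements on a regular grid are optimized by gradient-free
#' coordinate search (each node's x/y displacement is perturbed by a
#' shrinking set of steps; moves are kept only when the metric improves),
#' starting from the rigidly aligned moving image. An external
#' registration backend can be substituted via `backend`: a
#' `function(fixed, moving, initial, params, spacing)` returning an
#' `msi_chain` (parameter-file pass-through is the backend's concern).
#'
#' @param fixed,moving Numeric matrices.
#' @param initial The rigid `msi_rigid` from [register_rigid()].
#' @param params A [registration_params()] object; `grid_spacing_mm` sets
#'   the control spacing, `deformable_iterations` bounds the number of
#'   metric evaluations.
#' @param spacing Pixel size (physical units per pixel).
#' @param backend Optional external backend function; `NULL` uses the
#'   built-in stage. Set `backend = FALSE` to forbid the built-in (raises
#'   a configuration error), mirroring setups where only the external
#'   engine is acceptable.
#' @return An `msi_chain` of the rigid transform followed by the B-spline
#'   field; the final metric value is attached as attribute `"metric"`.
#' @export
register_deformable <- function(fixed, moving, initial,
                                params = registration_params(),
                                spacing = c(1, 1), backend = NULL) {
  if (isFALSE(backend)) {
    stop("configuration error: external backend unavailable and the ",
         "built-in deformable stage is disabled")
  }
  if (is.function(backend)) {
    return(backend(fixed, moving, initial, params, spacing))
  }
  h <- nrow(fixed); w <- ncol(fixed)
  moving_r <- apply_chain(moving, initial, "linear", spacing)
  g <- params$grid_spacing_mm * 1000  # physical units (micrometres)
  extent <- c((w - 1) * spacing[1], (h - 1) * spacing[2])
  n_cx <- ceiling(extent[1] / g) + 3L
  n_cy <- ceiling(extent[2] / g) + 3L
  Dx <- matrix(0, n_cy, n_cx)
  Dy <- matrix(0, n_cy, n_cx)

  pts <- .grid_points(h, w, spacing)
  Bx <- .bspline_basis(pts[, 1], g, n_cx)
  By <- .bspline_basis(pts[, 2], g, n_cy)
  fvals <- as.numeric(fixed)
  # mild quadratic penalty on control displacements (in pixels) keeps the
  # zero-deformation solution stable when the metric is flat
  reg <- 1e-3
  metric_of <- function(Dx, Dy) {
    dx <- rowSums((By %*% Dx) * Bx)
    dy <- rowSums((By %*% Dy) * Bx)
    mvals <- .sample_image(moving_r, cbind(pts[, 1] + dx, pts[, 2] + dy),
                           spacing)
    .metric_value(fvals, mvals, params$metric, params$bins) -
      reg * mean((Dx / spacing[1])^2 + (Dy / spacing[2])^2)
  }

  cur <- metric_of(Dx, Dy)
  budget <- params$deformable_iterations
  evals <- 0L
  steps <- c(1, 0.5, 0.25) * max(spacing)
  repeat {
    improved <- FALSE
    for (j in seq_len(n_cx)) {
      for (i in seq_len(n_cy)) {
        for (comp in 1:2) {
          for (s in steps) {
            for (sgn in c(1, -1)) {
              if (evals >= budget) break
              Dx2 <- Dx; Dy2 <- Dy
              if (comp == 1L) Dx2[i, j] <- Dx2[i, j] + sgn * s
              else Dy2[i, j] <- Dy2[i, j] + sgn * s
              v <- metric_of(Dx2, Dy2)
              evals <- evals + 1L
              if (v > cur + 1e-9) {
                cur <- v; Dx <- Dx2; Dy <- Dy2; improved <- TRUE
                break
              }
            }
          }
        }
      }
    }
    if (!improved || evals >= budget) break
  }
  out <- transform_chain(initial,
                         .make_bspline(Dx, Dy, g, extent, spacing))
  attr(out, "metric") <- cur
  out
}

#' Reconstruct a 3D stack by pairwise slice registration
#'
#' Starting at the reference slice (identity chain), each slice is
#' registered to the already-aligned neighbouring slice, moving outwards
#' in both directions. Spectra are never resampled: the returned chains
#' apply to ion images only.
#'
#' @param slices Ordered list of rasters (consecutive sections).
#' @param reference_index 1-based reference slice.
#' @param params A [registration_params()] object.
#' @param spacing Pixel size.
#' @param deformable Add the built-in B-spline refinement after the rigid
#'   stage.
#' @return A list of `msi_chain` objects, one per slice (identity at the
#'   reference).
#' @export
reconstruct_stack <- function(slices, reference_index = 1L,
                              params = registration_params(),
                              spacing = c(1, 1), deformable = FALSE) {
  n <- length(slices)
  if (n < 1L) stop("parameter error: empty stack")
  if (reference_index < 1L || reference_index > n) {
    stop("parameter error: reference_index out of range")
  }
  chains <- vector("list", n)
  chains[[reference_index]] <- transform_chain()
  align_next <- function(prev, i) {
    fixed <- apply_chain(slices[[prev]], chains[[prev]], "linear", spacing)
    r <- register_rigid(fixed, slices[[i]], params, spacing)
    if (deformable) {
      register_deformable(fixed, slices[[i]], r, params, spacing)
    } else {
      transform_chain(r)
    }
  }
  if (reference_index < n) {
    for (i in (reference_index + 1L):n) chains[[i]] <- align_next(i - 1L, i)
  }
  if (reference_index > 1L) {
    for (i in (reference_index - 1L):1L) chains[[i]] <- align_next(i + 1L, i)
  }
  chains
}

#' Landmark registration error
#'
#' Euclidean distance, in physical units, between each fixed-space
#' reference point and the corresponding moving-space point mapped into
#' fixed space through the chain (the inverse of the image pull map).
#'
#' @param fixed_points,moving_points n x 2 matrices (or data frames) of
#'   corresponding physical coordinates, same order.
#' @param chain The slice's `msi_chain` (or a single transform, or `NULL`
#'   for identity).
#' @return `list(mean =, sd =, per_point =)`; `sd` is the population
#'   standard deviation.
#' @export
landmark_error <- function(fixed_points, moving_points, chain = NULL) {
  fixed_points <- as.matrix(fixed_points)
  moving_points <- as.matrix(moving_points)
  if (!all(dim(fixed_points) == dim(moving_points))) {
    stop("pairing error: landmark sets differ in size")
  }
  if (inherits(chain, "msi_rigid") || inherits(chain, "msi_bspline")) {
    chain <- transform_chain(chain)
  }
  mapped <- if (is.null(chain) || !length(chain)) moving_points
            else .chain_unmap(chain, moving_points)
  d <- sqrt(rowSums((fixed_points - mapped)^2))
  list(mean = mean(d), sd = sqrt(mean((d - mean(d))^2)), per_point = d)
}

#' Serialize transform chains to JSON
#'
#' @param chains A list of `msi_chain` objects (one per slice).
#' @param path Output JSON path.
#' @param units Unit tag recorded in the file.
#' @return Invisibly, `path`.
#' @export
write_chains_json <- function(chains, path, units = "um") {
  ser <- lapply(seq_along(chains), function(i) {
    steps <- lapply(unclass(chains[[i]]), function(t) {
      if (inherits(t, "msi_rigid")) {
        list(type = "rigid", theta = t$theta, tx = t$tx, ty = t$ty,
             center = t$center)
      } else {
        list(type = "bspline", grid_spacing = t$grid_spacing,
             dx = t$Dx, dy = t$Dy)
      }
    })
    list(slice = i, steps = steps)
  })
  jsonlite::write_json(list(units = units, chains = ser), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
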