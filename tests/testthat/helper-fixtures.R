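# Shared fixtures and independent oracles. Everything is generated in
# code at test time; phantoms are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

# small continuous-profile dataset written by hand (not via make_phantom)
tiny_dataset <- function(n = 4L, depth = 6L, dir = tempfile("tiny"),
                         intensity_dtype = "float64", seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  mz <- as.numeric(seq(100, 100 + depth - 1))
  # integer-valued intensities: their partial sums are exact in floating
  # point, so chunked reductions are bit-identical for any worker count
  spectra <- lapply(seq_len(n), function(i) {
    list(mz = mz, intensity = as.numeric(sample.int(1000L, depth,
                                                    replace = TRUE)))
  })
  side <- ceiling(sqrt(n))
  coords <- cbind(((seq_len(n) - 1L) %% side) + 1L,
                  ((seq_len(n) - 1L) %/% side) + 1L)
  files <- write_imzml(spectra, coords, file.path(dir, "tiny.imzML"),
                       dialect = "continuous-profile",
                       intensity_dtype = intensity_dtype)
  list(files = files, spectra = spectra, coords = coords, mz = mz)
}

# the standard test phantom: finer axis than the package default so peak
# shapes are well sampled; cached across test files
test_phantom <- function() {
  if (!is.null(.fixture_cache$phantom)) return(.fixture_cache$phantom)
  spec <- phantom_spec(width = 40L, height = 40L,
                       mz_range = c(600, 1000), axis_depth = 1600L,
                       seed = 101L)
  ph <- make_phantom(spec, file.path(tempdir(), "msilazy-test-phantom"))
  ph$meta <- parse_imzml_metadata(ph$imzml)
  .fixture_cache$phantom <- ph
  ph
}

phantom_chain <- function() {
  signal_params(normalization = "tic", sg_window = 9L, sg_order = 2L,
                baseline = "tophat", baseline_halfwidth = 60L)
}

# brute-force peak-picking oracle: exhaustive double loop over windows,
# leftmost-of-plateau tie break
bf_pick_indices <- function(x, halfwindow, threshold) {
  n <- length(x)
  is_cand <- function(i) {
    w <- x[max(1L, i - halfwindow):min(n, i + halfwindow)]
    x[i] >= max(w) && x[i] > min(w) && x[i] > threshold
  }
  out <- integer(0)
  for (i in seq_len(n)) {
    if (!is_cand(i)) next
    if (i > 1L && x[i - 1L] == x[i] && is_cand(i - 1L)) next
    out <- c(out, i)
  }
  out
}

# direct least-squares Savitzky-Golay oracle for one interior point
sg_fit_center <- function(x, window, order) {
  h <- (window - 1L) %/% 2L
  t <- -h:h
  X <- outer(t, 0:order, `^`)
  c(X %*% solve(crossprod(X), crossprod(X, x)))[h + 1L]
}

# Poisson envelope fixture (exact model intensities)
poisson_envelope <- function(mono_mz, z, n_iso = 4L,
                             lambda_slope = 0.000594,
                             spacing = 1.00235,
                             mz_jitter = 0, int_noise = 0) {
  lambda <- lambda_slope * mono_mz
  k <- 0:(n_iso - 1L)
  mz <- mono_mz + k * spacing / z
  if (mz_jitter > 0) mz <- mz + c(0, rnorm(n_iso - 1L, sd = mz_jitter))
  int <- dpois(k, lambda)
  if (int_noise > 0) int <- int * pmax(1 + rnorm(n_iso, sd = int_noise), 0.05)
  peak_list(mz = mz, intensity = int)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
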