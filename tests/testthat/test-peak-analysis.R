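# MAD noise, sliding-window picking, binning, Poisson harvesting, sampling.

spec_of <- function(x, mz = seq_along(x)) {
  list(index = 1L, mz = mz, intensity = x)
}

test_that("MAD noise estimate matches the hand oracle", {
  expect_equal(estimate_noise_mad(rep(5, 10)), 0)
  expect_equal(estimate_noise_mad(c(1, 2, 3, 4, 5)), 1.4826)
  expect_equal(estimate_noise_mad(c(0, 0, 0, 0, 10)), 0)
  expect_error(estimate_noise_mad(numeric(0)), "empty")
})

test_that("peak picking: flat, single apex, resolved pair, plateaus", {
  expect_equal(nrow(pick_peaks(spec_of(rep(1, 50)), 4, 5)), 0L)

  # single noisy Gaussian apex at a known index
  set.seed(21)
  i0 <- 40L
  x <- 20 * exp(-((1:100) - i0)^2 / 8) + rnorm(100, sd = 0.5)
  pk <- pick_peaks(spec_of(x), snr_threshold = 4, halfwindow = 10)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$mz, i0)
  expect_gt(pk$snr, 4)

  # two Gaussians separated by more than 2*halfwindow
  x2 <- 20 * exp(-((1:200) - 60)^2 / 8) + 15 * exp(-((1:200) - 140)^2 / 8)
  pk2 <- pick_peaks(spec_of(x2 + rnorm(200, sd = 0.3)), 4, 10)
  expect_equal(pk2$mz, c(60, 140))

  # plateau: leftmost index wins
  x3 <- c(0, 0, 7, 7, 7, 0, 0)
  pk3 <- pick_peaks(spec_of(x3), snr_threshold = 1, halfwindow = 2,
                    noise = 1)
  expect_equal(pk3$mz, 3)

  expect_error(pick_peaks(spec_of(x3), 0, 2), "snr_threshold")
  expect_error(pick_peaks(spec_of(x3), 4, 0), "halfwindow")
})

test_that("peak picking equals the brute-force local-maxima oracle", {
  set.seed(33)
  for (k in 1:100) {
    n <- sample(32:512, 1)
    x <- pmax(0, rnorm(n, 2, 1))
    # sprinkle structured peaks and ties
    for (p in sample(n, 5)) x[p] <- x[p] + runif(1, 0, 10)
    if (k %% 3 == 0) {
      j <- sample(n - 1L, 1)
      x[j + 1L] <- x[j]
    }
    h <- sample(1:12, 1)
    thr <- runif(1, 0.5, 6)
    noise <- estimate_noise_mad(x)
    got <- pick_peaks(spec_of(x), snr_threshold = thr, halfwindow = h)
    want <- bf_pick_indices(x, h, thr * noise)
    expect_equal(got$mz, as.numeric(want))
  }
})

test_that("binning pools, partitions and weights correctly", {
  a <- peak_list(mz = c(100, 200, 300), intensity = c(1, 2, 3))
  dup <- bin_peaks(list(a, a, a), tolerance = 0.01)
  expect_equal(nrow(dup), 3L)
  expect_equal(dup$mz, c(100, 200, 300))
  expect_equal(sum(attr(dup, "bin_sizes")), 9L)

  b <- bin_peaks(peak_list(mz = c(100.000, 100.004),
                           intensity = c(5, 5)), tolerance = 0.01)
  expect_equal(nrow(b), 1L)
  expect_equal(b$mz, 100.002)
  expect_equal(b$intensity, 5)

  c2 <- bin_peaks(peak_list(mz = c(100.0, 100.1), intensity = c(1, 1)),
                  tolerance = 0.01)
  expect_equal(nrow(c2), 2L)
  expect_error(bin_peaks(a, 0), "tolerance")

  # member sets partition the pooled input on random lists
  set.seed(8)
  for (k in 1:20) {
    lists <- lapply(1:3, function(j) {
      m <- sort(runif(sample(5:30, 1), 100, 1000))
      m <- m[c(TRUE, diff(m) > 1e-6)]
      peak_list(mz = m, intensity = runif(length(m), 1, 10))
    })
    tol <- runif(1, 0.01, 5)
    out <- bin_peaks(lists, tol)
    expect_equal(sum(attr(out, "bin_sizes")),
                 sum(vapply(lists, nrow, integer(1))))
    expect_true(all(diff(out$mz) > 0))
  }
})

test_that("Poisson harvesting selects monoisotopic chain members", {
  # isolated peak passes through as a monoisotopic singleton
  single <- poisson_monoisotopic(peak_list(1000, 5), charges = 1:3)
  expect_true(single$is_monoisotopic)
  expect_true(is.na(single$isotope_group))

  # exact z=1 envelope at 1000 Da (lambda = 0.594)
  env1 <- poisson_envelope(1000, 1)
  out1 <- poisson_monoisotopic(env1, charges = 1L)
  expect_equal(out1$is_monoisotopic, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unique(out1$isotope_group), 1L)
  expect_equal(unique(out1$charge), 1L)

  # z=2 envelope: detected with charges={1,2}, untouched with charges={1}
  env2 <- poisson_envelope(1000, 2)
  out2 <- poisson_monoisotopic(env2, charges = c(1L, 2L))
  expect_equal(out2$charge[1], 2L)
  expect_equal(out2$is_monoisotopic, c(TRUE, FALSE, FALSE, FALSE))
  out2b <- poisson_monoisotopic(env2, charges = 1L)
  expect_true(all(is.na(out2b$isotope_group)))
  expect_true(all(out2b$is_monoisotopic))

  expect_error(poisson_monoisotopic(env1, charges = integer(0)), "charge")
})

test_that("sampling at common peaks takes the windowed maximum", {
  s <- spec_of(c(1, 2, 7, 4, 9), mz = c(100, 101, 102, 103, 110))
  pks <- peak_list(mz = c(102, 105, 110), intensity = c(1, 1, 1))
  expect_equal(sample_at_peaks(s, pks, tolerance = 0.1), c(7, 0, 9))
  # window spanning samples (2, 7, 4) picks 7
  expect_equal(sample_at_peaks(s, peak_list(102, 1), tolerance = 1.5),
               7)
})

test_that("mean-spectrum picking on the phantom recovers all analytes", {
  ph <- test_phantom()
  # overview from TIC-normalized spectra; smoothing and baseline
  # correction are applied to the mean spectrum itself before picking
  # (per-pixel baseline residuals would otherwise average into a pedestal)
  art <- initialize_artefacts(ph$meta,
                              signal_params(normalization = "tic"),
                              n_workers = 2L)
  mean_spec <- list(index = 0L, mz = art$overview$mz_axis,
                    intensity = art$overview$mean)
  mean_spec <- apply_signal_chain(mean_spec,
                                  signal_params(sg_window = 9L,
                                                sg_order = 2L,
                                                baseline = "tophat",
                                                baseline_halfwidth = 60L))
  pk <- pick_peaks(mean_spec, snr_threshold = 10, halfwindow = 8L)
  mono <- poisson_monoisotopic(pk, charges = 1L)
  mono <- mono[mono$is_monoisotopic, ]
  truth <- sort(unlist(ph$masses))
  step <- diff(ph$axis[1:2])
  hits <- vapply(truth, function(m) min(abs(mono$mz - m)), numeric(1))
  expect_true(all(hits <= 3 * step))        # recall = 1.0
  # false discoveries: monoisotopic calls away from any true analyte mass
  fd <- vapply(mono$mz, function(m) min(abs(truth - m)) > 1.5, logical(1))
  expect_lte(mean(fd), 0.1)
})

test_that("continuous-centroid export samples every pixel at the common
           list", {
  ph <- test_phantom()
  truth <- sort(unlist(ph$masses))[1:5]
  pks <- peak_list(mz = truth, intensity = rep(1, 5))
  out <- file.path(tempdir(), "centroid-export.imzML")
  export_centroid(ph$meta, pks, out, tolerance = 1.5,
                  params = signal_params(normalization = "tic"))
  m2 <- parse_imzml_metadata(out)
  expect_equal(m2$mode, "continuous")
  expect_equal(m2$representation, "centroid")
  expect_equal(m2$n_spectra, ph$meta$n_spectra)
  expect_true(all(m2$spectra$intensity_length == 5))
  s <- read_spectrum(m2, 7L)
  expect_equal(s$mz, truth)
  # oracle: recompute the sampled values for that pixel directly
  raw <- read_spectrum(ph$meta, 7L)
  proc <- apply_signal_chain(raw, signal_params(normalization = "tic"))
  expect_equal(s$intensity, sample_at_peaks(proc, pks, 1.5),
               tolerance = 1e-6)
})
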