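# Streaming imzML parsing, lazy .ibd access, chunked iteration, writing.

test_that("minimal continuous file: one spectrum of three points", {
  d <- tempfile(); dir.create(d)
  f <- write_imzml(list(list(mz = c(100, 101, 102),
                             intensity = c(1, 2, 3))),
                   coords = cbind(1L, 1L),
                   file.path(d, "min.imzML"), "continuous-profile")
  m <- parse_imzml_metadata(f$imzml)
  expect_equal(m$n_spectra, 1L)
  expect_equal(nrow(m$spectra), 1L)
  expect_equal(m$width, 1L)
  expect_equal(m$height, 1L)
  expect_equal(m$mode, "continuous")
  expect_equal(spectral_depth(m), 3L)
})

test_that("write-parse round trip preserves geometry, offsets and arrays", {
  td <- tiny_dataset(n = 4L, depth = 6L)
  m <- parse_imzml_metadata(td$files$imzml)
  expect_equal(m$n_spectra, 4L)
  expect_equal(m$width, 2L)
  expect_equal(m$height, 2L)
  for (i in 1:4) {
    s <- read_spectrum(m, i)
    expect_identical(s$mz, td$spectra[[i]]$mz)
    expect_identical(s$intensity, td$spectra[[i]]$intensity)
  }
  # intensities survive bit-identically at the declared dtype
  d2 <- tempfile(); dir.create(d2)
  f2 <- write_imzml(list(list(mz = c(1, 2, 3),
                              intensity = c(1.0, 2.5, 0.0))),
                    cbind(1L, 1L), file.path(d2, "bits.imzML"),
                    "continuous-profile", intensity_dtype = "float32")
  expect_identical(read_spectrum(parse_imzml_metadata(f2$imzml), 1)$intensity,
                   c(1.0, 2.5, 0.0))
})

test_that("write-parse-write is byte-idempotent for a fixed uuid", {
  td <- tiny_dataset(n = 3L, depth = 5L)
  m <- parse_imzml_metadata(td$files$imzml)
  uuid <- as.raw(strtoi(substring(m$uuid, seq(1, 31, 2), seq(2, 32, 2)),
                        16L))
  d2 <- tempfile(); dir.create(d2)
  sp <- lapply(1:3, function(i) read_spectrum(m, i)[c("mz", "intensity")])
  f2 <- write_imzml(sp, as.matrix(m$spectra[, c("x", "y", "z")]),
                    file.path(d2, "copy.imzML"), "continuous-profile",
                    mz_dtype = m$mz_dtype,
                    intensity_dtype = m$intensity_dtype, uuid = uuid)
  # same content modulo file name: compare the .ibd bytes and record table
  expect_identical(readBin(f2$ibd, "raw", file.size(f2$ibd)),
                   readBin(td$files$ibd, "raw",
                           file.size(td$files$ibd)))
  m2 <- parse_imzml_metadata(f2$imzml)
  expect_equal(m2$spectra, m$spectra)
})

test_that("continuous dialect: the m/z axis is shared across indices", {
  td <- tiny_dataset(n = 4L)
  m <- parse_imzml_metadata(td$files$imzml)
  expect_identical(read_spectrum(m, 1)$mz, read_spectrum(m, 2)$mz)
  expect_equal(length(unique(m$spectra$mz_offset)), 1L)
})

test_that("processed-centroid dialect keeps per-spectrum axes", {
  d <- tempfile(); dir.create(d)
  sp <- list(list(mz = c(100.5, 200.25), intensity = c(5, 6)),
             list(mz = c(100, 150, 200, 250, 300),
                  intensity = c(1, 2, 3, 4, 5)))
  f <- write_imzml(sp, cbind(1:2, 1L), file.path(d, "proc.imzML"),
                   "processed-centroid", intensity_dtype = "float64")
  m <- parse_imzml_metadata(f$imzml)
  expect_equal(m$mode, "processed")
  expect_equal(length(read_spectrum(m, 1)$mz), 2L)
  expect_equal(length(read_spectrum(m, 2)$mz), 5L)
  expect_identical(read_spectrum(m, 2)$intensity, c(1, 2, 3, 4, 5))
})

test_that("uuid in the XML equals the first 16 bytes of the .ibd", {
  td <- tiny_dataset()
  m <- parse_imzml_metadata(td$files$imzml)
  con <- file(td$files$ibd, "rb")
  head16 <- readBin(con, "raw", 16L)
  close(con)
  expect_identical(paste(format(head16), collapse = ""), m$uuid)
  # corrupting the header is detected
  bytes <- readBin(td$files$ibd, "raw", file.size(td$files$ibd))
  bytes[1] <- as.raw(bitwXor(as.integer(bytes[1]), 255L))
  writeBin(bytes, td$files$ibd)
  expect_error(parse_imzml_metadata(td$files$imzml), "uuid")
})

test_that("I/O error contracts: missing ibd, bounds, truncation, dialect", {
  td <- tiny_dataset()
  m <- parse_imzml_metadata(td$files$imzml)
  expect_error(read_spectrum(m, 0), "out of range")
  expect_error(read_spectrum(m, m$n_spectra + 1L), "out of range")

  # truncated .ibd is caught at parse (offset bookkeeping) ...
  bytes <- readBin(td$files$ibd, "raw", file.size(td$files$ibd))
  writeBin(bytes[1:40], td$files$ibd)
  expect_error(parse_imzml_metadata(td$files$imzml), "integrity|exceed")
  # ... and at read time when the file shrinks after parsing
  m$ibd_size <- length(bytes)
  expect_error(read_spectrum(m, m$n_spectra), "truncated")

  file.remove(td$files$ibd)
  expect_error(parse_imzml_metadata(td$files$imzml), "ibd")

  d <- tempfile(); dir.create(d)
  sp <- list(list(mz = c(1, 2), intensity = c(1, 1)),
             list(mz = c(1, 3), intensity = c(1, 1)))
  expect_error(write_imzml(sp, cbind(1:2, 1L), file.path(d, "bad.imzML"),
                           "continuous-profile"), "dialect")
})

test_that("chunked iteration is worker-invariant and equals the
           sequential oracle", {
  td <- tiny_dataset(n = 10L, depth = 8L)
  m <- parse_imzml_metadata(td$files$imzml)
  tic_fn <- function(s, i) sum(s$intensity)
  tics <- vapply(c(1L, 2L, 4L, 8L), function(w) {
    iterate_spectra_chunked(m, w, tic_fn, `+`)
  }, numeric(1))
  expect_true(all(tics == tics[1]))
  expect_equal(tics[1], sum(vapply(td$spectra,
                                   function(s) sum(s$intensity),
                                   numeric(1))))
  counts <- vapply(c(1L, 3L, 8L), function(w) {
    iterate_spectra_chunked(m, w, function(s, i) 1L, `+`)
  }, integer(1))
  expect_true(all(counts == 10L))
  # elementwise max against a brute-force loop
  brute <- Reduce(pmax, lapply(td$spectra, `[[`, "intensity"))
  expect_equal(iterate_spectra_chunked(m, 4L,
                                       function(s, i) s$intensity, pmax),
               brute)
  # a failing fn surfaces the first error
  expect_error(iterate_spectra_chunked(m, 2L, function(s, i) {
    if (i == 3L) stop("boom") else 0
  }, `+`), "boom")
})

test_that("written files are readable by an independent imzML parser", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  td <- tiny_dataset(n = 4L, depth = 6L)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "from pyimzml.ImzMLParser import ImzMLParser",
    "p = ImzMLParser(sys.argv[1])",
    "mz, ints = p.getspectrum(2)",
    "print(json.dumps({'coords': [list(c) for c in p.coordinates],",
    "                  'mz': list(mz), 'i': list(ints)}))"), script)
  out <- suppressWarnings(system2("python", c(script, td$files$imzml),
                                  stdout = TRUE, stderr = FALSE))
  skip_if(is.null(attr(out, "status")) && length(out) == 0,
          "pyimzml unavailable")
  res <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(res$coords[3, 1:2], td$coords[3, ])
  expect_equal(res$mz, td$spectra[[3]]$mz)
  expect_equal(res$i, td$spectra[[3]]$intensity, tolerance = 1e-6)
})
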