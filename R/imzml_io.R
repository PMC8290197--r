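# imzML 1.1 + .ibd access. The parser streams the XML in fixed-size text
# chunks and extracts <spectrum> blocks with regular expressions, so memory
# is proportional to the number of spectrum records, never to .ibd size.
# Binary arrays are little-endian; dtypes come from the CV params.

.DTYPES <- list(
  float64 = list(accession = "MS:1000523", name = "64-bit float",   size = 8L),
  float32 = list(accession = "MS:1000521", name = "32-bit float",   size = 4L),
  int64   = list(accession = "MS:1000522", name = "64-bit integer", size = 8L),
  int32   = list(accession = "MS:1000519", name = "32-bit integer", size = 4L)
)

.dtype_size <- function(dtype) .DTYPES[[dtype]]$size

.dtype_from_text <- function(text) {
  for (nm in names(.DTYPES)) {
    if (grepl(.DTYPES[[nm]]$accession, text, fixed = TRUE)) return(nm)
  }
  "float64"
}

# -- low-level binary helpers -------------------------------------------------

.read_array <- function(con, offset, n, dtype) {
  seek(con, where = offset, origin = "start")
  out <- switch(dtype,
    float64 = readBin(con, what = "double", n = n, size = 8L, endian = "little"),
    float32 = readBin(con, what = "double", n = n, size = 4L, endian = "little"),
    int32   = as.numeric(readBin(con, what = "integer", n = n, size = 4L,
                                 endian = "little")),
    int64   = {
      raw <- readBin(con, what = "raw", n = 8L * n)
      if (length(raw) < 8L * n) raw <- raw[0]  # force truncation error below
      if (length(raw) == 8L * n) .int64_from_raw(raw) else numeric(0)
    },
    stop("unsupported dtype: ", dtype)
  )
  if (length(out) < n) {
    stop("truncated .ibd: expected ", n, " elements at offset ", offset)
  }
  out
}

# little-endian int64 decoded into doubles (exact below 2^53)
.int64_from_raw <- function(raw) {
  m <- matrix(as.integer(raw), nrow = 8L)
  lo <- colSums(m[1:4, , drop = FALSE] * 2^c(0, 8, 16, 24))
  hi <- colSums(m[5:8, , drop = FALSE] * 2^c(0, 8, 16, 24))
  neg <- hi >= 2^31
  val <- lo + (hi - ifelse(neg, 2^32, 0)) * 2^32
  val
}

.int64_to_raw <- function(x) {
  x <- round(x)
  neg <- x < 0
  x64 <- x + ifelse(neg, 2^64, 0)
  hi <- floor(x64 / 2^32)
  lo <- x64 - hi * 2^32
  bytes <- function(v) {
    b0 <- v %% 256; v <- floor(v / 256)
    b1 <- v %% 256; v <- floor(v / 256)
    b2 <- v %% 256; v <- floor(v / 256)
    b3 <- v %% 256
    rbind(b0, b1, b2, b3)
  }
  as.raw(as.vector(rbind(bytes(lo), bytes(hi))))
}

.write_array <- function(con, x, dtype) {
  switch(dtype,
    float64 = writeBin(as.double(x), con, size = 8L, endian = "little"),
    float32 = writeBin(as.double(x), con, size = 4L, endian = "little"),
    int32   = writeBin(as.integer(round(x)), con, size = 4L, endian = "little"),
    int64   = writeBin(.int64_to_raw(x), con),
    stop("unsupported dtype: ", dtype)
  )
  invisible(NULL)
}

# -- XML snippet helpers ------------------------------------------------------

.xml_tags <- function(text, what = "(cvParam|userParam)") {
  pat <- paste0("<", what, "\\b[^>]*>")
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(text, gregexpr(pat, text))[[1]]
}

.tag_attr <- function(tag, attr) {
  m <- regmatches(tag, regexec(paste0(attr, "=\"([^\"]*)\""), tag))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

# value of the first cvParam with a given accession, NA if absent
.cv_value <- function(text, accession) {
  tags <- .xml_tags(text, "cvParam")
  hit <- tags[grepl(accession, tags, fixed = TRUE)]
  if (!length(hit)) return(NA_character_)
  .tag_attr(hit[1], "value")
}

.user_value <- function(text, name) {
  tags <- .xml_tags(text, "userParam")
  hit <- tags[grepl(paste0("name=\"", name, "\""), tags, fixed = TRUE)]
  if (!length(hit)) return(NA_character_)
  .tag_attr(hit[1], "value")
}

.uuid_clean <- function(x) tolower(gsub("[^0-9a-fA-F]", "", x))

.sibling_ibd <- function(path) {
  ibd <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd, path)) ibd <- paste0(path, ".ibd")
  ibd
}

# -- metadata parsing ---------------------------------------------------------

#' Parse imzML metadata without loading spectra
#'
#' Streams the `.imzML` XML in fixed-size text chunks (no DOM is built) and
#' collects image geometry, dialect flags, the binary-storage UUID and one
#' access record per spectrum (pixel position plus byte offsets into the
#' sibling `.ibd` file). No spectral arrays are read, so memory scales with
#' the number of spectra, not with the binary file size.
#'
#' @param path Path to an `.imzML` file with a sibling `.ibd` file.
#' @param verify_uuid Compare the XML UUID against the first 16 bytes of the
#'   `.ibd` file (always recommended; cheap).
#' @param verify_checksum If `TRUE` and the file declares an MD5 checksum,
#'   hash the whole `.ibd` and compare. Off by default: a checksum pass over
#'   a large `.ibd` defeats lazy loading.
#' @return An object of class `msi_dataset`: image geometry
#'   (`width`, `height`, `depth`, `pixel_size`), `mode`
#'   (`"continuous"`/`"processed"`), `representation`
#'   (`"profile"`/`"centroid"`), `uuid`, dtypes, and a data frame `spectra`
#'   with one row per spectrum in XML order (`x`, `y`, `z`, `mz_offset`,
#'   `mz_length`, `intensity_offset`, `intensity_length`, `norm_factor`).
#' @seealso [read_spectrum()], [write_imzml()], [iterate_spectra_chunked()]
#' @export
parse_imzml_metadata <- function(path, verify_uuid = TRUE,
                                 verify_checksum = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ibd <- .sibling_ibd(path)
  if (!file.exists(ibd)) stop("missing sibling .ibd for ", path)

  con <- file(path, open = "rb")
  on.exit(close(con), add = TRUE)

  chunk_size <- 65536L
  buf <- ""
  header <- NULL
  recs <- list()
  nrec <- 0L
  spectrum_open <- "<spectrum[ \t\r\n>]"

  repeat {
    piece <- readChar(con, nchars = chunk_size, useBytes = TRUE)
    eof <- length(piece) == 0L || !nzchar(piece)
    if (!eof) buf <- paste0(buf, piece)

    if (is.null(header)) {
      m <- regexpr(spectrum_open, buf)
      if (m[1] != -1) {
        header <- substr(buf, 1L, m[1] - 1L)
        buf <- substr(buf, m[1], nchar(buf))
      } else if (eof) {
        header <- buf
        buf <- ""
      }
    }
    if (!is.null(header)) {
      repeat {
        e <- regexpr("</spectrum>", buf, fixed = TRUE)
        if (e[1] == -1) break
        block <- substr(buf, 1L, e[1] + attr(e, "match.length") - 1L)
        buf <- substr(buf, e[1] + attr(e, "match.length"), nchar(buf))
        nrec <- nrec + 1L
        recs[[nrec]] <- .parse_spectrum_block(block, nrec)
      }
    }
    if (eof) break
  }
  if (is.null(header) || !grepl("<", header, fixed = TRUE)) {
    stop("malformed imzML: no XML content found in ", path)
  }
  if (nrec == 0L) stop("malformed imzML: no <spectrum> elements in ", path)

  # referenceable param groups: which one is the m/z array, which intensity
  grp_pat <- "<referenceableParamGroup\\b.*?</referenceableParamGroup>"
  grps <- regmatches(header, gregexpr(grp_pat, header))[[1]]
  mz_dtype <- intensity_dtype <- NULL
  mz_ref <- int_ref <- NA_character_
  for (g in grps) {
    id <- .tag_attr(g, "id")
    if (grepl("MS:1000514", g, fixed = TRUE)) {
      mz_ref <- id; mz_dtype <- .dtype_from_text(g)
    } else if (grepl("MS:1000515", g, fixed = TRUE)) {
      int_ref <- id; intensity_dtype <- .dtype_from_text(g)
    }
  }
  mz_dtype <- mz_dtype %||% "float64"
  intensity_dtype <- intensity_dtype %||% "float32"

  mode <- if (grepl("IMS:1000031", header, fixed = TRUE)) "processed"
          else "continuous"
  representation <- if (grepl("MS:1000127", header, fixed = TRUE)) "centroid"
                    else "profile"
  uuid <- .uuid_clean(.cv_value(header, "IMS:1000080") %||% "")
  if (!nzchar(uuid) || is.na(uuid)) uuid <- ""

  df <- do.call(rbind.data.frame, c(recs, stringsAsFactors = FALSE))
  rownames(df) <- NULL

  width  <- suppressWarnings(as.integer(.cv_value(header, "IMS:1000042")))
  height <- suppressWarnings(as.integer(.cv_value(header, "IMS:1000043")))
  if (is.na(width))  width  <- max(df$x)
  if (is.na(height)) height <- max(df$y)
  depth_px <- suppressWarnings(as.integer(.user_value(header,
                                                      "max count of pixels z")))
  if (is.na(depth_px)) depth_px <- max(df$z)
  px <- suppressWarnings(as.numeric(.cv_value(header, "IMS:1000046")))
  py <- suppressWarnings(as.numeric(.cv_value(header, "IMS:1000047")))
  pz <- suppressWarnings(as.numeric(.user_value(header, "pixel size z")))
  pixel_size <- c(x = ifelse(is.na(px), 1, px),
                  y = ifelse(is.na(py), 1, py),
                  z = ifelse(is.na(pz), 1, pz))

  ibd_size <- file.size(ibd)
  meta <- structure(list(
    imzml = normalizePath(path), ibd = normalizePath(ibd),
    width = width, height = height, depth = depth_px,
    pixel_size = pixel_size,
    mode = mode, representation = representation,
    uuid = uuid, mz_dtype = mz_dtype, intensity_dtype = intensity_dtype,
    n_spectra = nrow(df), spectra = df, ibd_size = ibd_size
  ), class = "msi_dataset")

  .validate_dataset(meta, verify_uuid = verify_uuid,
                    verify_checksum = verify_checksum, header = header)
  meta
}

.parse_spectrum_block <- function(block, ordinal) {
  x <- suppressWarnings(as.integer(.cv_value(block, "IMS:1000050")))
  y <- suppressWarnings(as.integer(.cv_value(block, "IMS:1000051")))
  z <- suppressWarnings(as.integer(.cv_value(block, "IMS:1000052")))
  if (is.na(z)) z <- 1L
  if (is.na(x) || is.na(y)) {
    stop("malformed imzML: spectrum ", ordinal, " lacks pixel position")
  }
  norm <- suppressWarnings(as.numeric(.user_value(block,
                                                  "normalization factor")))

  arrays <- regmatches(block,
    gregexpr("<binaryDataArray\\b.*?</binaryDataArray>", block))[[1]]
  if (length(arrays) < 2L) {
    stop("malformed imzML: spectrum ", ordinal, " has <2 binary arrays")
  }
  mz_off <- mz_len <- int_off <- int_len <- NA_real_
  for (a in arrays) {
    off <- as.numeric(.cv_value(a, "IMS:1000102"))
    len <- as.numeric(.cv_value(a, "IMS:1000103"))
    is_mz <- grepl("ref=\"mzArray\"", a, fixed = TRUE) ||
             grepl("MS:1000514", a, fixed = TRUE)
    is_int <- grepl("ref=\"intensityArray\"", a, fixed = TRUE) ||
              grepl("MS:1000515", a, fixed = TRUE)
    if (is_mz) { mz_off <- off; mz_len <- len }
    else if (is_int) { int_off <- off; int_len <- len }
  }
  if (anyNA(c(mz_off, mz_len, int_off, int_len))) {
    stop("malformed imzML: spectrum ", ordinal,
         " lacks external offset/length params")
  }
  list(index = ordinal, x = x, y = y, z = z,
       mz_offset = mz_off, mz_length = mz_len,
       intensity_offset = int_off, intensity_length = int_len,
       norm_factor = norm)
}

.validate_dataset <- function(meta, verify_uuid = TRUE,
                              verify_checksum = FALSE, header = "") {
  df <- meta$spectra
  if (any(df$x < 1L | df$x > meta$width |
          df$y < 1L | df$y > meta$height |
          df$z < 1L | df$z > meta$depth)) {
    stop("integrity error: spectrum pixel position outside the image grid")
  }
  if (any(df$mz_length != df$intensity_length)) {
    stop("integrity error: mz/intensity length mismatch in a spectrum record")
  }
  dmz <- .dtype_size(meta$mz_dtype)
  din <- .dtype_size(meta$intensity_dtype)
  if (any(df$mz_offset + df$mz_length * dmz > meta$ibd_size) ||
      any(df$intensity_offset + df$intensity_length * din > meta$ibd_size)) {
    stop("integrity error: binary offsets exceed .ibd size")
  }
  if (meta$mode == "continuous") {
    if (length(unique(df$mz_offset)) != 1L ||
        length(unique(df$mz_length)) != 1L) {
      stop("integrity error: continuous dataset with non-shared m/z array")
    }
  }
  if (verify_uuid && nzchar(meta$uuid)) {
    con <- file(meta$ibd, open = "rb")
    on.exit(close(con), add = TRUE)
    head16 <- readBin(con, what = "raw", n = 16L)
    if (!identical(paste(format(head16), collapse = ""), meta$uuid)) {
      stop("integrity error: XML uuid does not match .ibd header")
    }
  }
  if (verify_checksum) {
    md5 <- .cv_value(header, "IMS:1000090")
    if (!is.na(md5) &&
        !identical(tolower(md5), unname(tools::md5sum(meta$ibd)))) {
      stop("integrity error: .ibd MD5 checksum mismatch")
    }
  }
  invisible(meta)
}

#' @export
print.msi_dataset <- function(x, ...) {
  depth_s <- spectral_depth(x)
  cat("msi_dataset:", basename(x$imzml), "\n",
      " geometry  : ", x$width, "x", x$height, "x", x$depth,
      " px (", paste(x$pixel_size, collapse = "/"), " um)\n",
      " dialect   : ", x$mode, "-", x$representation, "\n",
      " spectra   : ", x$n_spectra, " (depth ", depth_s, ")\n",
      " est. memory (1 thread): ",
      format(estimate_memory(x$width * x$height * x$depth, depth_s, 1L),
             big.mark = ","), " bytes\n", sep = "")
  invisible(x)
}

#' Spectral depth of a dataset
#'
#' Number of samples per spectrum: the shared axis length for continuous
#' data, the maximum per-spectrum length for processed data.
#' @param meta An `msi_dataset`.
#' @return Integer depth.
#' @export
spectral_depth <- function(meta) {
  if (meta$mode == "continuous") as.integer(meta$spectra$mz_length[1])
  else as.integer(max(meta$spectra$mz_length))
}

# -- lazy spectrum access -----------------------------------------------------

.read_spectrum_con <- function(con, meta, index, validate = TRUE) {
  rec <- meta$spectra[index, ]
  mz <- .read_array(con, rec$mz_offset, rec$mz_length, meta$mz_dtype)
  intensity <- .read_array(con, rec$intensity_offset, rec$intensity_length,
                           meta$intensity_dtype)
  if (validate && is.unsorted(mz, strictly = TRUE)) {
    stop("spectrum ", index, ": m/z axis is not strictly ascending")
  }
  structure(list(index = index, mz = mz, intensity = intensity),
            class = "msi_spectrum")
}

#' Read one spectrum lazily from the .ibd file
#'
#' Seeks to the spectrum's byte offsets and decodes exactly one spectrum;
#' nothing else is read. For continuous data the returned m/z axis is
#' identical for every index.
#'
#' @param meta An `msi_dataset` from [parse_imzml_metadata()].
#' @param index 1-based spectrum ordinal in XML order.
#' @param validate Check that the m/z axis is strictly ascending.
#' @return A list of class `msi_spectrum` with `index`, `mz`, `intensity`.
#' @export
read_spectrum <- function(meta, index, validate = TRUE) {
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) ||
      index < 1L || index > meta$n_spectra) {
    stop("spectrum index out of range: ", index)
  }
  con <- file(meta$ibd, open = "rb")
  on.exit(close(con), add = TRUE)
  .read_spectrum_con(con, meta, index, validate = validate)
}

# -- chunked iteration --------------------------------------------------------

#' Chunked (multi-worker) reduction over all spectra
#'
#' Splits the spectrum ordinals into `n_workers` contiguous, equally sized
#' chunks (remainder to the last chunk). Each worker opens its own `.ibd`
#' connection, reads its spectra one at a time, applies `fn` and folds the
#' per-spectrum results with `reducer`; chunk results are folded the same
#' way. Spectrum data are discarded after processing, so retained memory is
#' proportional to the result size. For an associative, commutative
#' `reducer` the result is independent of `n_workers`.
#'
#' @param meta An `msi_dataset`.
#' @param n_workers Positive integer; chunks are processed with forked
#'   workers when `n_workers > 1` (falls back to sequential where forking
#'   is unavailable).
#' @param fn `function(spectrum, index)` returning a per-spectrum value;
#'   must not rely on shared mutable state.
#' @param reducer Associative, commutative `function(acc, value)`.
#' @param indices Optional subset of ordinals (default all).
#' @return The reduced value.
#' @export
iterate_spectra_chunked <- function(meta, n_workers = 1L, fn, reducer,
                                    indices = NULL) {
  indices <- if (is.null(indices)) seq_len(meta$n_spectra)
             else as.integer(indices)
  n <- length(indices)
  if (n == 0L) stop("no spectra to iterate over")
  w <- max(1L, min(as.integer(n_workers), n))
  base <- n %/% w
  sizes <- rep(base, w)
  sizes[w] <- n - base * (w - 1L)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  chunks <- lapply(seq_len(w), function(k) indices[starts[k]:ends[k]])

  run_chunk <- function(idx) {
    con <- file(meta$ibd, open = "rb")
    on.exit(close(con), add = TRUE)
    acc <- NULL
    first <- TRUE
    for (i in idx) {
      v <- fn(.read_spectrum_con(con, meta, i, validate = FALSE), i)
      if (first) { acc <- v; first <- FALSE } else acc <- reducer(acc, v)
    }
    acc
  }

  results <- if (w == 1L || .Platform$OS.type != "unix") {
    lapply(chunks, run_chunk)
  } else {
    # a failing fn is re-raised below from the try-error object, so
    # mclapply's own "scheduled core" warning is redundant
    suppressWarnings(parallel::mclapply(chunks, run_chunk, mc.cores = w))
  }
  bad <- vapply(results, inherits, logical(1), what = "try-error")
  if (any(bad)) {
    stop("worker error: ", attr(results[[which(bad)[1]]], "condition")$message)
  }
  Reduce(reducer, results[-1L], results[[1L]])
}

# -- writing ------------------------------------------------------------------

.XML_HEADER <- paste0(
  "<?xml version=\"1.0\" encoding=\"ISO-8859-1\"?>\n",
  "<mzML xmlns=\"http://psi.hupo.org/ms/mzml\" version=\"1.1\">\n",
  "  <cvList count=\"2\">\n",
  "    <cv id=\"MS\" fullName=\"Proteomics Standards Initiative Mass Spectrometry Ontology\" URI=\"http://psidev.info/ms/mzML/psi-ms.obo\"/>\n",
  "    <cv id=\"IMS\" fullName=\"Imaging MS Ontology\" URI=\"http://www.maldi-msi.org/download/imzml/imagingMS.obo\"/>\n",
  "  </cvList>\n")

.fmt_num <- function(x) {
  # offsets/lengths are exact integers stored as doubles
  formatC(x, format = "f", digits = if (all(x == round(x))) 0 else 6)
}

#' Write an imzML (+ .ibd) file
#'
#' Writes spectra in one of three dialects: `continuous-profile` and
#' `continuous-centroid` store one shared m/z axis, `processed-centroid`
#' stores a per-spectrum axis. A fresh binary UUID is generated (unless
#' given) and written to both the XML and the first 16 bytes of the `.ibd`.
#'
#' @param spectra List of `list(mz, intensity)` (or `msi_spectrum`) objects,
#'   or a `function(i)` returning one; length/number given by `coords`.
#' @param coords Integer matrix (n x 2 or n x 3) of 1-based pixel positions.
#' @param path Output `.imzML` path; the `.ibd` is written alongside.
#' @param dialect One of `"continuous-profile"`, `"continuous-centroid"`,
#'   `"processed-centroid"`.
#' @param pixel_size Numeric length-3 (x, y, z) in micrometres.
#' @param mz_dtype,intensity_dtype Binary encodings: `"float64"`,
#'   `"float32"`, `"int64"`, `"int32"`. Defaults 64-bit m/z, 32-bit
#'   intensity.
#' @param uuid Optional 16-byte raw vector; generated if `NULL`.
#' @param norm_factors Optional per-spectrum in-file normalization factors,
#'   written as spectrum-level user params.
#' @param width,height,depth Optional grid size; inferred from `coords`.
#' @return Invisibly, `list(imzml =, ibd =)` paths.
#' @export
write_imzml <- function(spectra, coords, path,
                        dialect = c("continuous-profile",
                                    "continuous-centroid",
                                    "processed-centroid"),
                        pixel_size = c(1, 1, 1),
                        mz_dtype = "float64", intensity_dtype = "float32",
                        uuid = NULL, norm_factors = NULL,
                        width = NULL, height = NULL, depth = NULL) {
  dialect <- match.arg(dialect)
  coords <- as.matrix(coords)
  if (ncol(coords) == 2L) coords <- cbind(coords, 1L)
  n <- nrow(coords)
  if (n < 1L) stop("need at least one spectrum")
  get_spec <- if (is.function(spectra)) spectra else function(i) spectra[[i]]
  if (!is.function(spectra) && length(spectra) != n) {
    stop("length(spectra) must match nrow(coords)")
  }
  continuous <- dialect != "processed-centroid"
  representation <- if (dialect == "continuous-profile") "profile"
                    else "centroid"
  width  <- width  %||% max(coords[, 1])
  height <- height %||% max(coords[, 2])
  depth  <- depth  %||% max(coords[, 3])
  if (is.null(uuid)) {
    uuid <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  }
  stopifnot(is.raw(uuid), length(uuid) == 16L)
  uuid_hex <- paste(format(uuid), collapse = "")
  uuid_str <- paste0("{", toupper(paste(
    substr(uuid_hex, 1, 8), substr(uuid_hex, 9, 12), substr(uuid_hex, 13, 16),
    substr(uuid_hex, 17, 20), substr(uuid_hex, 21, 32), sep = "-")), "}")

  ibd_path <- .sibling_ibd(path)
  ibd <- file(ibd_path, open = "wb")
  on.exit(tryCatch(close(ibd), error = function(e) NULL), add = TRUE)
  writeBin(uuid, ibd)
  offset <- 16

  dmz <- .dtype_size(mz_dtype)
  din <- .dtype_size(intensity_dtype)

  s1 <- get_spec(1L)
  shared_mz <- s1$mz
  if (continuous) {
    .write_array(ibd, shared_mz, mz_dtype)
    shared_mz_offset <- offset
    shared_mz_length <- length(shared_mz)
    offset <- offset + shared_mz_length * dmz
  }

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- if (i == 1L) s1 else get_spec(i)
    if (length(s$mz) != length(s$intensity)) {
      stop("spectrum ", i, ": mz and intensity lengths differ")
    }
    if (continuous) {
      if (length(s$mz) != shared_mz_length ||
          !isTRUE(all.equal(s$mz, shared_mz, tolerance = 0))) {
        stop("dialect error: continuous dialect requires one shared m/z ",
             "axis (spectrum ", i, " differs)")
      }
      mz_off <- shared_mz_offset; mz_len <- shared_mz_length
    } else {
      .write_array(ibd, s$mz, mz_dtype)
      mz_off <- offset; mz_len <- length(s$mz)
      offset <- offset + mz_len * dmz
    }
    .write_array(ibd, s$intensity, intensity_dtype)
    int_off <- offset; int_len <- length(s$intensity)
    offset <- offset + int_len * din
    recs[[i]] <- c(mz_off, mz_len, int_off, int_len)
  }
  close(ibd)

  xml <- file(path, open = "wb")
  on.exit(tryCatch(close(xml), error = function(e) NULL), add = TRUE)
  .write_imzml_xml(xml, recs, coords, n, width, height, depth, pixel_size,
                   continuous, representation, mz_dtype, intensity_dtype,
                   uuid_str, norm_factors)
  close(xml)
  invisible(list(imzml = path, ibd = ibd_path))
}

.write_imzml_xml <- function(con, recs, coords, n, width, height, depth,
                             pixel_size, continuous, representation,
                             mz_dtype, intensity_dtype, uuid_str,
                             norm_factors) {
  wl <- function(...) writeLines(paste0(...), con, useBytes = TRUE)
  mode_cv <- if (continuous) {
    "<cvParam cvRef=\"IMS\" accession=\"IMS:1000030\" name=\"continuous\"/>"
  } else {
    "<cvParam cvRef=\"IMS\" accession=\"IMS:1000031\" name=\"processed\"/>"
  }
  repr_cv <- if (representation == "profile") {
    "<cvParam cvRef=\"MS\" accession=\"MS:1000128\" name=\"profile spectrum\"/>"
  } else {
    "<cvParam cvRef=\"MS\" accession=\"MS:1000127\" name=\"centroid spectrum\"/>"
  }
  dt <- function(d) sprintf(
    "<cvParam cvRef=\"MS\" accession=\"%s\" name=\"%s\"/>",
    .DTYPES[[d]]$accession, .DTYPES[[d]]$name)

  writeChar(.XML_HEADER, con, eos = NULL, useBytes = TRUE)
  wl("  <fileDescription>")
  wl("    <fileContent>")
  wl("      ", mode_cv)
  wl("      ", repr_cv)
  wl("      <cvParam cvRef=\"IMS\" accession=\"IMS:1000080\" ",
     "name=\"universally unique identifier\" value=\"", uuid_str, "\"/>")
  wl("    </fileContent>")
  wl("  </fileDescription>")
  wl("  <referenceableParamGroupList count=\"2\">")
  wl("    <referenceableParamGroup id=\"mzArray\">")
  wl("      <cvParam cvRef=\"MS\" accession=\"MS:1000514\" name=\"m/z array\" unitCvRef=\"MS\" unitAccession=\"MS:1000040\" unitName=\"m/z\"/>")
  wl("      <cvParam cvRef=\"MS\" accession=\"MS:1000576\" name=\"no compression\"/>")
  wl("      ", dt(mz_dtype))
  wl("      <cvParam cvRef=\"IMS\" accession=\"IMS:1000101\" name=\"external data\" value=\"true\"/>")
  wl("    </referenceableParamGroup>")
  wl("    <referenceableParamGroup id=\"intensityArray\">")
  wl("      <cvParam cvRef=\"MS\" accession=\"MS:1000515\" name=\"intensity array\" unitCvRef=\"MS\" unitAccession=\"MS:1000131\" unitName=\"number of detector counts\"/>")
  wl("      <cvParam cvRef=\"MS\" accession=\"MS:1000576\" name=\"no compression\"/>")
  wl("      ", dt(intensity_dtype))
  wl("      <cvParam cvRef=\"IMS\" accession=\"IMS:1000101\" name=\"external data\" value=\"true\"/>")
  wl("    </referenceableParamGroup>")
  wl("  </referenceableParamGroupList>")
  wl("  <softwareList count=\"1\">")
  wl("    <software id=\"msilazy\" version=\"0.1.0\">")
  wl("      <cvParam cvRef=\"MS\" accession=\"MS:1000799\" name=\"custom unreleased software tool\" value=\"msilazy\"/>")
  wl("    </software>")
  wl("  </softwareList>")
  wl("  <scanSettingsList count=\"1\">")
  wl("    <scanSettings id=\"scanSettings1\">")
  wl("      <cvParam cvRef=\"IMS\" accession=\"IMS:1000042\" name=\"max count of pixels x\" value=\"", width, "\"/>")
  wl("      <cvParam cvRef=\"IMS\" accession=\"IMS:1000043\" name=\"max count of pixels y\" value=\"", height, "\"/>")
  wl("      <cvParam cvRef=\"IMS\" accession=\"IMS:1000046\" name=\"pixel size x\" value=\"", pixel_size[1], "\"/>")
  wl("      <cvParam cvRef=\"IMS\" accession=\"IMS:1000047\" name=\"pixel size y\" value=\"", pixel_size[2], "\"/>")
  wl("      <userParam name=\"max count of pixels z\" value=\"", depth, "\"/>")
  wl("      <userParam name=\"pixel size z\" value=\"", pixel_size[3], "\"/>")
  wl("    </scanSettings>")
  wl("  </scanSettingsList>")
  wl("  <instrumentConfigurationList count=\"1\">")
  wl("    <instrumentConfiguration id=\"IC1\"/>")
  wl("  </instrumentConfigurationList>")
  wl("  <dataProcessingList count=\"1\">")
  wl("    <dataProcessing id=\"export\">")
  wl("      <processingMethod order=\"1\" softwareRef=\"msilazy\">")
  wl("        <cvParam cvRef=\"MS\" accession=\"MS:1000544\" name=\"Conversion to mzML\"/>")
  wl("      </processingMethod>")
  wl("    </dataProcessing>")
  wl("  </dataProcessingList>")
  wl("  <run id=\"run1\" defaultInstrumentConfigurationRef=\"IC1\">")
  wl("    <spectrumList count=\"", n, "\">")
  for (i in seq_len(n)) {
    r <- recs[[i]]
    wl("      <spectrum index=\"", i - 1L, "\" id=\"spectrum=", i,
       "\" defaultArrayLength=\"", .fmt_num(r[4]), "\">")
    if (!is.null(norm_factors) && !is.na(norm_factors[i])) {
      wl("        <userParam name=\"normalization factor\" value=\"",
         formatC(norm_factors[i], format = "g", digits = 17), "\"/>")
    }
    wl("        <scanList count=\"1\">")
    wl("          <scan>")
    wl("            <cvParam cvRef=\"IMS\" accession=\"IMS:1000050\" name=\"position x\" value=\"", coords[i, 1], "\"/>")
    wl("            <cvParam cvRef=\"IMS\" accession=\"IMS:1000051\" name=\"position y\" value=\"", coords[i, 2], "\"/>")
    wl("            <cvParam cvRef=\"IMS\" accession=\"IMS:1000052\" name=\"position z\" value=\"", coords[i, 3], "\"/>")
    wl("          </scan>")
    wl("        </scanList>")
    wl("        <binaryDataArrayList count=\"2\">")
    wl("          <binaryDataArray encodedLength=\"0\">")
    wl("            <referenceableParamGroupRef ref=\"mzArray\"/>")
    wl("            <cvParam cvRef=\"IMS\" accession=\"IMS:1000102\" name=\"external offset\" value=\"", .fmt_num(r[1]), "\"/>")
    wl("            <cvParam cvRef=\"IMS\" accession=\"IMS:1000103\" name=\"external array length\" value=\"", .fmt_num(r[2]), "\"/>")
    wl("            <cvParam cvRef=\"IMS\" accession=\"IMS:1000104\" name=\"external encoded length\" value=\"", .fmt_num(r[2] * .dtype_size(mz_dtype)), "\"/>")
    wl("            <binary/>")
    wl("          </binaryDataArray>")
    wl("          <binaryDataArray encodedLength=\"0\">")
    wl("            <referenceableParamGroupRef ref=\"intensityArray\"/>")
    wl("            <cvParam cvRef=\"IMS\" accession=\"IMS:1000102\" name=\"external offset\" value=\"", .fmt_num(r[3]), "\"/>")
    wl("            <cvParam cvRef=\"IMS\" accession=\"IMS:1000103\" name=\"external array length\" value=\"", .fmt_num(r[4]), "\"/>")
    wl("            <cvParam cvRef=\"IMS\" accession=\"IMS:1000104\" name=\"external encoded length\" value=\"", .fmt_num(r[4] * .dtype_size(intensity_dtype)), "\"/>")
    wl("            <binary/>")
    wl("          </binaryDataArray>")
    wl("        </binaryDataArrayList>")
    wl("      </spectrum>")
  }
  wl("    </spectrumList>")
  wl("  </run>")
  wl("</mzML>")
  invisible(NULL)
}
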