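# Per-pixel feature matrices from ion-image stacks, PCA via SVD, and a
# pluggable t-SNE delegation.

#' Build a per-pixel feature matrix from ion images
#'
#' Column j is the ion image at peak j (same window tolerance and signal
#' chain for all peaks), flattened over the pixels that carry a spectrum.
#'
#' @param meta An `msi_dataset`.
#' @param peak_list An `msi_peaks` providing the m/z features.
#' @param tolerance Ion-image half-window (Da).
#' @param params [signal_params()] for the per-spectrum chain.
#' @param reducer Ion-image reducer (default `"max"`).
#' @param artefacts Optional artefact set from [initialize_artefacts()]
#'   (computed on the fly if missing).
#' @param n_workers Chunked iteration workers.
#' @return A matrix of class `msi_features` (rows = mask pixels, columns =
#'   peaks) with attributes `pixel_index` (linear raster indices) and
#'   `dims` (raster dimensions).
#' @export
build_feature_matrix <- function(meta, peak_list, tolerance,
                                 params = signal_params(),
                                 reducer = "max",
                                 artefacts = NULL, n_workers = 1L) {
  if (!nrow(peak_list)) stop("empty peak list")
  if (is.null(artefacts)) {
    artefacts <- initialize_artefacts(meta, params,
                                      n_workers = n_workers)$artefacts
  }
  mask <- artefacts$I_mask
  pix <- which(mask != 0)
  if (!length(pix)) stop("data error: empty mask")
  cols <- lapply(peak_list$mz, function(m) {
    img <- generate_ion_image(meta, m, tolerance, reducer, params,
                              n_workers = n_workers)
    img[pix]
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- sprintf("mz_%.4f", peak_list$mz)
  structure(mat, pixel_index = pix, dims = dim(mask),
            class = c("msi_features", class(mat)))
}

.scores_to_rasters <- function(scores, pixel_index, dims) {
  lapply(seq_len(ncol(scores)), function(k) {
    img <- array(0, dims)
    img[pixel_index] <- scores[, k]
    img
  })
}

#' Principal component images
#'
#' Columns are mean-centred (optionally unit-variance scaled) and the top
#' components are computed by singular value decomposition; per-component
#' scores are mapped back to the raster geometry.
#'
#' @param matrix An `msi_features` matrix.
#' @param n_components Number of components,
#'   `<= min(nrow, ncol)`.
#' @param scale Unit-variance scaling before the SVD (default off).
#' @return `list(component_images =, explained_variance_ratio =,
#'   scores =, loadings =)`.
#' @export
pca_images <- function(matrix, n_components = 3L, scale = FALSE) {
  n_components <- as.integer(n_components)
  if (n_components > min(dim(matrix))) {
    stop("parameter error: n_components exceeds matrix rank bound")
  }
  x <- base::scale(unclass(matrix), center = TRUE, scale = scale)
  sv <- svd(x)
  var_all <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  list(component_images = .scores_to_rasters(scores,
                                             attr(matrix, "pixel_index"),
                                             attr(matrix, "dims")),
       explained_variance_ratio = var_all[seq_len(n_components)],
       scores = scores,
       loadings = sv$v[, seq_len(n_components), drop = FALSE])
}

.default_tsne_backend <- function() {
  if (requireNamespace("Rtsne", quietly = TRUE)) {
    function(x, dims, seed) {
      set.seed(seed)
      perp <- min(30, floor((nrow(x) - 1) / 3))
      Rtsne::Rtsne(x, dims = dims, perplexity = perp,
                   check_duplicates = FALSE)$Y
    }
  } else {
    NULL
  }
}

#' t-SNE embedding images (delegated)
#'
#' Delegates the embedding to a standard t-SNE implementation and maps the
#' result back to the raster geometry, one channel per embedding
#' dimension, min-max normalized per channel. The backend is pluggable:
#' any `function(matrix, dims, seed)` returning an n x dims embedding.
#' Without a backend a capability error is raised (the package does not
#' re-implement t-SNE).
#'
#' @param matrix An `msi_features` matrix with >= 5 rows.
#' @param n_dims Target dimension (default 3).
#' @param seed Seed forwarded to the backend; a fixed seed must give an
#'   identical embedding.
#' @param backend Embedding function; defaults to the Rtsne package when
#'   installed.
#' @return `list(embedding_images =, embedding =)`.
#' @export
tsne_images <- function(matrix, n_dims = 3L, seed = 42L,
                        backend = .default_tsne_backend()) {
  if (nrow(matrix) < 5L) stop("need at least 5 pixels for an embedding")
  if (is.null(backend)) {
    stop("capability error: no t-SNE backend available; supply `backend` ",
         "or install a t-SNE implementation")
  }
  emb <- backend(unclass(matrix), n_dims, seed)
  stopifnot(nrow(emb) == nrow(matrix), ncol(emb) == n_dims)
  norm <- apply(emb, 2, function(v) {
    r <- range(v)
    if (r[1] == r[2]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  })
  list(embedding_images = .scores_to_rasters(norm,
                                             attr(matrix, "pixel_index"),
                                             attr(matrix, "dims")),
       embedding = emb)
}
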