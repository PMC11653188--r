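#' Z-score feature columns
#'
#' Morphometric features mix units (pixels, degrees, dimensionless), so
#' they are standardized before embedding. Constant columns map to zero.
#'
#' @param x Numeric matrix or data.frame of features.
#' @return Numeric matrix with columns of mean 0, sd 1.
#' @export
scale_features <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  scale(x, center = mu, scale = sdv)
}

#' UMAP embedding of the selected features
#'
#' Projects the (z-scored) feature matrix into a low-dimensional space
#' with uniform manifold approximation and projection. Defaults follow
#' common practice for morphometric tables: `n_neighbors = 10` balances
#' local and global structure, `min_dist = 0.1`, two output components.
#' Runs single-threaded so the result is bit-for-bit reproducible for a
#' given seed.
#'
#' @param x Feature matrix/data.frame (cells x features), or a feature
#'   table plus `features` column subset.
#' @param n_neighbors,min_dist,n_components UMAP hyperparameters.
#' @param seed Integer seed.
#' @param scale Z-score columns first (default TRUE).
#' @param features Optional feature column names when `x` is a table.
#' @return A `glia_embedding`: list with `coords` (n x n_components
#'   matrix, columns `umap1`, `umap2`, ...) and `params`.
#' @export
embed_features <- function(x, n_neighbors = 10, min_dist = 0.1,
                           n_components = 2, seed = NULL, scale = TRUE,
                           features = NULL) {
  if (is.data.frame(x)) {
    features <- features %||% feature_columns(x)
    x <- as.matrix(x[, features, drop = FALSE])
  }
  if (anyNA(x)) data_error("embed_features: missing values in features")
  if (n_neighbors >= nrow(x)) {
    config_error("embed_features: n_neighbors (", n_neighbors,
                 ") must be < number of rows (", nrow(x), ")")
  }
  if (scale) x <- scale_features(x)
  if (!is.null(seed)) set.seed(seed)
  coords <- uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
                       n_components = n_components, n_threads = 1,
                       n_sgd_threads = 0, verbose = FALSE)
  colnames(coords) <- paste0("umap", seq_len(n_components))
  structure(list(coords = coords,
                 params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                               n_components = n_components, seed = seed)),
            class = "glia_embedding")
}

#' @export
print.glia_embedding <- function(x, ...) {
  cat(sprintf("<glia_embedding> %d cells x %d components (n_neighbors=%d, min_dist=%g, seed=%s)\n",
              nrow(x$coords), ncol(x$coords), x$params$n_neighbors,
              x$params$min_dist, format(x$params$seed)))
  invisible(x)
}
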