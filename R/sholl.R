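#' Sholl intersection metrics
#'
#' Concentric circles with radii `step, 2*step, ...` are drawn around the
#' soma centroid, up to the largest radius that still reaches a skeleton
#' pixel. Crossings with each circle are counted as connected runs of
#' skeleton pixels inside the one-pixel annulus (not raw pixel hits, so a
#' thick intersection counts once), then summed over circles. The maximum
#' distance is the largest Euclidean distance between the centroid and the
#' four image corners.
#'
#' @param skeleton Binary skeleton matrix (cell-crop coordinates).
#' @param soma_centroid Numeric `(row, col)`, 0-based, in the skeleton's
#'   coordinate frame.
#' @param image_shape Integer `(height, width)` of the source image used
#'   for the corner distances; defaults to the skeleton's own shape.
#' @param centroid_in_image Optional 0-based `(row, col)` of the centroid
#'   in source-image coordinates (when the skeleton is a crop); defaults
#'   to `soma_centroid`.
#' @param step Radius increment in pixels (default 10).
#' @return Named numeric vector: `n_circles`, `n_crossings`, `max_distance`.
#' @export
sholl_metrics <- function(skeleton, soma_centroid, image_shape = NULL,
                          centroid_in_image = NULL, step = 10) {
  if (step <= 0) config_error("sholl_metrics: step must be > 0")
  s <- as_binary_matrix(skeleton)
  image_shape <- image_shape %||% dim(s)
  centroid_in_image <- centroid_in_image %||% soma_centroid
  corners <- rbind(c(0, 0), c(0, image_shape[2] - 1),
                   c(image_shape[1] - 1, 0),
                   c(image_shape[1] - 1, image_shape[2] - 1))
  max_distance <- max(sqrt((corners[, 1] - centroid_in_image[1])^2 +
                           (corners[, 2] - centroid_in_image[2])^2))
  fg <- which(s == 1L)
  if (length(fg) == 0L) {
    return(c(n_circles = 0, n_crossings = 0, max_distance = max_distance))
  }
  h <- nrow(s)
  rows <- ((fg - 1L) %% h)
  cols <- ((fg - 1L) %/% h)
  d <- sqrt((rows - soma_centroid[1])^2 + (cols - soma_centroid[2])^2)
  n_circles <- floor(max(d) / step)
  n_crossings <- 0L
  if (n_circles >= 1) {
    dall <- matrix(Inf, nrow(s), ncol(s))
    dall[fg] <- d
    for (k in seq_len(n_circles)) {
      ann <- matrix(as.integer(abs(dall - k * step) <= 0.5), nrow(s), ncol(s))
      n_crossings <- n_crossings + max(label_components(ann, 8))
    }
  }
  c(n_circles = as.numeric(n_circles), n_crossings = as.numeric(n_crossings),
    max_distance = max_distance)
}
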