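#' Box-counting fractal dimension of a silhouette
#'
#' The mask (boundary plus interior) is placed in a square dyadic canvas
#' and covered with grids of box side `s`; `N(s)` counts occupied boxes.
#' The dimension is minus the slope of the least-squares fit of
#' `log N(s)` against `log s`, clipped to `[0, 2]`. Default box sides are
#' dyadic, `2, 4, ..., S/2` for canvas side `S` (at least 8, so the fit
#' always has two points or more).
#'
#' @param mask Binary matrix with at least one foreground pixel.
#' @param box_sizes Box sides in pixels (at least two), or `NULL` for the
#'   dyadic default.
#' @return Fractal dimension (plane-filling sets approach 2, thin curves 1).
#' @examples
#' fractal_dimension(matrix(1L, 64, 64))  # ~2
#' @export
fractal_dimension <- function(mask, box_sizes = NULL) {
  m <- as_binary_matrix(mask)
  fg <- which(m == 1L)
  if (length(fg) == 0L) data_error("fractal_dimension: empty mask")
  h <- nrow(m); w <- ncol(m)
  side <- 2^ceiling(log2(max(h, w, 8)))
  if (is.null(box_sizes)) {
    box_sizes <- 2^(1:(log2(side) - 1))
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 2L) data_error("fractal_dimension: need >= 2 box sizes")
  rows <- ((fg - 1L) %% h)
  cols <- ((fg - 1L) %/% h)
  n_boxes <- vapply(box_sizes, function(s) {
    length(unique((rows %/% s) * (side %/% s + 1L) + (cols %/% s)))
  }, 0L)
  if (length(unique(n_boxes)) == 1L) {
    data_error("fractal_dimension: degenerate fit (box counts all equal)")
  }
  fit <- stats::lm.fit(cbind(1, log(box_sizes)), log(n_boxes))
  d <- -fit$coefficients[2]
  unname(min(max(d, 0), 2))
}
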