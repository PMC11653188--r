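# Shape descriptors shared by the soma, whole-cell and convex-hull feature
# families.

# Perimeter by the 4-direction Crofton estimate on 2x2 pixel patterns,
# plus pi to account for the half-pixel offset between pixel centres and
# the physical boundary (Minkowski dilation of the centre polygon by a
# radius-1/2 disk adds 2*pi*1/2 for convex silhouettes). The Crofton
# estimator is close to unbiased on smooth digitized outlines, where raw
# chain-code length overestimates by up to 8%.
perimeter_crofton <- function(mask) {
  m <- as_binary_matrix(mask)
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- m
  H <- h + 2L; W <- w + 2L
  a <- p[1:(H - 1), 1:(W - 1)]
  b <- p[1:(H - 1), 2:W]
  c_ <- p[2:H, 1:(W - 1)]
  d <- p[2:H, 2:W]
  code <- a + 4L * b + 2L * c_ + 8L * d
  cnt <- tabulate(code + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
             pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
             pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  sum(coefs * cnt) + pi
}

# boundary pixels = foreground with at least one background 8-neighbour
boundary_pixels <- function(m) {
  nb <- neighbor_count(m, 8)
  bd <- which(m == 1L & nb < 8L)
  rows <- ((bd - 1L) %% nrow(m)) + 1L
  cols <- ((bd - 1L) %/% nrow(m)) + 1L
  cbind(row = rows - 1, col = cols - 1)
}

# max caliper diameter: max pairwise distance between boundary pixel
# centres, + 1 for the two half-pixel extents
feret_diameter <- function(m) {
  pts <- boundary_pixels(m)
  if (nrow(pts) == 1L) return(1)
  hull <- grDevices::chull(pts[, "col"], pts[, "row"])
  hp <- pts[hull, , drop = FALSE]
  dmax <- max(dist(hp))
  dmax + 1
}

#' Shape metrics of a binary silhouette
#'
#' Computes the eight shape descriptors applied alike to the soma, the
#' whole cell, and its convex hull: area (foreground pixel count),
#' perimeter (Crofton 4-direction estimate with half-pixel correction),
#' circularity `4*pi*A/P^2` (1 for a perfect disk), Feret diameter
#' (maximum caliper), compactness (equivalent-circle diameter divided by
#' the Feret diameter), aspect ratio (bounding-box width/height),
#' orientation of the best-fit ellipse in degrees within `[0, 180)`
#' measured from the column (x) axis, and eccentricity defined as
#' major/minor axis length (>= 1). Second moments get the 1/12 unit-pixel
#' variance added so 1-pixel-wide shapes stay finite.
#'
#' @param mask Binary matrix with at least one foreground pixel.
#' @return Named numeric vector: `area`, `perimeter`, `circularity`,
#'   `feret_diameter`, `compactness`, `aspect_ratio`, `orientation`,
#'   `eccentricity`.
#' @examples
#' sq <- matrix(1L, 20, 20)
#' shape_metrics(sq)["eccentricity"]  # ~1: square has equal axes
#' @export
shape_metrics <- function(mask) {
  m <- as_binary_matrix(mask)
  fg <- which(m == 1L)
  if (length(fg) == 0L) data_error("shape_metrics: empty mask")
  area <- length(fg)
  if (area == 1L) {
    # single pixel: unit-square contour
    return(c(area = 1, perimeter = 4, circularity = 4 * pi / 16,
             feret_diameter = 1, compactness = sqrt(4 / pi),
             aspect_ratio = 1, orientation = 0, eccentricity = 1))
  }
  per <- perimeter_crofton(m)
  circ <- 4 * pi * area / per^2
  fer <- feret_diameter(m)
  comp <- sqrt(4 * area / pi) / fer
  bb <- mask_bbox(m)
  ar <- (bb[["col1"]] - bb[["col0"]]) / (bb[["row1"]] - bb[["row0"]])
  rows <- ((fg - 1L) %% nrow(m)) + 1L
  cols <- ((fg - 1L) %/% nrow(m)) + 1L
  x <- cols - mean(cols); y <- rows - mean(rows)
  m20 <- mean(x^2) + 1 / 12
  m02 <- mean(y^2) + 1 / 12
  m11 <- mean(x * y)
  common <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (m20 + m02 + common) / 2
  l2 <- (m20 + m02 - common) / 2
  ecc <- sqrt(l1 / max(l2, 1e-12))
  theta <- 0.5 * atan2(2 * m11, m20 - m02) * 180 / pi
  theta <- theta %% 180
  c(area = area, perimeter = per, circularity = circ, feret_diameter = fer,
    compactness = comp, aspect_ratio = unname(ar), orientation = theta,
    eccentricity = ecc)
}

#' Filled convex hull of a mask
#'
#' Smallest convex pixel set enclosing the cell: the convex polygon of the
#' foreground pixel centres, rasterized by including every pixel whose
#' centre lies inside or on the polygon. Always a superset of the input.
#'
#' @param mask Binary matrix with at least one foreground pixel.
#' @return Binary matrix of the same size.
#' @export
convex_hull_mask <- function(mask) {
  m <- as_binary_matrix(mask)
  fg <- which(m == 1L)
  if (length(fg) == 0L) data_error("convex_hull_mask: empty mask")
  h <- nrow(m); w <- ncol(m)
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  if (length(fg) <= 2L) return(m)
  hull <- grDevices::chull(cols, rows)  # counter-clockwise order
  hr <- rows[hull]; hc <- cols[hull]
  nh <- length(hull)
  if (nh < 3L) return(m)
  bb <- c(min(hr), max(hr), min(hc), max(hc))
  cand <- expand.grid(r = bb[1]:bb[2], c = bb[3]:bb[4])
  # orientation-independent: signed area fixes which cross-product sign
  # means "inside"
  jnx <- c(seq_len(nh)[-1], 1L)
  sgn <- sign(sum(hc * hr[jnx] - hc[jnx] * hr))
  if (sgn == 0) sgn <- 1
  inside <- rep(TRUE, nrow(cand))
  for (i in seq_len(nh)) {
    j <- jnx[i]
    cr <- (hc[j] - hc[i]) * (cand$r - hr[i]) - (hr[j] - hr[i]) * (cand$c - hc[i])
    inside <- inside & (sgn * cr >= -1e-9)
  }
  out <- matrix(0L, h, w)
  out[cbind(cand$r[inside], cand$c[inside])] <- 1L
  out[m == 1L] <- 1L  # numeric safety: hull always contains the input
  out
}
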