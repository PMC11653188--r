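#' Skeletonize a cell mask
#'
#' Zhang-Suen iterative thinning to a one-pixel-wide, topology-preserving
#' skeleton. The skeleton is a subset of the mask and keeps the number of
#' connected components.
#'
#' @param x A `glia_cell` record or binary matrix.
#' @return Binary matrix of the same size.
#' @export
skeletonize_cell <- function(x) {
  m <- as_binary_matrix(x) == 1L
  h <- nrow(m); w <- ncol(m)
  if (!any(m)) return(matrix(0L, h, w))
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- m
  sh <- function(dr, dc) p[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      cur <- p[2:(h + 1), 2:(w + 1)]
      P2 <- sh(-1, 0); P3 <- sh(-1, 1); P4 <- sh(0, 1); P5 <- sh(1, 1)
      P6 <- sh(1, 0); P7 <- sh(1, -1); P8 <- sh(0, -1); P9 <- sh(-1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      cond <- if (sub == 1) !(P2 & P4 & P6) & !(P4 & P6 & P8)
              else          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      del <- cur & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        changed <- TRUE
        cur[del] <- FALSE
        p[2:(h + 1), 2:(w + 1)] <- cur
      }
    }
    if (!changed) break
  }
  out <- matrix(0L, h, w)
  out[p[2:(h + 1), 2:(w + 1)]] <- 1L
  out
}

#' Detect the soma of a cell
#'
#' The soma is taken as the largest connected component that survives a
#' morphological opening with a disk: processes thinner than the
#' structuring element are erased while the compact cell body persists.
#' If the opening empties the mask entirely (cell thinner than the element
#' everywhere), the fallback is the maximal inscribed disk of the mask
#' (centre and radius from the distance transform), intersected with the
#' mask, so the result is never empty.
#'
#' @param cell A `glia_cell` record or binary matrix.
#' @param opening_radius Disk radius in pixels (default 6, sized for
#'   microglial somata at 40x).
#' @return Binary soma mask of the same size as the input.
#' @export
detect_soma <- function(cell, opening_radius = 6) {
  m <- as_binary_matrix(cell)
  if (!any(m == 1L)) data_error("detect_soma: empty mask")
  h <- nrow(m); w <- ncol(m)
  pad <- opening_radius + 1L
  p <- matrix(0L, h + 2L * pad, w + 2L * pad)
  p[pad + (1:h), pad + (1:w)] <- m
  kern <- EBImage::makeBrush(odd_brush(2L * opening_radius + 1L), shape = "disc")
  op <- EBImage::opening(p, kern)
  op <- as_binary_matrix(op)[pad + (1:h), pad + (1:w), drop = FALSE]
  if (any(op == 1L)) {
    lab <- label_components(op, 8)
    sizes <- tabulate(lab[lab > 0L])
    best <- which.max(sizes)
    return(matrix(as.integer(lab == best), h, w))
  }
  # fallback: maximal inscribed disk
  dm <- EBImage::distmap(p)
  dm <- matrix(as.numeric(dm), nrow(p), ncol(p))[pad + (1:h), pad + (1:w), drop = FALSE]
  ctr <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  r <- max(max(dm), 1)
  d2 <- outer((seq_len(h) - ctr[1])^2, (seq_len(w) - ctr[2])^2, `+`)
  soma <- matrix(as.integer(d2 <= r^2 & m == 1L), h, w)
  if (!any(soma == 1L)) soma[ctr[1], ctr[2]] <- 1L
  soma
}

#' Skeleton topology metrics
#'
#' Counts on a one-pixel-wide skeleton using 8-connectivity:
#' * `n_endpoints` -- skeleton pixels with exactly one skeleton neighbour;
#' * `n_junctions` -- pixels with three or more neighbours, with touching
#'   junction pixels merged into a single junction;
#' * `n_initial_points` -- skeleton pixels outside the soma that touch it,
#'   i.e. processes emerging from the cell body;
#' * `branch_length` -- skeleton pixels outside the soma. With
#'   `diagonal_weight = TRUE` diagonal steps add `sqrt(2) - 1` each, an
#'   edge-weighted approximation of geodesic length.
#'
#' @param skeleton Binary matrix (see [skeletonize_cell()]).
#' @param soma Binary matrix of the soma, or `NULL` for no soma (all
#'   skeleton pixels count toward branch length; no initial points).
#' @param diagonal_weight Weight diagonal steps by `sqrt(2)` instead of 1.
#' @return Named numeric vector: `branch_length`, `n_initial_points`,
#'   `n_junctions`, `n_endpoints`.
#' @export
skeleton_metrics <- function(skeleton, soma = NULL, diagonal_weight = FALSE) {
  s <- as_binary_matrix(skeleton)
  zero <- c(branch_length = 0, n_initial_points = 0, n_junctions = 0,
            n_endpoints = 0)
  if (!any(s == 1L)) return(zero)
  nb <- neighbor_count(s, 8)
  n_end <- sum(s == 1L & nb == 1L)
  junc <- matrix(as.integer(s == 1L & nb >= 3L), nrow(s), ncol(s))
  n_junc <- max(label_components(junc, 8))
  if (is.null(soma)) {
    outside <- s
    n_init <- 0L
  } else {
    so <- as_binary_matrix(soma)
    stopifnot(all(dim(so) == dim(s)))
    outside <- matrix(as.integer(s == 1L & so == 0L), nrow(s), ncol(s))
    adj <- neighbor_count(so, 8)
    n_init <- sum(outside == 1L & adj >= 1L)
  }
  bl <- sum(outside)
  if (diagonal_weight && bl > 0) {
    # count diagonal adjacencies between outside-skeleton pixels that have
    # no orthogonal 2-step detour, each lengthens the path by sqrt(2)-1
    h <- nrow(s); w <- ncol(s)
    p <- matrix(0L, h + 2L, w + 2L)
    p[2:(h + 1), 2:(w + 1)] <- outside
    ndiag <- 0L
    for (d in list(c(1, 1), c(-1, 1))) {
      a <- p[2:(h + 1), 2:(w + 1)]
      b <- p[(2 + d[1]):(h + 1 + d[1]), (2 + d[2]):(w + 1 + d[2])]
      o1 <- p[(2 + d[1]):(h + 1 + d[1]), 2:(w + 1)]
      o2 <- p[2:(h + 1), (2 + d[2]):(w + 1 + d[2])]
      ndiag <- ndiag + sum(a & b & !o1 & !o2)
    }
    bl <- bl + (sqrt(2) - 1) * ndiag
  }
  c(branch_length = bl, n_initial_points = as.numeric(n_init),
    n_junctions = as.numeric(n_junc), n_endpoints = as.numeric(n_end))
}
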