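# Shape builders and independent brute-force oracles used across tests.

disk_raster <- function(r, pad = 10) {
  side <- 2 * r + 2 * pad
  ctr <- side / 2
  d2 <- outer((1:side - ctr)^2, (1:side - ctr)^2, `+`)
  matrix(as.integer(d2 <= r^2), side, side)
}

rect_raster <- function(width, height, pad = 10) {
  m <- matrix(0L, height + 2 * pad, width + 2 * pad)
  m[pad + (1:height), pad + (1:width)] <- 1L
  m
}

# two crossing 3-px bars
plus_raster <- function(arm = 25, thick = 3, pad = 5) {
  side <- 2 * arm + thick + 2 * pad
  m <- matrix(0L, side, side)
  mid <- pad + arm + (1:thick)
  m[mid, (pad + 1):(side - pad)] <- 1L
  m[(pad + 1):(side - pad), mid] <- 1L
  m
}

sierpinski_raster <- function(depth) {
  m <- matrix(1L, 1, 1)
  for (i in seq_len(depth)) {
    z <- matrix(0L, nrow(m), ncol(m))
    m <- rbind(cbind(m, z), cbind(m, m))
  }
  m
}

# per-pixel loop oracle for skeleton metrics (independent of the
# vectorized implementation)
oracle_skeleton_metrics <- function(skel, soma = NULL) {
  h <- nrow(skel); w <- ncol(skel)
  nb_at <- function(m, r, c) {
    cnt <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && m[rr, cc] == 1L) {
        cnt <- cnt + 1L
      }
    }
    cnt
  }
  endpoints <- 0L
  junction_px <- matrix(0L, h, w)
  for (r in 1:h) for (c in 1:w) {
    if (skel[r, c] != 1L) next
    nb <- nb_at(skel, r, c)
    if (nb == 1L) endpoints <- endpoints + 1L
    if (nb >= 3L) junction_px[r, c] <- 1L
  }
  # merge adjacent junction pixels by flood fill
  njunc <- 0L
  seen <- matrix(FALSE, h, w)
  for (r in 1:h) for (c in 1:w) {
    if (junction_px[r, c] == 1L && !seen[r, c]) {
      njunc <- njunc + 1L
      stack <- list(c(r, c))
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        if (seen[p[1], p[2]]) next
        seen[p[1], p[2]] <- TRUE
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              junction_px[rr, cc] == 1L && !seen[rr, cc]) {
            stack[[length(stack) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  if (is.null(soma)) soma <- matrix(0L, h, w)
  init <- 0L
  blen <- 0L
  for (r in 1:h) for (c in 1:w) {
    if (skel[r, c] == 1L && soma[r, c] == 0L) {
      blen <- blen + 1L
      if (nb_at(soma, r, c) >= 1L) init <- init + 1L
    }
  }
  c(branch_length = blen, n_initial_points = init, n_junctions = njunc,
    n_endpoints = endpoints)
}

oracle_chisq <- function(tab) {
  N <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / N
  sum((tab - E)^2 / E)
}

# full-enumeration two-sided Mann-Whitney p-value (no ties)
oracle_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, `>`))
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

expect_binary_equal <- function(a, b) {
  expect_identical(unname(as_bin01(a)), unname(as_bin01(b)))
}
as_bin01 <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  m[m != 0L] <- 1L
  m
}

# small labelled scene set reused by pipeline-ish tests
build_test_cells <- function(seed, scenes = 2, per = c(ramified = 3, amoeboid = 3)) {
  cells <- list(); arch <- character(0)
  for (s in seq_len(scenes)) {
    sc <- make_scene(scene_spec(canvas = c(650, 650), n_cells = per,
                                min_separation = 30, seed = seed * 50 + s,
                                group = if (s %% 2) "A" else "B",
                                lateral_mm = 0.48 + 0.1 * s,
                                image_id = sprintf("t%d_%d", seed, s)))
    cl <- segment_cells(sc$image)
    arch <- c(arch, match_truth(cl, sc$truth))
    cells <- c(cells, cl)
  }
  list(cells = cells, archetype = arch)
}
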