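# Internal raster helpers. Masks are integer/logical matrices indexed
# [row, col]; user-facing coordinates are 0-based with origin at the
# top-left pixel centre.

# condition constructors so the CLI can map error classes to exit codes
config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("gliaclust_config_error", "error")))
}
data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("gliaclust_data_error", "error")))
}

as_binary_matrix <- function(x) {
  if (is.list(x) && !is.null(x$mask)) x <- x$mask
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "integer"
  x[x != 0L] <- 1L
  x
}

# sum of 8-neighbourhood (or 4-) foreground counts for every pixel
neighbor_count <- function(m, connectivity = 8) {
  m <- as_binary_matrix(m)
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- m
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  out <- matrix(0L, h, w)
  for (d in offs) {
    out <- out + p[(2 + d[1]):(h + 1 + d[1]), (2 + d[2]):(w + 1 + d[2])]
  }
  out
}

# Connected-component labelling via the adjacency graph of foreground
# pixels. Deterministic: components are relabelled later by position.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- as_binary_matrix(mask)
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  fg <- which(m == 1L)
  if (length(fg) == 0L) return(lab)
  node <- integer(h * w)
  node[fg] <- seq_along(fg)
  offs <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(-1, 1)))
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  from <- integer(0); to <- integer(0)
  for (d in offs) {
    r2 <- rows + d[1]; c2 <- cols + d[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    idx2 <- (c2[ok] - 1L) * h + r2[ok]
    hit <- m[idx2] == 1L
    from <- c(from, node[fg[ok]][hit])
    to <- c(to, node[idx2][hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

# filled disk raster; odd side 2*r+1, centre pixel included
disk_matrix <- function(r) {
  s <- 2L * as.integer(r) + 1L
  cc <- r + 1
  d2 <- outer((1:s - cc)^2, (1:s - cc)^2, `+`)
  matrix(as.integer(d2 <= r^2 + 1e-9), s, s)
}

odd_brush <- function(width) {
  s <- max(1L, as.integer(width))
  if (s %% 2L == 0L) s <- s + 1L
  s
}

# bbox of foreground as half-open 0-based (row0, col0, row1, col1)
mask_bbox <- function(m) {
  m <- as_binary_matrix(m)
  fg <- which(m == 1L)
  if (length(fg) == 0L) return(NULL)
  rows <- ((fg - 1L) %% nrow(m)) + 1L
  cols <- ((fg - 1L) %/% nrow(m)) + 1L
  c(row0 = min(rows) - 1L, col0 = min(cols) - 1L,
    row1 = max(rows), col1 = max(cols))
}

mask_centroid <- function(m) {
  m <- as_binary_matrix(m)
  fg <- which(m == 1L)
  rows <- ((fg - 1L) %% nrow(m)) + 1L
  cols <- ((fg - 1L) %/% nrow(m)) + 1L
  c(row = mean(rows) - 1, col = mean(cols) - 1)
}

# derive a stream of sub-seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
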