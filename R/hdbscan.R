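#' HDBSCAN clustering of an embedding
#'
#' Hierarchical density-based clustering with noise. Implementation of the
#' standard algorithm: (1) core distance of each point = distance to its
#' `min_samples`-th nearest neighbour (counting the point itself);
#' (2) mutual-reachability distance `max(core_i, core_j, d_ij)`;
#' (3) minimum spanning tree of the mutual-reachability graph;
#' (4) single-linkage hierarchy condensed with the `min_cluster_size`
#' threshold; (5) cluster extraction by excess of mass: a cluster is kept
#' when its stability (integral of point memberships over density
#' lambda = 1/distance) exceeds the summed stability of its children.
#' Points never captured by a selected cluster are labelled noise (-1).
#' A single all-encompassing cluster is not reported: if the hierarchy
#' never splits into two viable clusters, everything is noise.
#'
#' Cluster ids are renumbered by decreasing size, so cluster 0 is always
#' the largest.
#'
#' @param emb A `glia_embedding` (see [embed_features()]) or a numeric
#'   matrix of coordinates.
#' @param min_cluster_size Smallest viable cluster (default 20).
#' @param min_samples Neighbour count for the core distance (default 10).
#' @return A `glia_clusters`: list with `labels` (integer, -1 = noise),
#'   `cluster_sizes` (named), and `params`.
#' @export
cluster_cells <- function(emb, min_cluster_size = 20, min_samples = 10) {
  X <- if (inherits(emb, "glia_embedding")) emb$coords else as.matrix(emb)
  if (min_cluster_size < 2L) config_error("min_cluster_size must be >= 2")
  if (min_samples < 1L) config_error("min_samples must be >= 1")
  n <- nrow(X)
  labels <- rep(-1L, n)
  if (n < min_cluster_size) {
    warning("fewer points (", n, ") than min_cluster_size (",
            min_cluster_size, "): all labelled noise")
  } else {
    labels <- hdbscan_labels(X, min_cluster_size, min_samples)
  }
  sizes <- table(labels[labels >= 0L])
  structure(list(labels = labels,
                 cluster_sizes = sizes,
                 params = list(min_cluster_size = min_cluster_size,
                               min_samples = min_samples)),
            class = "glia_clusters")
}

#' @export
print.glia_clusters <- function(x, ...) {
  k <- length(x$cluster_sizes)
  cat(sprintf("<glia_clusters> %d points, %d cluster(s), %d noise (min_cluster_size=%d, min_samples=%d)\n",
              length(x$labels), k, sum(x$labels == -1L),
              x$params$min_cluster_size, x$params$min_samples))
  if (k) print(x$cluster_sizes)
  invisible(x)
}

hdbscan_labels <- function(X, min_cluster_size, min_samples) {
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  k <- min(min_samples, n)
  core <- apply(d, 1, function(r) sort(r, partial = k)[k])
  mr <- pmax(d, outer(core, core, pmax))
  diag(mr) <- 0
  mst <- prim_mst(mr)
  hier <- single_linkage(mst, n)
  cond <- condense_tree(hier, n, min_cluster_size)
  extract_eom(cond, n)
}

# Prim's algorithm on a dense distance matrix, O(n^2)
prim_mst <- function(w) {
  n <- nrow(w)
  in_tree <- logical(n)
  best <- rep(Inf, n)
  from <- integer(n)
  in_tree[1] <- TRUE
  best <- w[1, ]
  from[] <- 1L
  edges <- matrix(0, n - 1L, 3L)
  for (i in seq_len(n - 1L)) {
    best[in_tree] <- Inf
    v <- which.min(best)
    edges[i, ] <- c(from[v], v, best[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & w[v, ] < best
    best[upd] <- w[v, upd]
    from[upd] <- v
  }
  edges[order(edges[, 3]), , drop = FALSE]
}

# single-linkage dendrogram from MST edges sorted ascending; returns
# children (2 x (n-1)), heights, sizes per node (leaves 1..n, merges
# n+1..2n-1)
single_linkage <- function(edges, n) {
  parent <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  sizes <- c(rep(1L, n), integer(n - 1L))
  children <- matrix(0L, 2L, n - 1L)
  heights <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    ra <- find(edges[i, 1]); rb <- find(edges[i, 2])
    node <- n + i
    children[, i] <- c(ra, rb)
    heights[i] <- edges[i, 3]
    sizes[node] <- sizes[ra] + sizes[rb]
    parent[ra] <- node
    parent[rb] <- node
  }
  list(children = children, heights = heights, sizes = sizes)
}

subtree_leaves <- function(hier, node, n) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v)
    else stack <- c(stack, hier$children[, v - n])
  }
  out
}

# Condense the single-linkage tree: clusters persist through merges where
# the smaller side is below min_cluster_size (those points "fall out"),
# and split where both sides are viable.
condense_tree <- function(hier, n, mcs) {
  lam <- function(h) 1 / max(h, 1e-12)
  cl_parent <- integer(0)      # condensed-tree parent of each cluster
  cl_birth <- numeric(0)       # birth lambda
  cl_stab <- numeric(0)        # accumulated stability
  cl_children <- list()        # condensed children ids
  pt_cluster <- integer(n)     # cluster each point fell out of
  new_cluster <- function(parent, birth) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_stab[length(cl_stab) + 1L] <<- 0
    cl_children[[length(cl_parent)]] <<- integer(0)
    if (parent > 0L) {
      cl_children[[parent]] <<- c(cl_children[[parent]], length(cl_parent))
    }
    length(cl_parent)
  }
  root_node <- 2L * n - 1L
  root <- new_cluster(0L, 0)
  stack_nodes <- root_node
  stack_cl <- root
  while (length(stack_nodes)) {
    i <- length(stack_nodes)
    node <- stack_nodes[i]; cl <- stack_cl[i]
    stack_nodes <- stack_nodes[-i]; stack_cl <- stack_cl[-i]
    if (node <= n) {  # singleton root (n == 1): falls out immediately
      pt_cluster[node] <- cl
      next
    }
    kids <- hier$children[, node - n]
    h <- hier$heights[node - n]
    l <- lam(h)
    s <- hier$sizes[kids]
    big <- s >= mcs
    if (all(big)) {
      # true split: current cluster dies here, two children are born
      cl_stab[cl] <- cl_stab[cl] + sum(s) * (l - cl_birth[cl])
      for (kid in kids) {
        stack_nodes <- c(stack_nodes, kid)
        stack_cl <- c(stack_cl, new_cluster(cl, l))
      }
    } else if (any(big)) {
      # the small side falls out; the big side continues the cluster
      small <- kids[!big]
      pts <- subtree_leaves(hier, small, n)
      pt_cluster[pts] <- cl
      cl_stab[cl] <- cl_stab[cl] + length(pts) * (l - cl_birth[cl])
      stack_nodes <- c(stack_nodes, kids[big])
      stack_cl <- c(stack_cl, cl)
    } else {
      # both sides too small: the cluster evaporates
      for (kid in kids) {
        pts <- subtree_leaves(hier, kid, n)
        pt_cluster[pts] <- cl
        cl_stab[cl] <- cl_stab[cl] + length(pts) * (l - cl_birth[cl])
      }
    }
  }
  list(parent = cl_parent, birth = cl_birth, stability = cl_stab,
       children = cl_children, pt_cluster = pt_cluster)
}

# Excess-of-mass selection; root (id 1) is never selected.
extract_eom <- function(cond, n) {
  m <- length(cond$parent)
  selected <- logical(m)
  subtree_stab <- numeric(m)
  for (id in rev(seq_len(m))) {
    kids <- cond$children[[id]]
    if (id == 1L) {
      selected[1L] <- FALSE
      next
    }
    if (!length(kids)) {
      selected[id] <- TRUE
      subtree_stab[id] <- cond$stability[id]
    } else if (cond$stability[id] >= sum(subtree_stab[kids])) {
      selected[id] <- TRUE
      subtree_stab[id] <- cond$stability[id]
      # unselect all descendants
      stack <- kids
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        selected[v] <- FALSE
        stack <- c(stack, cond$children[[v]])
      }
    } else {
      subtree_stab[id] <- sum(subtree_stab[kids])
    }
  }
  # assign each point to the selected ancestor of its fall-out cluster
  sel_anc <- integer(m)  # 0 = none
  for (id in seq_len(m)) {
    cur <- id
    hit <- 0L
    while (cur > 0L) {
      if (selected[cur]) { hit <- cur; break }
      cur <- cond$parent[cur]
    }
    sel_anc[id] <- hit
  }
  raw <- sel_anc[cond$pt_cluster]
  labels <- rep(-1L, n)
  if (any(raw > 0L)) {
    kept <- sort(unique(raw[raw > 0L]))
    sizes <- vapply(kept, function(k) sum(raw == k), 0L)
    ord <- kept[order(-sizes, kept)]
    for (j in seq_along(ord)) labels[raw == ord[j]] <- j - 1L
  }
  labels
}
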