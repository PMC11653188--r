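#' Colour palette for cluster painting
#'
#' Okabe-Ito colourblind-safe hues for clusters 0, 1, 2, ...; mid-gray
#' (`#808080`) is reserved for noise. Colours are distinct, so a painted
#' image can be decoded back to labels exactly.
#'
#' @param n Number of clusters.
#' @return Character vector of `n` hex colours (attribute `noise` holds
#'   the reserved noise colour).
#' @export
cluster_palette <- function(n) {
  base <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
            "#D55E00", "#CC79A7", "#000000", "#999933", "#882255",
            "#44AA99", "#AA4499", "#117733", "#DDCC77", "#332288")
  if (n > length(base)) {
    extra <- grDevices::hcl(h = seq(15, 375, length.out = n - length(base) + 1)[-1],
                            c = 100, l = 45)
    base <- c(base, extra)
  }
  structure(base[seq_len(n)], noise = "#808080")
}

#' Paint cluster-coloured cells onto the image canvas
#'
#' Re-maps every segmented cell onto its source image, filling its mask
#' with the colour of its cluster; noise cells get the reserved gray.
#' Background pixels stay black. This is the spatial-validation view: the
#' cluster structure becomes visible in tissue context.
#'
#' @param img `glia_mask` or integer `(height, width)` of the canvas.
#' @param cells List of `glia_cell` records belonging to the image.
#' @param labels Integer cluster labels (-1 = noise) named by `cell_id`,
#'   or in the same order as `cells`; every cell must be covered.
#' @param palette Cluster colours (default [cluster_palette()]).
#' @return `height x width x 3` array in `[0, 1]` with attributes
#'   `palette` and `noise_color`.
#' @export
paint_clusters <- function(img, cells, labels, palette = NULL) {
  shape <- if (inherits(img, "glia_mask")) dim(img$pixels) else as.integer(img)
  labs <- label_vector(labels)
  if (!is.null(names(labs))) {
    ids <- vapply(cells, `[[`, "", "cell_id")
    miss <- setdiff(ids, names(labs))
    if (length(miss)) {
      data_error("paint_clusters: no cluster label for cell(s): ",
                 paste(miss, collapse = ", "))
    }
    labs <- labs[ids]
  } else if (length(labs) != length(cells)) {
    data_error("paint_clusters: ", length(cells), " cells but ",
               length(labs), " labels")
  }
  maxk <- if (any(labs >= 0L)) max(labs) + 1L else 0L
  palette <- palette %||% cluster_palette(max(maxk, 1L))
  noise_col <- attr(palette, "noise") %||% "#808080"
  canvas <- array(0, dim = c(shape[1], shape[2], 3))
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    col <- if (labs[i] < 0L) noise_col else palette[labs[i] + 1L]
    rgb <- grDevices::col2rgb(col)[, 1] / 255
    bb <- cl$bbox
    idx <- which(cl$mask == 1L, arr.ind = TRUE)
    rr <- idx[, 1] + bb[["row0"]]
    cc <- idx[, 2] + bb[["col0"]]
    for (ch in 1:3) canvas[cbind(rr, cc, ch)] <- rgb[ch]
  }
  attr(canvas, "palette") <- palette
  attr(canvas, "noise_color") <- noise_col
  canvas
}

label_vector <- function(labels) {
  if (inherits(labels, "glia_clusters")) return(labels$labels)
  v <- as.integer(labels)
  names(v) <- names(labels)
  v
}

#' Read layer polygon annotations
#'
#' JSON file `{image_id: {layer_name: [[row, col], ...], ...}, ...}` with
#' 0-based image coordinates, e.g. the CA1 strata SO, SPyr and SR.
#'
#' @param path JSON file.
#' @return Named list: per image, a named list of `n x 2` vertex matrices.
#' @export
read_layer_annotations <- function(path) {
  if (!file.exists(path)) data_error("annotation file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(layers) {
    lapply(layers, function(v) {
      m <- matrix(as.numeric(unlist(v)), ncol = 2, byrow = !is.matrix(v))
      if (is.matrix(v)) m <- v
      colnames(m) <- c("row", "col")
      m
    })
  })
}

# ray-casting point-in-polygon with inclusive boundary: a point on an
# edge or vertex counts as inside
point_in_polygon <- function(pr, pc, poly) {
  nv <- nrow(poly)
  j <- nv
  inside <- FALSE
  for (i in seq_len(nv)) {
    ri <- poly[i, 1]; ci <- poly[i, 2]
    rj <- poly[j, 1]; cj <- poly[j, 2]
    # boundary test: point on segment i-j
    cross <- (cj - ci) * (pr - ri) - (rj - ri) * (pc - ci)
    if (abs(cross) < 1e-9 &&
        pc >= min(ci, cj) - 1e-9 && pc <= max(ci, cj) + 1e-9 &&
        pr >= min(ri, rj) - 1e-9 && pr <= max(ri, rj) + 1e-9) {
      return(TRUE)
    }
    if ((ri > pr) != (rj > pr)) {
      xint <- ci + (pr - ri) * (cj - ci) / (rj - ri)
      if (pc < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Count cluster membership per anatomical layer
#'
#' A cell belongs to the layer polygon containing its centroid (boundary
#' inclusive); cells inside no layer are tallied as `"unassigned"`. If
#' polygons overlap, the first listed layer wins and a warning is issued.
#' Noise cells (label -1) are excluded. Relative frequencies are per
#' layer: cluster count over total assigned cells of that layer (`NA`
#' when the layer is empty).
#'
#' @param cells List of `glia_cell` records of one image.
#' @param labels Cluster labels as in [paint_clusters()].
#' @param annotation Named list of layer polygons for this image
#'   (`n x 2` matrices of 0-based `(row, col)` vertices).
#' @param include_noise Count noise cells too (default FALSE).
#' @return data.frame: `group`, `image_id`, `unit_type` (`"layer"`),
#'   `unit_name`, `cluster`, `count`, `rel_freq`.
#' @export
count_by_layer <- function(cells, labels, annotation, include_noise = FALSE) {
  labs <- align_labels(cells, labels)
  keep <- include_noise | labs >= 0L
  cells <- cells[keep]; labs <- labs[keep]
  layer_names <- names(annotation)
  assigned <- character(length(cells))
  overlap <- FALSE
  for (i in seq_along(cells)) {
    ctr <- cells[[i]]$centroid
    hits <- vapply(annotation, function(poly)
      point_in_polygon(ctr[["row"]], ctr[["col"]], poly), TRUE)
    if (sum(hits) > 1L) overlap <- TRUE
    assigned[i] <- if (any(hits)) layer_names[which(hits)[1]] else "unassigned"
  }
  if (overlap) warning("overlapping layer polygons: cells assigned to the first listed layer")
  clusters <- sort(unique(labs))
  units <- c(layer_names, "unassigned")
  grid <- expand.grid(unit_name = units, cluster = clusters,
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(u, k) sum(assigned == u & labs == k),
                       grid$unit_name, grid$cluster)
  totals <- vapply(units, function(u) sum(assigned == u), 0L)
  grid$rel_freq <- ifelse(totals[grid$unit_name] > 0,
                          grid$count / totals[grid$unit_name], NA_real_)
  data.frame(group = cells[[1]]$group %||% NA_character_,
             image_id = cells[[1]]$image_id %||% NA_character_,
             unit_type = "layer", grid, row.names = NULL,
             stringsAsFactors = FALSE)
}

align_labels <- function(cells, labels) {
  labs <- label_vector(labels)
  if (!is.null(names(labs))) {
    ids <- vapply(cells, `[[`, "", "cell_id")
    miss <- setdiff(ids, names(labs))
    if (length(miss)) {
      data_error("no cluster label for cell(s): ", paste(miss, collapse = ", "))
    }
    labs <- unname(labs[ids])
  } else if (length(labs) != length(cells)) {
    data_error(length(cells), " cells but ", length(labs), " labels")
  }
  labs
}

#' Mean cluster counts per lateral-distance bin
#'
#' Cells are grouped into half-open lateral bins
#' `[start + k*width, start + (k+1)*width)` from the slice coordinate in
#' their metadata (defaults reproduce 240-micron intervals from 0.48 mm).
#' Within each (group, bin, cluster) the per-image cell counts are
#' averaged over the images falling in that bin. Cells without a lateral
#' coordinate are excluded with a message. Noise is excluded.
#'
#' @param cells List of `glia_cell` records (any number of images).
#' @param labels Cluster labels as in [paint_clusters()].
#' @param bin_start First bin edge in mm (default 0.48).
#' @param bin_width Bin width in mm (default 0.24).
#' @param include_noise Count noise cells too (default FALSE).
#' @return data.frame: `group`, `unit_type` (`"lateral_bin"`), `unit_name`
#'   (`"[a,b)"`), `bin_start`, `cluster`, `mean_count`, `n_images`.
#' @export
count_by_lateral_bin <- function(cells, labels, bin_start = 0.48,
                                 bin_width = 0.24, include_noise = FALSE) {
  labs <- align_labels(cells, labels)
  keep <- include_noise | labs >= 0L
  cells <- cells[keep]; labs <- labs[keep]
  lat <- vapply(cells, function(cl) cl$lateral_mm %||% NA_real_, 0)
  drop <- is.na(lat)
  if (any(drop)) {
    message("count_by_lateral_bin: excluded ", sum(drop),
            " cell(s) without lateral_mm")
    cells <- cells[!drop]; labs <- labs[!drop]; lat <- lat[!drop]
  }
  if (!length(cells)) {
    return(data.frame(group = character(), unit_type = character(),
                      unit_name = character(), bin_start = numeric(),
                      cluster = integer(), mean_count = numeric(),
                      n_images = integer()))
  }
  img <- vapply(cells, `[[`, "", "image_id")
  grp <- vapply(cells, function(cl) cl$group %||% NA_character_, "")
  bin <- floor((lat - bin_start) / bin_width)
  b0 <- bin_start + bin * bin_width
  unit <- sprintf("[%.2f,%.2f)", b0, b0 + bin_width)
  clusters <- sort(unique(labs))
  # per-image counts, then mean across the images of each (group, bin)
  imgs <- unique(data.frame(image_id = img, group = grp, bin_start = b0,
                            unit_name = unit, stringsAsFactors = FALSE))
  out <- list()
  for (gb in split(imgs, list(imgs$group, imgs$unit_name), drop = TRUE)) {
    for (k in clusters) {
      counts <- vapply(gb$image_id, function(im)
        sum(img == im & labs == k), 0L)
      out[[length(out) + 1L]] <- data.frame(
        group = gb$group[1], unit_type = "lateral_bin",
        unit_name = gb$unit_name[1], bin_start = gb$bin_start[1],
        cluster = k, mean_count = mean(counts), n_images = nrow(gb),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out[order(out$group, out$bin_start, out$cluster), , drop = FALSE]
}
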