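#' Morphometry configuration
#'
#' Parameters of the feature-extraction stage with their defaults:
#' soma-opening disk radius 6 px, Sholl step 10 px, unit diagonal weights
#' for branch length. All sized for 40x photomicrographs.
#'
#' @param opening_radius Disk radius for soma detection, px.
#' @param sholl_step Sholl circle increment, px.
#' @param diagonal_weight Use `sqrt(2)` diagonal steps in branch length.
#' @return List of class `morpho_config`.
#' @export
morpho_config <- function(opening_radius = 6, sholl_step = 10,
                          diagonal_weight = FALSE) {
  structure(list(opening_radius = opening_radius, sholl_step = sholl_step,
                 diagonal_weight = diagonal_weight), class = "morpho_config")
}

#' Names of the 32 morphometric features
#'
#' Family prefixes: `Sk_` skeleton (4), `So_` soma (8), `C_` whole cell
#' (8), `F_` fractal/convex hull (9), `Sh_` Sholl (3).
#'
#' @return Character vector of length 32.
#' @export
feature_names <- function() {
  shape8 <- c("area", "perimeter", "circularity", "feret_diameter",
              "compactness", "aspect_ratio", "orientation", "eccentricity")
  c(paste0("Sk_", c("branch_length", "initial_points", "junctions", "endpoints")),
    paste0("So_", shape8),
    paste0("C_", shape8),
    paste0("F_", shape8), "F_fractal_dimension",
    paste0("Sh_", c("circles", "crossings", "max_distance")))
}

#' Extract the 32-feature morphometric vector of one cell
#'
#' Runs the five analysis families on a segmented cell: skeleton topology
#' (branch length, initial points, junctions, endpoints), shape metrics of
#' the detected soma, of the whole cell, and of its convex hull, the
#' box-counting fractal dimension, and Sholl circle/crossing counts around
#' the soma centroid. The Sholl maximum distance uses the cell's position
#' in the source image when the record carries one.
#'
#' @param cell A `glia_cell` record (see [segment_cells()]) or binary
#'   matrix.
#' @param config A [morpho_config()].
#' @return Named numeric vector of length 32, all finite.
#' @export
extract_features <- function(cell, config = morpho_config()) {
  if (is.matrix(cell)) {
    cell <- structure(list(cell_id = "cell", mask = as_binary_matrix(cell),
                           bbox = c(row0 = 0L, col0 = 0L,
                                    row1 = nrow(cell), col1 = ncol(cell)),
                           centroid = mask_centroid(cell),
                           image_shape = dim(cell)),
                      class = "glia_cell")
  }
  m <- cell$mask
  if (!any(m == 1L)) data_error("extract_features: empty cell mask")
  soma <- detect_soma(m, opening_radius = config$opening_radius)
  skel <- skeletonize_cell(m)
  sk <- skeleton_metrics(skel, soma, diagonal_weight = config$diagonal_weight)
  so <- shape_metrics(soma)
  ce <- shape_metrics(m)
  hull <- convex_hull_mask(m)
  fr <- shape_metrics(hull)
  # fractal dimension on the bbox crop so the box grid is anchored to the
  # cell, making the feature translation-invariant
  bb <- mask_bbox(m)
  fd <- fractal_dimension(m[(bb[["row0"]] + 1L):bb[["row1"]],
                            (bb[["col0"]] + 1L):bb[["col1"]], drop = FALSE])
  soma_ctr <- mask_centroid(soma)
  img_shape <- cell$image_shape %||% dim(m)
  ctr_img <- c(soma_ctr[1] + cell$bbox[["row0"]], soma_ctr[2] + cell$bbox[["col0"]])
  sh <- sholl_metrics(skel, soma_ctr, image_shape = img_shape,
                      centroid_in_image = ctr_img, step = config$sholl_step)
  v <- c(sk, so, ce, fr, fd, sh)
  names(v) <- feature_names()
  if (!all(is.finite(v))) {
    bad <- names(v)[!is.finite(v)]
    data_error("non-finite features for cell ", cell$cell_id %||% "?", ": ",
               paste(bad, collapse = ", "))
  }
  v
}

#' Build the cells x features table
#'
#' Applies [extract_features()] to every cell; cells whose extraction
#' fails are excluded with a warning naming the cell and the reason.
#'
#' @param cells List of `glia_cell` records.
#' @param config A [morpho_config()].
#' @return data.frame with metadata columns `cell_id`, `image_id`,
#'   `group`, `lateral_mm`, `centroid_row`, `centroid_col` followed by the
#'   32 feature columns.
#' @export
extract_feature_table <- function(cells, config = morpho_config()) {
  rows <- vector("list", length(cells))
  failed <- character(0)
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    fv <- tryCatch(extract_features(cl, config), error = function(e) e)
    if (inherits(fv, "error")) {
      failed <- c(failed, sprintf("%s (%s)", cl$cell_id, conditionMessage(fv)))
      next
    }
    meta <- data.frame(cell_id = cl$cell_id,
                       image_id = cl$image_id %||% NA_character_,
                       group = cl$group %||% NA_character_,
                       lateral_mm = cl$lateral_mm %||% NA_real_,
                       centroid_row = cl$centroid[["row"]],
                       centroid_col = cl$centroid[["col"]],
                       stringsAsFactors = FALSE)
    rows[[i]] <- cbind(meta, as.data.frame(as.list(fv)))
  }
  if (length(failed)) {
    warning("excluded ", length(failed), " cell(s): ",
            paste(failed, collapse = "; "))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

metadata_columns <- function() {
  c("cell_id", "image_id", "group", "lateral_mm", "centroid_row",
    "centroid_col", "archetype", "cluster", "umap1", "umap2")
}

# feature columns of a table: known 32 names if present, otherwise all
# numeric non-metadata columns
feature_columns <- function(table) {
  known <- intersect(feature_names(), names(table))
  if (length(known)) return(known)
  setdiff(names(table)[vapply(table, is.numeric, TRUE)], metadata_columns())
}
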