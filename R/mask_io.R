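#' Load a binary mask image
#'
#' Reads a single-channel TIFF or PNG produced by upstream thresholding of
#' an Iba-1 photomicrograph and binarizes it. Pixel intensities are
#' interpreted on the 8-bit scale (0--255); values strictly above
#' `binarize_threshold` become foreground.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param binarize_threshold Intensity cut-off on the 0--255 scale
#'   (default 127, i.e. foreground = values > 127).
#' @param image_id Identifier for the image; defaults to the file name
#'   without extension.
#' @param group Optional study-group label (e.g. `"SS-CA1"`).
#' @param lateral_mm Optional lateral coordinate of the slice in mm.
#' @return A `glia_mask` object: list with `pixels` (integer matrix of
#'   0/1, indexed `[row, col]`), `image_id`, `group`, `lateral_mm`.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(c(0, 1, 1, 0), 2, 2), f)
#' m <- load_mask(f)
#' sum(m$pixels)
#' @export
load_mask <- function(path, binarize_threshold = 127, image_id = NULL,
                      group = NA_character_, lateral_mm = NA_real_) {
  if (!file.exists(path)) data_error("cannot read mask file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tryCatch(tiff::readTIFF(path), error = function(e)
      data_error("failed to decode TIFF ", path, ": ", conditionMessage(e))),
    png = tryCatch(png::readPNG(path), error = function(e)
      data_error("failed to decode PNG ", path, ": ", conditionMessage(e))),
    data_error("unsupported mask format '", ext, "' (expected tiff or png)")
  )
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] == 1L) {
      raw <- raw[, , 1]
    } else {
      data_error("expected a single-channel mask, got ", dim(raw)[3],
                 " channels: ", path)
    }
  }
  if (nrow(raw) < 1L || ncol(raw) < 1L) data_error("empty raster: ", path)
  pixels <- matrix(as.integer(raw * 255 > binarize_threshold),
                   nrow(raw), ncol(raw))
  new_glia_mask(pixels,
                image_id = image_id %||% tools::file_path_sans_ext(basename(path)),
                group = group, lateral_mm = lateral_mm)
}

new_glia_mask <- function(pixels, image_id, group = NA_character_,
                          lateral_mm = NA_real_) {
  structure(list(pixels = as_binary_matrix(pixels),
                 image_id = as.character(image_id),
                 group = as.character(group),
                 lateral_mm = as.numeric(lateral_mm)),
            class = "glia_mask")
}

#' @export
print.glia_mask <- function(x, ...) {
  cat(sprintf("<glia_mask> %s: %d x %d px, %d foreground, group=%s, lateral=%s mm\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              x$group, format(x$lateral_mm)))
  invisible(x)
}

#' Read per-image metadata sidecar
#'
#' The sidecar CSV carries acquisition metadata that cannot be derived from
#' the mask itself: the study group and the lateral (sagittal) coordinate
#' of the slice. Header must be `image_id,group,lateral_mm`.
#'
#' @param path CSV file path.
#' @return data.frame with columns `image_id`, `group`, `lateral_mm`.
#' @export
read_image_metadata <- function(path) {
  if (!file.exists(path)) data_error("metadata file not found: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "group", "lateral_mm")
  if (!all(need %in% names(md))) {
    data_error("metadata CSV must have header image_id,group,lateral_mm; got: ",
               paste(names(md), collapse = ","))
  }
  md$lateral_mm <- as.numeric(md$lateral_mm)
  md
}

#' Segment a mask image into single cells
#'
#' Every connected component of the binary image with at least `min_area`
#' foreground pixels becomes one cell record. Components touching the image
#' border are kept by default (`border_policy = "keep"`) since upstream
#' reconstruction traces whole cells; set `"drop"` to exclude them.
#' Cell ids are deterministic: components are ordered by the top-left
#' corner (`row0`, then `col0`) of their bounding box.
#'
#' @param img A `glia_mask` (see [load_mask()]) or a binary matrix.
#' @param min_area Minimum component area in pixels (default 60, tuned to
#'   reject debris at 40x magnification).
#' @param connectivity Pixel adjacency, 4 or 8 (default 8 so that thin
#'   diagonal processes do not fragment a cell).
#' @param border_policy `"keep"` or `"drop"` components touching the border.
#' @return List of `glia_cell` records, each with `cell_id`, `mask` (crop),
#'   `bbox` (0-based half-open `row0,col0,row1,col1`), `centroid`
#'   (0-based `row,col` in image coordinates), `area`, `image_id`, `group`,
#'   `lateral_mm` and `image_shape`.
#' @export
segment_cells <- function(img, min_area = 60, connectivity = 8,
                          border_policy = c("keep", "drop")) {
  border_policy <- match.arg(border_policy)
  if (is.matrix(img)) img <- new_glia_mask(img, image_id = "image")
  stopifnot(inherits(img, "glia_mask"))
  m <- img$pixels
  lab <- label_components(m, connectivity)
  n <- max(lab)
  if (n == 0L) return(list())
  h <- nrow(m); w <- ncol(m)
  recs <- list()
  for (k in seq_len(n)) {
    sel <- lab == k
    area <- sum(sel)
    if (area < min_area) next
    bb <- mask_bbox(sel)
    touches <- bb["row0"] == 0L || bb["col0"] == 0L || bb["row1"] == h || bb["col1"] == w
    if (border_policy == "drop" && touches) next
    crop <- matrix(0L, bb["row1"] - bb["row0"], bb["col1"] - bb["col0"])
    sub <- sel[(bb["row0"] + 1L):bb["row1"], (bb["col0"] + 1L):bb["col1"], drop = FALSE]
    crop[sub] <- 1L
    recs[[length(recs) + 1L]] <- structure(list(
      cell_id = NA_character_,
      mask = crop,
      bbox = bb,
      centroid = mask_centroid(sel),
      area = area,
      image_id = img$image_id,
      group = img$group,
      lateral_mm = img$lateral_mm,
      image_shape = c(h, w)
    ), class = "glia_cell")
  }
  if (length(recs) == 0L) return(list())
  ord <- order(vapply(recs, function(r) r$bbox[["row0"]], 0),
               vapply(recs, function(r) r$bbox[["col0"]], 0))
  recs <- recs[ord]
  for (i in seq_along(recs)) {
    recs[[i]]$cell_id <- sprintf("%s_c%03d", img$image_id, i)
  }
  recs
}

#' @export
print.glia_cell <- function(x, ...) {
  cat(sprintf("<glia_cell> %s: %d px, bbox [%d,%d)x[%d,%d), centroid (%.1f, %.1f)\n",
              x$cell_id, x$area, x$bbox[["row0"]], x$bbox[["row1"]],
              x$bbox[["col0"]], x$bbox[["col1"]],
              x$centroid[["row"]], x$centroid[["col"]]))
  invisible(x)
}

#' Write a quality-control gallery of single-cell crops
#'
#' One lossless PNG per cell plus a `manifest.csv` mapping `cell_id` to
#' file and bounding box, mirroring the per-image QC directories of the
#' morphometry stage. Reloading a crop reproduces the mask bitwise.
#'
#' @param cells List of `glia_cell` records.
#' @param out_dir Output directory (created if missing).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cell_gallery <- function(cells, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) data_error("cannot create gallery directory: ", out_dir)
  rows <- lapply(cells, function(cl) {
    f <- file.path(out_dir, paste0(cl$cell_id, ".png"))
    png::writePNG(cl$mask + 0.0, f)
    data.frame(cell_id = cl$cell_id, file = basename(f),
               row0 = cl$bbox[["row0"]], col0 = cl$bbox[["col0"]],
               row1 = cl$bbox[["row1"]], col1 = cl$bbox[["col1"]],
               area = cl$area, stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(), file = character(), row0 = integer(),
               col0 = integer(), row1 = integer(), col1 = integer(),
               area = integer())
  mf <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}
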