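test_that("load_mask binarizes at the requested 8-bit threshold", {
  f <- tempfile(fileext = ".png")
  vals <- matrix(c(0, 128, 255, 0, 255, 128, 0, 0, 255) / 255, 3, 3)
  png::writePNG(vals, f)
  m <- load_mask(f, binarize_threshold = 127)
  expect_s3_class(m, "glia_mask")
  expect_setequal(unique(as.vector(m$pixels)), c(0L, 1L))
  expect_equal(sum(m$pixels), sum(vals * 255 > 127))

  # all-zero image: zero foreground, no error
  f0 <- tempfile(fileext = ".png")
  png::writePNG(matrix(0, 64, 64), f0)
  expect_equal(sum(load_mask(f0)$pixels), 0)

  # {0,255} image: foreground equals the 255 count
  f1 <- tempfile(fileext = ".tiff")
  v <- matrix(sample(c(0, 1), 100, replace = TRUE), 10, 10)
  tiff::writeTIFF(v, f1)
  expect_equal(sum(load_mask(f1)$pixels), sum(v))
})

test_that("load_mask rejects missing files and multi-channel images", {
  expect_error(load_mask(tempfile(fileext = ".png")), "cannot read")
  f <- tempfile(fileext = ".png")
  png::writePNG(array(runif(3 * 4 * 3), c(3, 4, 3)), f)
  expect_error(load_mask(f), "3 channels")
})

test_that("segmentation separates components by area, connectivity and border", {
  m <- matrix(0L, 40, 60)
  m[5:14, 5:14] <- 1L    # 100 px blob
  m[25:34, 40:49] <- 1L  # second 100 px blob
  expect_length(segment_cells(m, min_area = 50), 2)
  expect_length(segment_cells(m, min_area = 150), 0)

  # diagonal pair: one component at 8-connectivity, two at 4
  d <- matrix(0L, 10, 10)
  d[4, 4] <- 1L; d[5, 5] <- 1L
  expect_length(segment_cells(d, min_area = 1, connectivity = 8), 1)
  expect_length(segment_cells(d, min_area = 1, connectivity = 4), 2)

  # border policy
  b <- matrix(0L, 20, 20)
  b[1:5, 1:5] <- 1L    # touches border
  b[10:14, 10:14] <- 1L
  expect_length(segment_cells(b, min_area = 1, border_policy = "keep"), 2)
  kept <- segment_cells(b, min_area = 1, border_policy = "drop")
  expect_length(kept, 1)
  expect_equal(kept[[1]]$bbox[["row0"]], 9)
})

test_that("per-cell areas conserve the image foreground at min_area 1", {
  set.seed(42)
  m <- matrix(as.integer(runif(2500) < 0.3), 50, 50)
  cells <- segment_cells(m, min_area = 1, border_policy = "keep")
  expect_equal(sum(vapply(cells, `[[`, 0L, "area")), sum(m))
  # deterministic ids across repeated runs
  cells2 <- segment_cells(m, min_area = 1, border_policy = "keep")
  expect_identical(vapply(cells, `[[`, "", "cell_id"),
                   vapply(cells2, `[[`, "", "cell_id"))
  # centroid inside bbox, bbox within image
  for (cl in cells) {
    expect_true(cl$centroid[["row"]] >= cl$bbox[["row0"]] - 0.5)
    expect_true(cl$centroid[["row"]] <= cl$bbox[["row1"]] - 0.5)
    expect_true(cl$bbox[["row1"]] <= 50 && cl$bbox[["col1"]] <= 50)
    expect_gte(sum(cl$mask), 1)
  }
})

test_that("cell gallery round-trips masks exactly", {
  sc <- make_scene(scene_spec(canvas = c(400, 400),
                              n_cells = c(amoeboid = 3), seed = 4))
  cells <- segment_cells(sc$image)
  expect_length(cells, 3)
  dir <- file.path(tempdir(), "gallery_test")
  mf <- write_cell_gallery(cells, dir)
  manifest <- read.csv(mf)
  expect_equal(nrow(manifest), 3)
  for (i in seq_len(3)) {
    crop <- png::readPNG(file.path(dir, manifest$file[i]))
    expect_binary_equal(crop, cells[[i]]$mask)
  }
  # empty gallery: manifest with 0 rows, no crash
  mf0 <- write_cell_gallery(list(), file.path(tempdir(), "gallery_empty"))
  expect_equal(nrow(read.csv(mf0)), 0)
})
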