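two_cell_fixture <- function() {
  m <- matrix(0L, 60, 80)
  m[10:19, 10:19] <- 1L
  m[35:44, 50:59] <- 1L
  img <- gliaclust:::new_glia_mask(m, image_id = "img1", group = "A")
  cells <- segment_cells(img, min_area = 1)
  list(img = img, cells = cells)
}

test_that("painting colours each cell by cluster and covers exactly the masks", {
  fx <- two_cell_fixture()
  labs <- setNames(c(0L, 1L), vapply(fx$cells, `[[`, "", "cell_id"))
  canvas <- paint_clusters(fx$img, fx$cells, labs)
  flat <- matrix(grDevices::rgb(canvas[, , 1], canvas[, , 2], canvas[, , 3]),
                 nrow(canvas))
  cols <- setdiff(unique(as.vector(flat)), "#000000")
  expect_length(cols, 2)
  # painted pixel set equals the union of cell masks
  expect_equal(sum(flat != "#000000"), sum(fx$img$pixels))
  # palette is bijective: labels can be recovered from colours
  pal <- attr(canvas, "palette")
  for (i in 1:2) {
    cl <- fx$cells[[i]]
    px <- flat[cl$bbox[["row0"]] + 1, cl$centroid[["col"]] + 1]
    expect_equal(toupper(px), toupper(pal[labs[i] + 1]))
  }
})

test_that("noise cells get the reserved gray and missing labels error", {
  fx <- two_cell_fixture()
  canvas <- paint_clusters(fx$img, fx$cells, c(-1L, -1L))
  flat <- matrix(grDevices::rgb(canvas[, , 1], canvas[, , 2], canvas[, , 3]),
                 nrow(canvas))
  expect_setequal(setdiff(unique(as.vector(flat)), "#000000"), "#808080")
  labs <- setNames(0L, fx$cells[[1]]$cell_id)
  expect_error(paint_clusters(fx$img, fx$cells, labs),
               fx$cells[[2]]$cell_id)
})

test_that("layer counting assigns by centroid with inclusive boundaries", {
  fx <- two_cell_fixture()
  # square layer containing the first cell's centroid (14.5, 14.5)
  ann <- list(L1 = cbind(row = c(0, 0, 30, 30), col = c(0, 30, 30, 0)))
  counts <- count_by_layer(fx$cells, c(0L, 0L), ann)
  l1 <- counts[counts$unit_name == "L1", ]
  expect_equal(l1$count[l1$cluster == 0], 1)
  un <- counts[counts$unit_name == "unassigned", ]
  expect_equal(un$count[un$cluster == 0], 1)
  # conservation: assigned + unassigned = non-noise cells
  expect_equal(sum(counts$count), 2)

  # three cells, clusters {0,0,1}: frequencies 2/3 and 1/3
  cells3 <- c(fx$cells[1], fx$cells[1], fx$cells[1])
  cnt3 <- count_by_layer(cells3, c(0L, 0L, 1L), ann)
  l13 <- cnt3[cnt3$unit_name == "L1", ]
  expect_equal(l13$count[order(l13$cluster)], c(2, 1))
  expect_equal(l13$rel_freq[order(l13$cluster)], c(2 / 3, 1 / 3))

  # centroid (13.5, 13.5) exactly on the polygon vertex/edge counts inside
  edge_ann <- list(L = cbind(row = c(13.5, 13.5, 25, 25),
                             col = c(13.5, 25, 25, 13.5)))
  ce <- count_by_layer(fx$cells[1], 0L, edge_ann)
  expect_equal(ce$count[ce$unit_name == "L"], 1)

  # empty layer: zero count, missing frequency
  far_ann <- list(Far = cbind(row = c(50, 50, 59, 59), col = c(0, 9, 9, 0)))
  cf <- count_by_layer(fx$cells[1], 0L, far_ann)
  expect_equal(cf$count[cf$unit_name == "Far"], 0)
  expect_true(is.na(cf$rel_freq[cf$unit_name == "Far"]))
})

test_that("layer assignment is invariant to polygon vertex orientation", {
  fx <- two_cell_fixture()
  cw <- list(L = cbind(row = c(0, 0, 30, 30), col = c(0, 30, 30, 0)))
  ccw <- list(L = cbind(row = rev(c(0, 0, 30, 30)), col = rev(c(0, 30, 30, 0))))
  a <- count_by_layer(fx$cells, c(0L, 1L), cw)
  b <- count_by_layer(fx$cells, c(0L, 1L), ccw)
  expect_equal(a$count, b$count)
})

test_that("noise is excluded from layer counts", {
  fx <- two_cell_fixture()
  ann <- list(L1 = cbind(row = c(0, 0, 60, 60), col = c(0, 80, 80, 0)))
  counts <- count_by_layer(fx$cells, c(0L, -1L), ann)
  expect_equal(sum(counts$count), 1)
})

test_that("lateral bins are half-open with the documented default edges", {
  mk <- function(id, lat, grp = "A") {
    m <- matrix(0L, 40, 40); m[15:24, 15:24] <- 1L
    segment_cells(gliaclust:::new_glia_mask(m, image_id = id, group = grp,
                                            lateral_mm = lat), min_area = 1)
  }
  # 0.72 must land in the second bin [0.72, 0.96)
  cells <- c(mk("i1", 0.5), mk("i2", 0.72))
  out <- count_by_lateral_bin(cells, c(0L, 0L))
  expect_setequal(out$unit_name, c("[0.48,0.72)", "[0.72,0.96)"))

  # two images in one bin with cluster-0 counts 4 and 6 -> mean 5
  c4 <- do.call(c, lapply(1:4, function(i) mk("a", 0.5)))
  c6 <- do.call(c, lapply(1:6, function(i) mk("b", 0.6)))
  out2 <- count_by_lateral_bin(c(c4, c6), rep(0L, 10))
  expect_equal(out2$mean_count, 5)
  expect_equal(out2$n_images, 2)

  # cells without lateral coordinate are excluded with a message
  expect_message(out3 <- count_by_lateral_bin(c(mk("i1", 0.5), mk("i3", NA)),
                                              c(0L, 0L)),
                 "excluded 1")
  expect_equal(sum(out3$mean_count), 1)
})
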