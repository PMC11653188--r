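test_that("every cell yields exactly the 32 named features, all finite", {
  set.seed(2)
  for (arch in archetype_presets()) {
    cell <- make_cell(arch, seed = 21)
    fv <- extract_features(cell$mask)
    expect_length(fv, 32)
    expect_identical(names(fv), feature_names())
    expect_true(all(is.finite(fv)))
  }
})

test_that("features are invariant under translation on a matched canvas", {
  cell <- make_cell(archetype_presets()$reactive, seed = 5)
  m <- cell$mask
  bb <- gliaclust:::mask_bbox(m)
  crop <- m[(bb[["row0"]] + 1):bb[["row1"]], (bb[["col0"]] + 1):bb[["col1"]]]
  ch <- nrow(crop); cw <- ncol(crop)
  canvas_a <- matrix(0L, ch + 40, cw + 40)
  canvas_a[10 + (1:ch), 10 + (1:cw)] <- crop
  canvas_b <- matrix(0L, ch + 40, cw + 40)
  canvas_b[17 + (1:ch), 23 + (1:cw)] <- crop
  fa <- extract_features(canvas_a)
  fb <- extract_features(canvas_b)
  # all features except the centroid-to-corner distance must match
  keep <- setdiff(feature_names(), "Sh_max_distance")
  expect_equal(fa[keep], fb[keep], tolerance = 1e-10)
})

test_that("hull metrics dominate cell metrics", {
  set.seed(7)
  for (s in 1:5) {
    fv <- extract_features(make_cell(archetype_presets()$ramified, seed = s)$mask)
    expect_gte(fv[["F_area"]], fv[["C_area"]])
    expect_lte(fv[["C_area"]] / fv[["F_area"]], 1)
  }
})

test_that("a disk-only cell is jointly sane across families", {
  fv <- extract_features(disk_raster(50, pad = 8))
  expect_lte(fv[["Sk_endpoints"]], 2)
  expect_gte(fv[["C_circularity"]], 0.95)
  # finite-size box-counting of a filled disk approaches the plane-filling
  # limit from below
  expect_gte(fv[["F_fractal_dimension"]], 1.7)
  expect_equal(fv[["So_area"]], fv[["C_area"]], tolerance = 0.05)
})

test_that("adding a process never decreases the endpoint count", {
  side <- 160
  base <- matrix(0L, side, side)
  ctr <- 80
  d2 <- outer((1:side - ctr)^2, (1:side - ctr)^2, `+`)
  base[d2 <= 64] <- 1L
  angles <- seq(0, 2 * pi, length.out = 7)[-7]
  prev_endpoints <- -1
  for (k in 1:6) {
    m <- base
    for (a in angles[1:k]) {
      for (t in 8:55) {
        m[round(ctr + t * sin(a)), round(ctr + t * cos(a))] <- 1L
      }
    }
    fv <- extract_features(m)
    expect_gte(fv[["Sk_endpoints"]], prev_endpoints)
    prev_endpoints <- fv[["Sk_endpoints"]]
  }
  expect_gte(prev_endpoints, 6)
})

test_that("the feature table carries metadata and skips failing cells", {
  built <- build_test_cells(1)
  ft <- extract_feature_table(built$cells)
  expect_equal(nrow(ft), length(built$cells))
  expect_true(all(c("cell_id", "image_id", "group", "lateral_mm") %in% names(ft)))
  expect_identical(gliaclust:::feature_columns(ft), feature_names())
  expect_false(anyNA(ft[, feature_names()]))
})
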