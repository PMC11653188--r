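# count connected components through the public segmentation API
label_components_test <- function(m) {
  length(segment_cells(m, min_area = 1, border_policy = "keep"))
}

test_that("thinning collapses bars and disks to their medial curves", {
  bar <- matrix(0L, 9, 60)
  bar[4:6, 6:55] <- 1L
  sk <- skeletonize_cell(bar)
  expect_true(all(sk[bar == 0L] == 0L))            # skeleton within mask
  expect_equal(max(label_components_test(sk)), 1)  # same topology
  expect_gte(sum(sk), 44)                          # ~50-px line
  expect_lte(sum(sk), 52)
  m <- skeleton_metrics(sk)
  expect_equal(m[["n_endpoints"]], 2)
  expect_equal(m[["n_junctions"]], 0)

  disk <- disk_raster(15, pad = 4)
  expect_lte(sum(skeletonize_cell(disk)), 6)       # disk collapses centrally
})

test_that("plus-sign skeleton keeps four arms meeting at one junction", {
  pl <- plus_raster()
  sk <- skeletonize_cell(pl)
  m <- skeleton_metrics(sk)
  expect_equal(m[["n_endpoints"]], 4)
  expect_equal(m[["n_junctions"]], 1)
  expect_equal(label_components_test(sk), 1)
})

test_that("initial points count processes emerging from the soma", {
  # T-shape skeleton with a soma disk at the junction
  h <- 41; w <- 41
  sk <- matrix(0L, h, w)
  sk[21, 1:41] <- 1L   # horizontal bar
  sk[21:41, 21] <- 1L  # stem down
  soma <- matrix(0L, h, w)
  d2 <- outer((1:h - 21)^2, (1:w - 21)^2, `+`)
  soma[d2 <= 25] <- 1L
  m <- skeleton_metrics(sk, soma)
  expect_equal(m[["n_initial_points"]], 3)
  expect_equal(m[["branch_length"]], sum(sk == 1L & soma == 0L))
  # empty skeleton: all zeros
  expect_equal(unname(skeleton_metrics(matrix(0L, 5, 5))), rep(0, 4))
})

test_that("skeleton metrics match the per-pixel neighbour-count oracle", {
  set.seed(101)
  for (i in 1:100) {
    m <- matrix(as.integer(runif(32 * 32) < runif(1, 0.05, 0.5)), 32, 32)
    soma <- if (i %% 3 == 0) {
      matrix(as.integer(runif(32 * 32) < 0.15), 32, 32)
    } else NULL
    got <- skeleton_metrics(m, soma)
    want <- oracle_skeleton_metrics(m, soma)
    expect_equal(unname(got), unname(want), info = paste("case", i))
  }
})

test_that("soma detection keeps the cell body and strips thin processes", {
  # plain disk: opening preserves nearly all of it
  disk <- disk_raster(20, pad = 8)
  soma <- detect_soma(disk, opening_radius = 5)
  expect_gte(sum(soma) / sum(disk), 0.95)

  # disk with four 1-px processes of length 40: processes excluded
  side <- 120
  m <- matrix(0L, side, side)
  ctr <- 60
  d2 <- outer((1:side - ctr)^2, (1:side - ctr)^2, `+`)
  m[d2 <= 100] <- 1L           # r = 10 soma
  m[ctr, (ctr + 10):(ctr + 50)] <- 1L
  m[ctr, (ctr - 50):(ctr - 10)] <- 1L
  m[(ctr + 10):(ctr + 50), ctr] <- 1L
  m[(ctr - 50):(ctr - 10), ctr] <- 1L
  soma <- detect_soma(m, opening_radius = 4)
  outside_disk <- m == 1L & d2 > (10 + 2)^2
  expect_equal(sum(soma[outside_disk]), 0)
  expect_gt(sum(soma), 0)

  # mask thinner than the element everywhere: fallback non-empty
  thin <- matrix(0L, 30, 30); thin[15, 5:25] <- 1L
  expect_gt(sum(detect_soma(thin, opening_radius = 6)), 0)
})
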