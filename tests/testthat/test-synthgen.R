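test_that("cell generation is seed-deterministic and respects the spec", {
  pres <- archetype_presets()
  a <- make_cell(pres$ramified, seed = 13)
  b <- make_cell(pres$ramified, seed = 13)
  expect_identical(a$mask, b$mask)
  expect_identical(a$n_processes, b$n_processes)
  expect_gt(sum(a$mask), 0)
  expect_true(all(a$mask[a$soma == 1L] == 1L))  # soma inside the cell

  # amoeboid spec with zero processes is almost a disk
  blob <- archetype("blob", c(15, 1), c(0, 0), c(0, 0))
  fv <- extract_features(make_cell(blob, seed = 1)$mask)
  expect_gte(fv[["C_circularity"]], 0.85)

  # infeasible canvas errors
  expect_error(make_cell(pres$amoeboid, seed = 1, canvas = 10), "too small")
})

test_that("ramified cells keep at least their primary processes as endpoints", {
  spec <- archetype("ram", soma_radius = c(8, 0.5), n_processes = c(6, 0.5),
                    process_length = c(80, 5), branch_prob = 0.3,
                    tortuosity = 0.25, process_width = 1)
  ok <- 0L
  for (s in 1:40) {
    fv <- extract_features(make_cell(spec, seed = s)$mask)
    ok <- ok + (fv[["Sk_endpoints"]] >= 6)
  }
  expect_gte(ok, ceiling(0.9 * 40))
})

test_that("archetype ordering shows in circularity and endpoints", {
  pres <- archetype_presets()
  n <- 50
  feats <- function(arch, off) t(vapply(seq_len(n), function(s)
    extract_features(make_cell(arch, seed = off + s)$mask)[
      c("C_circularity", "Sk_endpoints")], numeric(2)))
  am <- feats(pres$amoeboid, 100)
  ra <- feats(pres$ramified, 200)
  expect_gt(mean(am[, 1]), mean(ra[, 1]))  # amoeboid rounder
  expect_gt(mean(ra[, 2]), mean(am[, 2]))  # ramified more endpoints
})

test_that("scenes place the requested cells apart and segment cleanly", {
  sp <- scene_spec(canvas = c(700, 700),
                   n_cells = c(ramified = 4, amoeboid = 3, reactive = 3),
                   min_separation = 40, seed = 3, group = "A",
                   lateral_mm = 0.9, image_id = "sc1")
  sc <- make_scene(sp)
  expect_equal(nrow(sc$truth), 10)
  cells <- segment_cells(sc$image, min_area = 60)
  expect_length(cells, 10)
  ctr <- as.matrix(sc$truth[, c("centroid_row", "centroid_col")])
  expect_gte(min(dist(ctr)), 40)
  # metadata propagates
  expect_equal(cells[[1]]$group, "A")
  expect_equal(cells[[1]]$lateral_mm, 0.9)
  # determinism
  sc2 <- make_scene(sp)
  expect_identical(sc$image$pixels, sc2$image$pixels)
  # archetype matching is consistent with requested mixture
  arch <- match_truth(cells, sc$truth)
  expect_equal(sort(as.integer(table(arch))), c(3, 3, 4))
  # an impossible packing errors
  expect_error(make_scene(scene_spec(canvas = c(150, 150),
                                     n_cells = c(ramified = 30), seed = 1)),
               "canvas")
})
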