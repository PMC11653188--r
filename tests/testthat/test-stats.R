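test_that("contingency cross-tabulates classified cells only", {
  tab <- contingency(c(0L, 0L, 1L, 1L), c("A", "A", "B", "B"))
  expect_equal(unname(tab), matrix(c(2L, 0L, 0L, 2L), 2))
  # noise excluded: same table
  tab2 <- contingency(c(0L, 0L, 1L, 1L, -1L), c("A", "A", "B", "B", "A"))
  expect_identical(tab, tab2)
  expect_error(contingency(integer(0), character(0)))
  expect_error(contingency(c(0L, 0L), c("A", "A")), ">= 2")
})

test_that("chi-square matches hand computations and reports residual flavours", {
  # proportional table: statistic 0, all residuals 0
  prop <- matrix(c(10, 20, 20, 40), 2)
  r0 <- chi_square(prop)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_true(all(abs(r0$std_residuals) < 1e-9))

  # [[10,20],[20,10]]: E = 15 everywhere, X2 = 4*(25/15)
  r1 <- chi_square(matrix(c(10, 20, 20, 10), 2))
  expect_equal(r1$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(r1$df, 1)
  expect_true(all(r1$expected == 15))
  # O > E gives a positive residual
  expect_gt(r1$std_residuals[2, 1], 0)
  expect_lt(r1$std_residuals[1, 1], 0)
  # Pearson residual formula
  expect_equal(unname(r1$pearson_residuals), unname((matrix(c(10, 20, 20, 10), 2) - 15) / sqrt(15)))
  # adjusted residuals are larger in magnitude
  expect_true(all(abs(r1$adjusted_residuals) >= abs(r1$pearson_residuals) - 1e-12))

  # expected margins reproduce observed margins
  set.seed(2)
  tb <- matrix(rpois(12, 30) + 1, 3)
  rr <- chi_square(tb)
  expect_equal(rowSums(rr$expected), rowSums(tb))
  expect_equal(colSums(rr$expected), colSums(tb))
  # empty marginal errors with the offender named
  bad <- tb; bad[2, ] <- 0
  expect_error(chi_square(bad), "row")
})

test_that("chi-square statistic equals the brute-force oracle on random tables", {
  set.seed(11)
  for (i in 1:100) {
    r <- sample(2:5, 1); c <- sample(2:5, 1)
    tb <- matrix(rpois(r * c, lambda = 20) + 1, nrow = r)
    expect_equal(chi_square(tb)$statistic, oracle_chisq(tb), tolerance = 1e-9)
  }
})

test_that("type-I error of the chi-square test is calibrated under the null", {
  set.seed(77)
  n_sim <- 2000
  rej <- 0L
  for (i in seq_len(n_sim)) {
    grp <- sample(4, 500, replace = TRUE)
    cl <- sample(5, 500, replace = TRUE)
    tb <- table(cl, grp)
    p <- chi_square(matrix(as.numeric(tb), nrow(tb)))$p_value
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / n_sim, 0.03)
  expect_lte(rej / n_sim, 0.07)
})

test_that("heatmap entries are mean z-scores with the expected structure", {
  set.seed(5)
  n <- 200
  tab <- data.frame(f1 = c(rnorm(n / 2, 0), rnorm(n / 2, 2)),
                    f2 = rnorm(n))
  keys <- rep(c("k1", "k2"), each = n / 2)
  hm <- cluster_heatmap(tab, keys, features = c("f1", "f2"))
  # two equal groups shifted by 2 sigma: entries near +/- 1 in f1
  expect_equal(abs(unname(hm$matrix[, "f1"])), c(1, 1) * 0.71, tolerance = 0.15)
  expect_lt(max(abs(hm$matrix[, "f2"])), 0.3)
  # single-level key: all entries ~0
  hm1 <- cluster_heatmap(tab, rep("all", n), features = c("f1", "f2"))
  expect_true(all(abs(hm1$matrix) < 1e-9))
  # constant feature warns and maps to zero
  tab$f3 <- 1
  expect_warning(hm3 <- cluster_heatmap(tab, keys, features = c("f1", "f3")),
                 "constant")
  expect_true(all(hm3$matrix[, "f3"] == 0))
})

test_that("cluster keys explain more feature variance than random keys", {
  built <- build_test_cells(3, scenes = 4)
  ft <- extract_feature_table(built$cells)
  hm_arch <- cluster_heatmap(ft, built$archetype)
  set.seed(1)
  hm_rand <- cluster_heatmap(ft, sample(built$archetype))
  expect_gt(mean(hm_arch$between_var), mean(hm_rand$between_var))
})

test_that("rank test matches enumeration, symmetry and tie conventions", {
  # frozen example: complete separation of 4 vs 4
  rt <- rank_test(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(rt$U, 0)
  expect_equal(rt$p_value, 2 / 70, tolerance = 1e-12)

  # identical samples: all tied -> p = 1 with warning
  expect_warning(rt1 <- rank_test(c(2, 2, 2), c(2, 2, 2)), "tied")
  expect_equal(rt1$p_value, 1)

  # symmetry: swapping gives same p, U -> n1*n2 - U
  x <- c(3, 9, 1, 7); y <- c(2, 8, 4, 10, 6)
  a <- rank_test(x, y); b <- rank_test(y, x)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$U + b$U, length(x) * length(y))

  # exact p equals full enumeration for all n1, n2 <= 6 (spot grid)
  set.seed(8)
  for (n1 in 3:6) for (n2 in 3:6) {
    x <- sample(100, n1); y <- sample(100, n2) + 0.5
    expect_equal(rank_test(x, y)$p_value, oracle_mwu_p(x, y),
                 tolerance = 1e-9, info = paste(n1, n2))
  }
  expect_error(rank_test(numeric(0), 1), "empty")
})

test_that("layer rank tests compare per-image values between groups", {
  rows <- expand.grid(image = 1:8, unit_name = c("SO", "SR"), cluster = 0L,
                      stringsAsFactors = FALSE)
  rows$group <- ifelse(rows$image <= 4, "SS", "SCOP")
  rows$image_id <- paste0("img", rows$image)
  set.seed(3)
  rows$count <- ifelse(rows$group == "SCOP", rows$image + 10, rows$image)
  rows$rel_freq <- rows$count / 40
  out <- layer_rank_tests(rows, "SS", "SCOP")
  expect_equal(nrow(out), 2)
  expect_true(all(out$p_value < 0.05))  # complete separation, n=4 vs 4
  expect_equal(out$p_adj, out$p_value)  # no correction by default
})
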