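test_that("binarization applies inclusive fixed thresholds", {
  img <- micrograph(matrix(200L, 10, 10), scale = 10)
  expect_false(any(binarize(img)))
  expect_true(all(binarize(micrograph(matrix(75L, 4, 4), 10))))
  expect_false(any(binarize(micrograph(matrix(76L, 4, 4), 10))))
  # non-8-bit input is rejected at construction
  expect_error(micrograph(matrix(300, 2, 2), 10), "8-bit")
  expect_error(micrograph(matrix(0.5, 2, 2), 10), "8-bit")
})

test_that("labeling uses 8-connectivity and the area noise floor", {
  # two disjoint squares with exact areas
  m <- matrix(FALSE, 20, 20)
  m[2:4, 2:4] <- TRUE # 3x3
  m[10:14, 10:14] <- TRUE # 5x5
  rec <- label_pores(m, scale = 10)
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$area_nm2, c(9, 25) * 100)

  # diagonal touch joins under 8-connectivity
  d <- matrix(FALSE, 6, 6)
  d[2, 2] <- TRUE
  d[3, 3] <- TRUE
  expect_equal(nrow(label_pores(d, scale = 1, min_size = 0)), 1)

  # single pixel at 10 nm/px passes the 0.1 nm noise floor
  s <- matrix(FALSE, 5, 5)
  s[3, 3] <- TRUE
  one <- label_pores(s, scale = 10, min_size = 0.1)
  expect_equal(nrow(one), 1)
  expect_equal(one$feret_min_nm, 10) # corner-point convention
  expect_equal(one$feret_max_nm, sqrt(2) * 10)
  # a large min_size removes it
  expect_equal(nrow(label_pores(s, scale = 10, min_size = 11)), 0)

  # border flagging and optional exclusion
  b <- matrix(FALSE, 6, 6)
  b[1, 1:2] <- TRUE
  b[4, 4] <- TRUE
  rec2 <- label_pores(b, scale = 1, min_size = 0)
  expect_equal(sum(rec2$touches_border), 1)
  expect_equal(nrow(label_pores(b, scale = 1, min_size = 0, exclude_border = TRUE)), 1)
})

test_that("labeling is translation invariant and Feret rotation tolerant", {
  set.seed(4)
  m <- matrix(FALSE, 30, 30)
  m[5:9, 6:12] <- TRUE
  m[20:24, 15:16] <- TRUE
  base <- label_pores(m, scale = 1, min_size = 0)
  shifted <- matrix(FALSE, 30, 30)
  shifted[5:9 + 3, 6:12 + 2] <- TRUE
  shifted[20:24 + 3, 15:16 + 2] <- TRUE
  moved <- label_pores(shifted, scale = 1, min_size = 0)
  expect_equal(base$area_nm2, moved$area_nm2)
  expect_equal(base$feret_max_nm, moved$feret_max_nm)
  expect_equal(base$feret_min_nm, moved$feret_min_nm)
  # 90-degree rotation preserves Feret diameters exactly on a raster
  rot <- label_pores(t(m[nrow(m):1, ]), scale = 1, min_size = 0)
  expect_setequal(round(rot$feret_max_nm, 9), round(base$feret_max_nm, 9))
  expect_setequal(round(rot$feret_min_nm, 9), round(base$feret_min_nm, 9))
})

test_that("Feret diameters match geometry on rectangles and random shapes", {
  # axis-aligned a x b pixel rectangle from corner points
  m <- matrix(FALSE, 20, 20)
  m[3:7, 4:12] <- TRUE # 5 x 9 pixels
  rec <- label_pores(m, scale = 2, min_size = 0)
  expect_equal(rec$feret_min_nm, 5 * 2)
  expect_equal(rec$feret_max_nm, sqrt(5^2 + 9^2) * 2)

  # feret_max >= feret_min over random point clouds; oracle agreement
  set.seed(9)
  for (i in 1:10) {
    pts <- random_blob()
    f <- feret_diameters(pts)
    expect_gte(f["feret_max"], f["feret_min"])
    bf <- brute_force_feret(pts)
    expect_lte(f["feret_min"], bf["feret_min"] + 1e-9) # caliper never above grid
    expect_equal(unname(f["feret_max"]), unname(bf["feret_max"]),
      tolerance = 1e-6
    )
  }
})

test_that("pipeline round trip recovers ground-truth Feret diameters", {
  spec <- pore_image_sim_spec(n_pores = 10, seed = 3)
  res <- gen_pore_image(spec)
  scale <- res$image$scale_nm_per_px
  rec <- label_pores(binarize(res$image), scale = scale)
  expect_equal(nrow(rec), 10)
  tr <- res$truth
  for (i in seq_len(nrow(tr))) {
    d <- sqrt((rec$centroid_row - tr$center_row[i])^2 +
      (rec$centroid_col - tr$center_col[i])^2)
    j <- which.min(d)
    expect_lt(abs(rec$feret_min_nm[j] - tr$feret_min_nm[i]), 2 * scale)
    expect_lt(abs(rec$feret_max_nm[j] - tr$feret_max_nm[i]), 2 * scale)
  }
})

test_that("paired Feret comparison and method cross-validation behave", {
  # all circles: degenerate, no signal
  circ <- data.frame(feret_max_nm = rep(5, 8), feret_min_nm = rep(5, 8))
  class(circ) <- c("pore_records", "data.frame")
  res <- compare_feret_max_min(circ)
  expect_equal(res$method, "degenerate")

  # strictly elongated pores: minimal attainable one-sided p = 2^-20
  set.seed(6)
  rec <- data.frame(
    feret_min_nm = runif(20, 5, 10),
    feret_max_nm = runif(20, 5, 10) + runif(20, 1, 3)
  )
  rec$feret_max_nm <- rec$feret_min_nm + runif(20, 0.5, 3)
  class(rec) <- c("pore_records", "data.frame")
  one <- compare_feret_max_min(rec, alternative = "greater")
  expect_equal(one$p_value, 2^-20, tolerance = 1e-12)

  # identical groups agree; separated groups differ
  same <- cross_validate_pore_size(theoretical = c(30, 40, 50), binarization = c(30, 40, 50))
  expect_equal(same$test$statistic, 0)
  expect_equal(same$test$p_value, 1)
  expect_true(same$agree)
  # complete separation: exact enumeration gives the minimal attainable p,
  # 2 extreme arrangements out of choose(10, 5)
  apart <- cross_validate_pore_size(theoretical = 1:5, binarization = 101:105)
  expect_false(apart$agree)
  expect_equal(apart$test$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  # at 3 vs 3 the minimal attainable exact p is 2/20, not significant at 0.05
  tiny <- cross_validate_pore_size(theoretical = c(1, 2, 3), binarization = c(100, 101, 102))
  expect_equal(tiny$test$p_value, 0.1, tolerance = 1e-12)
  # <3 values in a group flagged underpowered
  up <- suppressWarnings(
    cross_validate_pore_size(theoretical = c(1, 2), binarization = c(1, 2, 3))
  )
  expect_equal(up$underpowered, "theoretical")
})
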