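test_that("the coefficient rule fires on a dominant coefficient", {
  dict <- make_dict(cbind(c(1, 0, 0), c(0, 1, 0)))
  x <- dict$atoms[, 1]
  sc <- matching_pursuit(x, dict)
  d <- decide(sc, x, dict)
  expect_equal(d$class_code, 1L)
  expect_equal(d$rule_used, "coefficient")
  expect_null(d$per_class_residuals)
})

test_that("the hand-traced mixture decides class 2 by coefficient", {
  dict <- make_dict(cbind(c(1, 0, 0), c(0, 1, 0)))
  x <- normalize_pixel(c(3, 4, 0))
  sc <- matching_pursuit(x, dict)
  d <- decide(sc, x, dict, threshold = 0.5)
  expect_equal(d$class_code, 2L)
  expect_equal(d$rule_used, "coefficient")
  expect_equal(d$top_coefficient, 4 / 7)
})

test_that("the residual rule picks the class that reconstructs the pixel", {
  # orthonormal 3-class dictionary; force sub-threshold coefficients with a
  # high threshold so the residual path runs
  dict <- make_dict(diag(3) + 0, class_code = 1:3)
  x <- normalize_pixel(c(0.1, 0.99, 0.05))
  sc <- matching_pursuit(x, dict)
  d <- decide(sc, x, dict, threshold = 0.999)
  expect_equal(d$rule_used, "residual")
  expect_equal(d$class_code, 2L)
  expect_equal(unname(which.min(d$per_class_residuals)), 2L)
  expect_error(decide(sc, x, dict, threshold = 1.5), "threshold")
})

test_that("an all-zero code degenerates to a flagged lowest-code tie", {
  dict <- make_dict(cbind(c(1, 0, 0), c(0, 1, 0)), class_code = c(4L, 7L))
  x <- c(0, 0, 1)
  sc <- matching_pursuit(x, dict)
  d <- decide(sc, x, dict)
  expect_true(d$degenerate)
  expect_equal(d$rule_used, "residual")
  expect_equal(d$class_code, 4L)   # lowest class code on a tie
})

test_that("cubes of exact atoms classify perfectly and scale-invariantly", {
  dict <- random_dict(41, bands = 8, m = 3)
  layout <- matrix(c(1L, 2L, 3L, 2L), 2, 2)
  arr <- array(0, c(2, 2, 8))
  for (r in 1:2) for (c in 1:2) arr[r, c, ] <- dict$atoms[, layout[r, c]]
  cube <- hsi_cube(arr)
  map <- classify_cube(cube, dict)
  expect_equal(map$labels, layout)
  # doubling every pixel changes nothing after normalization
  map2 <- classify_cube(hsi_cube(arr * 2), dict)
  expect_identical(map2$labels, map$labels)
  expect_error(classify_cube(hsi_cube(arr[, , 1:5]), dict), "band")
})

test_that("noiseless scenes with the true-endmember dictionary score 100%", {
  sp <- scene_spec(rows = 12, cols = 12, bands = 30, n_classes = 4,
                   snr_db = 120, mix_fraction = 0, seed = 17)
  tr <- render_scene(sp)
  dict <- make_dict(t(tr$endmembers), class_code = 1:4)
  pred <- classify_cube(tr$cube, dict)
  expect_equal(overall_accuracy(confusion(tr$labels, pred)), 100)
})

test_that("relabeling dictionary classes permutes the output map", {
  dict <- random_dict(43, bands = 8, m = 3)
  # pixels are noisy convex combinations of atoms, so no pixel is left
  # without a positively correlated atom (the all-zero tie-break is,
  # by design, not equivariant)
  set.seed(18)
  arr <- array(0, c(8, 9, 8))
  for (r in 1:8) for (c in 1:9) {
    w <- stats::runif(3); w <- w / sum(w)
    arr[r, c, ] <- as.numeric(dict$atoms %*% w) + stats::runif(8, 0, 0.02)
  }
  cube <- hsi_cube(arr)
  map1 <- classify_cube(cube, dict)
  # relabel atoms 1,2,3 -> 3,1,2 without moving them
  dict2 <- dict
  perm <- c(3L, 1L, 2L)
  dict2$class_code <- perm
  ord <- order(dict2$class_code)
  dict2$atoms <- dict2$atoms[, ord]
  dict2$class_code <- dict2$class_code[ord]
  map2 <- classify_cube(cube, dict2)
  expect_identical(map2$labels, matrix(perm[map1$labels],
                                       nrow(map1$labels), ncol(map1$labels)))
})

test_that("the audit log records one decision per pixel", {
  dict <- random_dict(45, bands = 6, m = 3)
  layout <- matrix(c(1L, 2L, 3L, 2L), 2, 2)
  arr <- array(0, c(2, 2, 6))
  for (r in 1:2) for (c in 1:2) arr[r, c, ] <- dict$atoms[, layout[r, c]]
  p <- withr::local_tempfile(fileext = ".tsv")
  map <- classify_cube(hsi_cube(arr), dict, audit = p)
  log <- utils::read.delim(p)
  expect_equal(nrow(log), 4)
  expect_equal(log$class[order(log$row, log$col)], as.vector(t(layout)))
  expect_true(all(log$rule == "coefficient"))
})

test_that("at threshold 0.5 at most one class can fire the coefficient rule", {
  set.seed(19)
  dict <- random_dict(44, bands = 10, m = 5)
  for (i in 1:25) {
    x <- normalize_pixel(stats::runif(10))
    sc <- matching_pursuit(x, dict)
    expect_lte(sum(sc$coefficients > 0.5), 1)
  }
})
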