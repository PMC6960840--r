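test_that("instance kernel matches its closed forms", {
  expect_equal(instance_prob(c(1, 2), c(1, 2)), 1)
  expect_equal(instance_prob(0, 1), exp(-1), tolerance = 1e-12)
  expect_equal(instance_prob(c(0, 0), c(1, 1)), exp(-2), tolerance = 1e-12)
  expect_error(instance_prob(c(0, 0), 1), "length")
})

test_that("positive bags follow the noisy-OR model", {
  t <- c(0.3, -0.2)
  bag <- dd_bag(rbind(t, c(5, 5)), "positive", 1L)
  expect_equal(positive_bag_prob(bag, t), 1)   # member absorbs
  far <- dd_bag(matrix(c(4, 3, -4, 3), 2, byrow = TRUE), "positive", 1L)
  expect_lt(positive_bag_prob(far, t), 1e-9)
  # 1-D bag {0, 2}, t = 0: 1 - (1-1)(1-e^-4) = 1
  b <- dd_bag(matrix(c(0, 2), 2, 1), "positive", 1L)
  expect_equal(positive_bag_prob(b, 0), 1)
  expect_error(positive_bag_prob(dd_bag(1, "negative", 1L), 0),
               "not positive")
})

test_that("negative bags follow the product model", {
  b <- dd_bag(matrix(c(0, 1), 2, 1), "negative", 1L)
  expect_equal(negative_bag_prob(b, 0), 0)     # contains t
  b10 <- dd_bag(matrix(10, 1, 1), "negative", 1L)
  expect_equal(negative_bag_prob(b10, 0), 1 - exp(-100), tolerance = 1e-12)
  b1 <- dd_bag(matrix(1, 1, 1), "negative", 1L)
  expect_equal(negative_bag_prob(b1, 0), 1 - exp(-1), tolerance = 1e-12)
  expect_error(negative_bag_prob(dd_bag(1, "positive", 1L), 0),
               "not negative")
})

test_that("dd_value multiplies bag factors and flags exact zeros", {
  t <- c(0.5, 0.5)
  bag <- dd_bag(t, "positive", 1L)
  v <- dd_value(list(bag), t)
  expect_equal(v$dd, 1)
  expect_equal(v$log_dd, 0)
  # a negative bag containing t forces an exact zero with -Inf sentinel
  v0 <- dd_value(list(bag, dd_bag(t, "negative", 1L)), t)
  expect_equal(v0$dd, 0)
  expect_identical(v0$log_dd, -Inf)
  expect_error(dd_value(list(dd_bag(t, "negative", 1L)), t), "positive")
  # 1-D worked case against the direct product-of-factors oracle
  bags <- list(dd_bag(matrix(c(0, 5), 2, 1), "positive", 1L),
               dd_bag(matrix(0.1, 1, 1), "positive", 1L),
               dd_bag(matrix(3, 1, 1), "negative", 1L))
  got <- dd_value(bags, 0.05)
  expect_equal(got$dd, brute_dd(bags, 0.05), tolerance = 1e-12)
})

test_that("log-domain and linear-domain diverse density agree", {
  for (s in 1:50) {
    bags <- random_bags(s)
    t <- bags[[1]]$instances[1, ] + 0.1
    v <- dd_value(bags, t)
    if (v$dd > 1e-300)
      expect_equal(v$log_dd, log(brute_dd(bags, t)), tolerance = 1e-10)
  }
})

test_that("candidate maximization equals brute-force evaluation", {
  for (s in 1:60) {
    bags <- random_bags(1000 + s)
    got <- maximize_dd(bags, refine = FALSE)
    expect_identical(got$point, as.numeric(brute_maximize_dd(bags)))
  }
})

test_that("adding a negative bag never increases diverse density", {
  set.seed(99)
  for (i in 1:100) {
    bags <- random_bags(2000 + i)
    t <- stats::runif(ncol(bags[[1]]$instances), -1, 1)
    extra <- dd_bag(matrix(stats::runif(ncol(bags[[1]]$instances) * 2, -1, 1),
                           ncol = ncol(bags[[1]]$instances)), "negative", 1L)
    expect_lte(dd_value(c(bags, list(extra)), t)$log_dd,
               dd_value(bags, t)$log_dd)
  }
})

test_that("refined maximization tracks the continuous optimum (1-D grid)", {
  bags <- list(dd_bag(matrix(c(0, 5), 2, 1), "positive", 1L),
               dd_bag(matrix(0.1, 1, 1), "positive", 1L),
               dd_bag(matrix(3, 1, 1), "negative", 1L))
  grid <- seq(-1, 6, by = 1e-3)
  vals <- vapply(grid, function(g) dd_value(bags, g)$log_dd, numeric(1))
  t_grid <- grid[which.max(vals)]
  got <- maximize_dd(bags, refine = TRUE)
  expect_lt(abs(got$point - t_grid), 1e-3)
})

test_that("a known concept is recovered from clustered bags", {
  set.seed(31)
  t_star <- stats::runif(10, 0, 1)
  pos <- lapply(1:20, function(i)
    dd_bag(matrix(stats::rnorm(50, mean = t_star, sd = 0.1), 5, 10,
                  byrow = TRUE), "positive", 1L))
  neg <- lapply(1:20, function(i)
    dd_bag(matrix(stats::rnorm(50, mean = t_star + 3, sd = 0.1), 5, 10,
                  byrow = TRUE), "negative", 1L))
  got <- maximize_dd(c(pos, neg), refine = TRUE)
  expect_lt(sqrt(sum((got$point - t_star)^2)), 0.05)
})

test_that("dictionary learning recovers separated class atoms", {
  # degenerate bags: one sample per class -> atoms are the samples normalized
  tr <- list(`1` = matrix(c(1, 0, 0), 1), `2` = matrix(c(0, 2, 0), 1))
  d <- learn_dictionary(tr)
  expect_equal(d$atoms, cbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(d$class_code, 1:2)
  # two well-separated synthetic classes at 30 dB: cosine >= 0.99 to truth
  sp <- scene_spec(rows = 10, cols = 10, bands = 24, n_classes = 2,
                   snr_db = 30, seed = 13,
                   endmember_spec = list(
                     cbind(center = c(6, 18), width = c(2, 3),
                           amplitude = c(1, 0.4)),
                     cbind(center = c(12, 20), width = c(3, 2),
                           amplitude = c(1, 0.6))))
  truth <- render_scene(sp)
  training <- sample_training(truth, seed = 3, per_class = 10)
  d2 <- learn_dictionary(training)
  En <- truth$endmembers / sqrt(rowSums(truth$endmembers^2))
  expect_gt(sum(En[1, ] * d2$atoms[, 1]), 0.99)
  expect_gt(sum(En[2, ] * d2$atoms[, 2]), 0.99)
  expect_error(learn_dictionary(list(`1` = matrix(1, 1, 1))), "2 classes")
})

test_that("learned atoms are unit norm and ordered by class code", {
  set.seed(14)
  tr <- list(`3` = matrix(rnorm(30, 2), 5), `1` = matrix(rnorm(30, -2), 5),
             `2` = matrix(rnorm(30, 5), 5))
  d <- learn_dictionary(tr)
  expect_equal(d$class_code, 1:3)
  expect_equal(colSums(d$atoms^2), rep(1, 3), tolerance = 1e-10)
})

test_that("multi-atom dictionaries stay class-grouped and distinct", {
  set.seed(16)
  tr <- list(`1` = matrix(rnorm(40, 3), 8), `2` = matrix(rnorm(40, -3), 8))
  d <- learn_dictionary(tr, atoms_per_class = 3L)
  expect_equal(ncol(d$atoms), 6)
  expect_equal(d$class_code, rep(1:2, each = 3))
  # excluded candidates are not re-chosen: atoms within a class differ
  for (k in 1:2) {
    a <- d$atoms[, d$class_code == k]
    expect_gt(min(dist(t(a))), 0)
  }
  expect_error(learn_dictionary(tr, atoms_per_class = 9L), "requested")
})

test_that("dictionaries round-trip through the text format", {
  set.seed(15)
  tr <- list(`1` = matrix(rnorm(20, 2), 4), `2` = matrix(rnorm(20, -2), 4))
  d <- learn_dictionary(tr, bag_size = 2L)
  p <- withr::local_tempfile(fileext = ".txt")
  write_dictionary(d, p)
  back <- read_dictionary(p)
  expect_equal(back$atoms, d$atoms)
  expect_equal(back$class_code, d$class_code)
  expect_equal(back$bag_size, 2L)
  expect_equal(back$normalize, d$normalize)
})
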