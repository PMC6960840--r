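test_that("endmembers are bump sums with unit peak and distinct classes", {
  sp <- scene_spec(rows = 6, cols = 6, bands = 21, n_classes = 2, seed = 1,
                   endmember_spec = list(
                     cbind(center = 10, width = 2, amplitude = 1),
                     cbind(center = 18, width = 1, amplitude = 0.7)))
  E <- make_endmembers(sp)
  expect_equal(which.max(E[1, ]), 10)
  expect_equal(max(E[1, ]), 1)           # rescaled to unit peak
  expect_equal(max(E[2, ]), 1)
  # near-disjoint bump supports -> near-zero cosine
  cs <- sum(E[1, ] * E[2, ]) / sqrt(sum(E[1, ]^2) * sum(E[2, ]^2))
  expect_lt(cs, 0.05)
  # identical specs for two classes are refused
  sp_bad <- scene_spec(rows = 6, cols = 6, bands = 21, n_classes = 2, seed = 1,
                       endmember_spec = rep(list(
                         cbind(center = 10, width = 2, amplitude = 1)), 2))
  expect_error(make_endmembers(sp_bad), "degenerate")
})

test_that("endmember generation is deterministic in the seed", {
  sp <- scene_spec(preset = "phi", seed = 42)
  expect_identical(make_endmembers(sp), make_endmembers(sp))
  sp2 <- scene_spec(preset = "phi", seed = 43)
  expect_false(identical(make_endmembers(sp), make_endmembers(sp2)))
})

test_that("noiseless scenes reproduce endmembers at every labeled pixel", {
  sp <- scene_spec(rows = 12, cols = 12, bands = 30, n_classes = 4,
                   snr_db = 120, mix_fraction = 0, seed = 7)
  tr <- render_scene(sp)
  for (k in 1:4) {
    px <- extract_pixels(tr$cube, tr$labels, k)
    rel <- abs(sweep(px, 2L, tr$endmembers[k, ])) / max(tr$endmembers[k, ])
    expect_lt(max(rel), 1e-5)
  }
})

test_that("rendered noise matches the requested SNR within 1 dB", {
  sp <- scene_spec(rows = 110, cols = 100, bands = 20, n_classes = 4,
                   snr_db = 20, mix_fraction = 0, seed = 8)
  tr <- render_scene(sp)
  lab <- as.vector(t(tr$labels$labels))
  keep <- lab > 0
  expect_gt(sum(keep), 1e4)
  px <- ddsr:::cube_to_matrix(tr$cube)[keep, ]
  sig <- tr$endmembers[lab[keep], ]
  snr_est <- 10 * log10(mean(sig^2) / mean((px - sig)^2))
  expect_lt(abs(snr_est - 20), 1)
})

test_that("scenes are deterministic and abundances live on the simplex", {
  sp <- scene_spec(rows = 12, cols = 12, bands = 16, n_classes = 3,
                   snr_db = 25, mix_fraction = 0.3, seed = 9)
  t1 <- render_scene(sp); t2 <- render_scene(sp)
  expect_identical(t1$cube$data, t2$cube$data)
  expect_identical(t1$labels$labels, t2$labels$labels)
  lab <- as.vector(t(t1$labels$labels))
  A <- t1$abundances[lab > 0, ]
  expect_true(all(A >= 0))
  expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-12)
  # mixed pixels carry their patch's class as the dominant weight
  expect_true(all(A[cbind(seq_len(nrow(A)), lab[lab > 0])] >= 0.5))
})

test_that("pixels approach their endmember monotonically in SNR", {
  dist_at <- function(snr) {
    sp <- scene_spec(rows = 12, cols = 12, bands = 16, n_classes = 3,
                     snr_db = snr, mix_fraction = 0, seed = 10)
    tr <- render_scene(sp)
    lab <- as.vector(t(tr$labels$labels))
    px <- ddsr:::cube_to_matrix(tr$cube)[lab > 0, ]
    mean(sqrt(rowSums((px - tr$endmembers[lab[lab > 0], ])^2)))
  }
  d <- vapply(c(10, 20, 30), dist_at, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("training draws honor quotas, seeds, and per-class overrides", {
  sp <- scene_spec(preset = "phi", rows = 21, cols = 21, snr_db = 30,
                   seed = 11)
  tr <- render_scene(sp)
  # 0.5 x 65 bands over 7 classes: 32 total, quotas within 1 of each other
  s <- sample_training(tr, 0.5, seed = 1)
  quotas <- vapply(s, nrow, integer(1))
  expect_equal(sum(quotas), round(0.5 * 65))
  expect_lte(diff(range(quotas)), 1)
  # remainder goes to the lowest class codes
  expect_true(all(diff(quotas) <= 0))
  # reproducible under the seed; different under another
  s2 <- sample_training(tr, 0.5, seed = 1)
  expect_identical(s, s2)
  s3 <- sample_training(tr, 0.5, seed = 2)
  expect_false(identical(s, s3))
  # per-class override (e.g. 4 per ground cover)
  s4 <- sample_training(tr, seed = 1, per_class = 4)
  expect_true(all(vapply(s4, nrow, integer(1)) == 4))
  # quota boundary: exactly the class's full pixel set
  n1 <- nrow(extract_pixels(tr$cube, tr$labels, 1L))
  s5 <- sample_training(tr, seed = 1, per_class = n1)
  expect_equal(nrow(s5[[1]]), n1)
  expect_error(sample_training(tr, seed = 1, per_class = n1 + 1),
               "quota")
})

test_that("contamination replaces the stated fraction with other classes", {
  sp <- scene_spec(rows = 20, cols = 20, bands = 16, n_classes = 4,
                   snr_db = 120, seed = 12)
  tr <- render_scene(sp)
  training <- sample_training(tr, seed = 1, per_class = 8)
  cont <- contaminate_training(training, tr, 0.25, seed = 2)
  for (k in 1:4) {
    # at 120 dB a replaced row sits on another class's endmember
    d_own <- rowSums(sweep(cont[[k]], 2L, tr$endmembers[k, ])^2)
    expect_equal(sum(d_own > 1e-6), 2)  # round(0.25 * 8)
  }
  expect_identical(contaminate_training(training, tr, 0, seed = 2), training)
})
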