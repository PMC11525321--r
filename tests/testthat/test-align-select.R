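# DTW alignment, spectral inlier selection, uniform-shift alignment.

make_ann <- function(v, id, stim = "s1", rate = 1) {
  annotation(v, rate_hz = rate, annotator_id = id, stimulus_id = stim)
}

test_that("identical annotations align to themselves", {
  x <- make_ann(sin(seq(0, 6, length.out = 40)) * 50, "a")
  y <- make_ann(x$values, "b")
  pr <- dtw_align_pair(x, y, band_s = 5, seed = 3)
  expect_equal(pr$x$values, pr$y$values)
  expect_equal(length(pr$x$values), 40)
})

test_that("a delay within the band is recovered (post-alignment SDA 1)", {
  base <- c(rep(0, 10), seq(0, 50, length.out = 10), rep(50, 10),
            seq(50, 10, length.out = 10), rep(10, 10))
  delayed <- c(rep(0, 2), base[1:(length(base) - 2)])
  x <- make_ann(base, "a")
  y <- make_ann(delayed, "b")
  pr <- dtw_align_pair(x, y, band_s = 5, seed = 1)
  expect_equal(sda(pr$x, pr$y), 1)
})

test_that("length differences beyond the band are infeasible", {
  x <- make_ann(rnorm(10), "a")
  y <- make_ann(rnorm(40), "b")
  expect_error(dtw_align_pair(x, y, band_s = 5, seed = 1), "infeasible")
  expect_error(dtw_align_pair(x, x, band_s = 0.2, seed = 1),
               "sampling period")
})

test_that("warp paths are monotone and stay within the band", {
  set.seed(5)
  x <- make_ann(cumsum(rnorm(30)), "a")
  y <- make_ann(cumsum(rnorm(30)), "b")
  pr <- dtw_align_pair(x, y, band_s = 4, seed = 2)
  expect_true(all(diff(pr$path$ref_index) >= 0))
  expect_true(all(diff(pr$path$query_index) >= 0))
  expect_true(all(abs(pr$path$ref_index - pr$path$query_index) <= 4))
})

test_that("trend-identical majority beats a sign-flipped minority", {
  base <- c(0, 5, 10, 15, 15, 15, 10, 5, 0, 0, 5, 10)
  anns <- c(
    lapply(1:6, function(i) make_ann(base * (0.5 + 0.2 * i) + i, paste0("g", i))),
    lapply(1:3, function(i) make_ann(-base * (0.8 + 0.1 * i) + 40, paste0("f", i))))
  sel <- select_inliers(anns, band_s = 2, seed = 11)
  expect_setequal(sel$inlier_ids, paste0("g", 1:6))
  expect_setequal(sel$outlier_ids, paste0("f", 1:3))
})

test_that("three annotations are all inliers (bipartition degenerate)", {
  anns <- lapply(1:3, function(i) make_ann(c(0, 1, 2, 3, 2, 1), paste0("a", i)))
  sel <- select_inliers(anns, seed = 1)
  expect_setequal(sel$inlier_ids, paste0("a", 1:3))
  expect_length(sel$outlier_ids, 0)
})

test_that("selection is invariant to affine revaluation and annotator order", {
  st <- simulate_study(n_annotators = 5, n_adversarial = 2, n_runs = 5,
                       grid_len = 80, seed = 9)
  anns <- st$annotations
  sel1 <- select_inliers(anns, seed = 2)
  rescaled <- lapply(anns, function(a)
    annotation(0.3 * a$values - 11, rate_hz = a$rate_hz,
               annotator_id = a$annotator_id, stimulus_id = a$stimulus_id))
  sel2 <- select_inliers(rescaled, seed = 2)
  expect_setequal(sel1$inlier_ids, sel2$inlier_ids)
})

test_that("planted adversaries land among the outliers at low noise", {
  hits <- 0
  for (seed in 1:25) {
    st <- simulate_study(n_annotators = 6, n_adversarial = 2, n_runs = 5,
                         grid_len = 80, seed = seed,
                         noise_sd = 0.3, drift_sd = 1, overshoot_gain = 0.05)
    sel <- select_inliers(st$annotations, seed = seed)
    if (all(c("adv1", "adv2") %in% sel$outlier_ids)) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.95)
})

test_that("the inlier reference is the annotation with highest mean agreement", {
  a1 <- make_ann(c(0, 1, 2, 2, 1, 0), "a1")
  a2 <- make_ann(c(0, 1, 2, 2, 1, 1), "a2")   # agrees most with both others
  a3 <- make_ann(c(0, 1, 2, 2, 2, 2), "a3")
  aln <- align_inliers(list(a1, a2, a3), band_s = 2)
  M <- sda_matrix(list(a1, a2, a3))
  diag(M) <- NA
  expect_equal(aln$reference_id,
               rownames(M)[which.max(rowMeans(unclass(M), na.rm = TRUE))])
  # two identical inliers come back unchanged
  aln2 <- align_inliers(list(a1, make_ann(a1$values, "b1")), band_s = 2)
  expect_equal(aln2$annotations[[1]]$values, aln2$annotations[[2]]$values)
})

test_that("delayed copies align to pairwise SDA 1 under the reference", {
  base <- c(rep(0, 8), seq(0, 40, length.out = 8), rep(40, 8),
            seq(40, 5, length.out = 8), rep(5, 8))
  anns <- lapply(0:2, function(d)
    make_ann(c(rep(0, d), base[1:(length(base) - d)]), paste0("a", d)))
  aln <- align_inliers(anns, band_s = 5)
  n <- length(aln$annotations)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    expect_equal(sda(aln$annotations[[i]], aln$annotations[[j]]), 1)
})

test_that("uniform shift alignment recovers a constructed offset", {
  set.seed(3)
  base <- cumsum(rnorm(60))
  x <- make_ann(base, "a")
  y <- make_ann(c(rep(base[1], 3), base[1:57]), "b")
  res <- uniform_shift_align(list(x, y), max_shift_s = 5)
  expect_true(res$success)
  expect_equal(abs(unname(diff(res$shifts))), 3)

  res_id <- uniform_shift_align(list(x, make_ann(base, "b")), max_shift_s = 5)
  expect_true(res_id$success)
  expect_equal(unname(res_id$shifts), c(0L, 0L))

  flat <- lapply(1:2, function(i) make_ann(rep(3, 30), paste0("c", i)))
  res_flat <- uniform_shift_align(flat, max_shift_s = 5)
  expect_false(res_flat$success)
})
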