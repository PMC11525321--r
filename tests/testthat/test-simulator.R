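# Latent signal generator, annotator models, and the comparison oracle.

test_that("one run gives a constant signal; generation is deterministic", {
  s1 <- generate_true_signal(1, 30, seed = 5)
  expect_equal(s1$values, rep(s1$values[1], 30))
  expect_equal(nrow(s1$flats), 1)
  s2 <- generate_true_signal(6, 90, seed = 8)
  s3 <- generate_true_signal(6, 90, seed = 8)
  expect_identical(s2$values, s3$values)
  expect_error(generate_true_signal(10, 15), "infeasible")
})

test_that("recorded flats match an independent scan for zero-slope runs", {
  for (seed in c(1, 4, 9)) {
    sig <- generate_true_signal(7, 120, seed = seed)
    d <- diff(sig$values)
    r <- rle(abs(d) < 1e-12)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    # a zero-diff run over steps s..e means samples s..e+1 are constant
    scan <- data.frame(start = starts[keep], end = ends[keep] + 2L)
    expect_equal(sig$flats$start, scan$start)
    expect_equal(sig$flats$end, scan$end)
    expect_equal(sig$flats$level, sig$values[sig$flats$start])
  }
})

test_that("explicit node levels are honored", {
  sig <- generate_true_signal(5, 60, levels = c(0.2, 0.8, 0.4), seed = 1)
  expect_equal(sig$flats$level, c(0.2, 0.8, 0.4))
  expect_equal(max(sig$values), 0.8)
  expect_error(generate_true_signal(5, 60, levels = c(0.2, 0.8), seed = 1),
               "length 3")
})

test_that("an error-free identity annotator reproduces the signal", {
  sig <- generate_true_signal(5, 60, level_range = c(-50, 50), seed = 3)
  ident <- make_annotator("id", lag_s = 0, overshoot_gain = 0, drift_sd = 0,
                          noise_sd = 0, deadzone = 0,
                          perception = data.frame(x = c(-100, 100),
                                                  y = c(-100, 100)))
  ann <- simulate_annotation(sig, ident, seed = 1, range_adapt = FALSE)
  expect_equal(ann$values, sig$values)
})

test_that("noiseless monotone perception keeps SDA with the truth at 1", {
  sig <- generate_true_signal(7, 100, seed = 6)
  ann <- simulate_annotation(
    sig, make_annotator("m", lag_s = 0, overshoot_gain = 0, drift_sd = 0,
                        noise_sd = 0, deadzone = 0, seed = 21), seed = 2)
  expect_equal(sda(ann$values, sig$values), 1)
})

test_that("overshoot peaks inside the window after a trend completes", {
  # levels kept inside the scale so the pulse is not clipped away at the top
  sig <- generate_true_signal(3, 40, levels = c(0.15, 0.75), seed = 2)
  ann <- simulate_annotation(
    sig, make_annotator("o", lag_s = 0, overshoot_gain = 0.5, drift_sd = 0,
                        noise_sd = 0, deadzone = 0,
                        perception = data.frame(x = c(0, 1), y = c(-100, 100))),
    seed = 1, range_adapt = FALSE)
  base <- approx(c(0, 1), c(-100, 100), xout = sig$values)$y
  resid <- abs(ann$values - base)
  onset <- sig$flats$start[2] # sample where the rise reaches its level
  expect_true(which.max(resid) %in% onset:(onset + 3))
  expect_gt(max(resid), 0)
})

test_that("annotations are reproducible under (params, seed)", {
  sig <- generate_true_signal(5, 60, seed = 1)
  a <- make_annotator("a", seed = 4)
  expect_identical(simulate_annotation(sig, a, seed = 9)$values,
                   simulate_annotation(sig, a, seed = 9)$values)
})

test_that("drift degrades value agreement but spares trend agreement", {
  sig <- generate_true_signal(7, 120, seed = 12)
  # SDA read at the motor model's move granularity (zero_tol 3 units): a
  # revaluation jump during a flat is a value error, not a trend
  mean_pair <- function(drift) {
    anns <- lapply(1:5, function(i)
      simulate_annotation(sig, make_annotator(
        paste0("a", i), lag_s = 0, overshoot_gain = 0, noise_sd = 0,
        deadzone = 2, drift_sd = drift, seed = 100 + i), seed = 200 + i))
    M <- sapply(anns, `[[`, "values")
    cm <- cor(M)
    sm <- sda_matrix(anns, zero_tol = 3)
    c(pearson = mean(cm[upper.tri(cm)]),
      sda = mean(unclass(sm)[upper.tri(sm)]))
  }
  res <- sapply(c(0, 1, 2), mean_pair)
  expect_true(all(diff(res["pearson", ]) < 0))
  expect_true(all(abs(res["sda", ] - res["sda", 1]) <= 0.05))
})

test_that("the comparison oracle follows its logistic noise model", {
  pairs <- data.frame(region_a = "x", region_b = "y")
  levels <- c(x = 0.2, y = 0.7)
  # noiseless limit: always the truly lower region
  for (s in 1:10)
    expect_equal(oracle_compare(pairs, levels, beta = Inf, seed = s)$lower, "x")
  # beta = 0: chance level
  hits <- vapply(1:1000, function(s)
    oracle_compare(pairs, levels, beta = 0, seed = s)$lower == "x", logical(1))
  expect_gt(mean(hits), 0.45)
  expect_lt(mean(hits), 0.55)
  # equal levels: random and flagged
  tie <- oracle_compare(pairs, c(x = 0.5, y = 0.5), beta = Inf, seed = 1)
  expect_true(tie$flagged)
})

test_that("injected lapses produce flagged gaps after resampling", {
  st <- simulate_study(n_annotators = 1, n_runs = 5, grid_len = 60, seed = 3)
  log <- annotation_to_event_log(st$annotations[[1]])
  # remove events across a sloped run so the gap endpoints differ
  sl <- st$signal$run_bounds[2:3]
  lapsed <- inject_lapse(log, at_s = sl[1] - 1, duration_s = diff(sl))
  ann <- resample(lapsed, rate_hz = 1)
  expect_gt(sum(is.na(ann$values)), 0)
})
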