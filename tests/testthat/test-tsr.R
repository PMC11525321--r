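# Trapezoidal segmented regression, segment-budget heuristic, trend codes.

trapezoid <- function() {
  c(rep(2, 5), seq(2, 8, length.out = 5)[-1], rep(8, 4),
    seq(8, 1, length.out = 6)[-1])
}

test_that("a realizable trapezoid is fit exactly with its true budget", {
  v <- trapezoid()
  m <- fit_tsr(v, 4)
  expect_equal(m$sse, 0, tolerance = 1e-10)
  expect_equal(m$segment_kinds, c("flat", "sloped", "flat", "sloped"))
  expect_equal(m$breakpoints, c(1, 5, 9, 13, 18))
  expect_equal(m$fitted, v, tolerance = 1e-8)
})

test_that("T = 1 is the least-squares constant", {
  set.seed(2)
  v <- rnorm(15)
  m <- fit_tsr(v, 1)
  expect_equal(m$sse, sum((v - mean(v))^2))
  expect_equal(unique(m$values), mean(v))
  expect_equal(m$segment_kinds, "flat")
})

test_that("the exact engine equals brute force on random small instances", {
  set.seed(11)
  for (k in 1:40) {
    n <- sample(6:12, 1)
    T <- min(sample(1:4, 1), n - 2)
    v <- rnorm(n)
    expect_equal(fit_tsr(v, T)$sse, oracle_tsr_sse(v, T), tolerance = 1e-9)
  }
})

test_that("sse (min over parities) is non-increasing in T", {
  set.seed(13)
  for (k in 1:10) {
    v <- rnorm(12)
    sses <- vapply(1:4, function(T) fit_tsr(v, T)$sse, numeric(1))
    expect_true(all(diff(sses) <= 1e-9))
  }
})

test_that("refitting a TSR to its own samples reproduces it exactly", {
  set.seed(17)
  v <- rnorm(30)
  m <- fit_tsr(v, 3)
  m2 <- fit_tsr(m$fitted, 3)
  expect_equal(m2$sse, 0, tolerance = 1e-9)
  # also through the large-scale dynamic-program path
  sig <- generate_true_signal(7, 120, seed = 5)
  m3 <- fit_tsr(sig$values, 7)
  expect_equal(m3$sse, 0, tolerance = 1e-8)
  expect_false(m3$exact)
})

test_that("infeasible budgets and missing samples are rejected", {
  expect_error(fit_tsr(rnorm(4), 4), "budget too large")
  expect_error(fit_tsr(c(1, NA, 3, 4, 5), 2), "complete")
  expect_error(fit_tsr(rnorm(5), 0), "at least 1")
})

test_that("T_hat counts macro trend runs", {
  expect_equal(estimate_T_hat(seq(0, 10, length.out = 20)), 1L)
  expect_equal(estimate_T_hat(trapezoid(), smooth_w = 1), 4L)
  hits <- 0
  for (s in 1:20) {
    st <- simulate_study(n_annotators = 1, n_runs = 7, grid_len = 120, seed = s,
                         noise_sd = 0.3, drift_sd = 0.5, overshoot_gain = 0,
                         lag_s = 0)
    th <- estimate_T_hat(st$annotations[[1]]$values)
    if (abs(th - 7) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("the candidate set follows the printed 4/5 .. 6/5 rule", {
  sb <- select_segment_count(generate_true_signal(10, 120, seed = 2)$values, 10)
  expect_equal(sb$candidates, 8:12)
  expect_true(sb$T_prime %in% sb$candidates)
  # floor at 1
  sb2 <- select_segment_count(c(1, 2, 3, 2, 1, 2, 3), 1)
  expect_equal(sb2$candidates, 1:2)
})

test_that("the SDA-then-tau scan follows the documented two-stage rule", {
  sel <- ogt:::.select_from_profiles(8:12,
                                     c(.80, .90, .85, .88, .87),
                                     c(.70, .72, .75, .74, .73))
  expect_equal(sel$T_prime, 10) # SDA local max at 9, then tau local max at 10
  # strictly increasing profiles select the endpoint
  sel2 <- ogt:::.select_from_profiles(8:12, seq(.5, .9, .1), seq(.4, .8, .1))
  expect_equal(sel2$T_prime, 12)
  # immediately decreasing profiles stop at the first candidate
  sel3 <- ogt:::.select_from_profiles(3:5, c(.9, .8, .7), c(.9, .8, .7))
  expect_equal(sel3$T_prime, 3)
})

test_that("a realizable budget inside the candidate set reaches SDA 1", {
  v <- trapezoid()
  sb <- select_segment_count(v, 4)
  expect_equal(sb$sda_profile[match(4, sb$candidates)], 1)
  expect_equal(fit_tsr(v, sb$T_prime)$sse, 0, tolerance = 1e-9)
})

test_that("trend codes follow segment slopes with half-open boundaries", {
  m <- structure(
    list(breakpoints = c(1L, 4L, 7L, 9L), values = c(2, 2, 5, 5),
         segment_kinds = c("flat", "sloped", "flat"), T = 3L, sse = 0, n = 9L),
    class = "tsr_model")
  expect_equal(to_tss(m)$codes, c(0, 0, 0, 1, 1, 1, 0, 0, 0))
  m_down <- structure(
    list(breakpoints = c(1L, 6L), values = c(5, 0),
         segment_kinds = "sloped", T = 1L, sse = 0, n = 6L),
    class = "tsr_model")
  expect_equal(to_tss(m_down)$codes, rep(-1, 6))
})

test_that("random TSR codes agree with independently recomputed slope signs", {
  set.seed(23)
  for (k in 1:10) {
    v <- rnorm(20)
    m <- fit_tsr(v, sample(2:4, 1))
    codes <- to_tss(m)$codes
    for (j in seq_len(m$T)) {
      a <- m$breakpoints[j]; b <- m$breakpoints[j + 1]
      idx <- if (j == m$T) a:m$n else a:(b - 1)
      slope <- (m$values[j + 1] - m$values[j]) / (b - a)
      want <- if (m$segment_kinds[j] == "flat") 0 else sign(slope)
      expect_true(all(codes[idx] == want))
    }
  }
})

test_that("TSR models survive a JSON round trip", {
  m <- fit_tsr(trapezoid(), 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_tsr(m, f)
  back <- read_tsr(f)
  expect_equal(back$breakpoints, m$breakpoints)
  expect_equal(back$values, m$values)
  expect_equal(back$fitted, m$fitted)
})

test_that("missing blocks receive code 0 and the longest block is fitted", {
  v <- c(rep(NA, 3), trapezoid(), NA, 1, 2) # trapezoid spans samples 4..21
  ts <- tss_for_values(v, T_hat = 4)
  expect_equal(ts$block, c(4, 21))
  expect_true(all(ts$codes[1:3] == 0))
  expect_true(all(ts$codes[22:24] == 0))
})
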