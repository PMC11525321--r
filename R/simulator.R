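# Simulator of latent construct signals, annotators, and a pairwise
# comparison oracle — the test bed for every pipeline stage. Annotators obey
# the two perceptual assumptions the pipeline is built on: each has a unique,
# strictly monotone perception function (so trends are captured reliably)
# while their *values* are corrupted by overshoot at trend changes, slow
# drift in revaluation, reaction lag, and white noise.

#' Generate a latent trapezoidal construct signal
#'
#' Alternating flat/sloped runs (starting flat) with randomized durations and
#' flat levels; the flat windows and their levels are recorded as ground
#' truth for recovery tests. Consecutive node levels are kept at least 15%
#' of the level range apart so every sloped run has a visible slope.
#'
#' @param n_runs number of runs (1 gives a constant signal).
#' @param grid_len number of samples (>= 2 * n_runs).
#' @param level_range numeric length-2 range of construct levels.
#' @param levels optional explicit node levels (one per flat run, plus one
#'   more if the final run is sloped); overrides random draws.
#' @param seed integer seed.
#' @param rate_hz sampling rate.
#' @param stimulus_id identifier stamped on the signal.
#' @return A `true_signal`: list with `values`, `flats` (data.frame `start`,
#'   `end` half-open, `level`), `kinds`, `rate_hz`, `stimulus_id`, `seed`.
#' @export
generate_true_signal <- function(n_runs, grid_len, level_range = c(0, 1),
                                 levels = NULL, seed = 1, rate_hz = 1,
                                 stimulus_id = "s1") {
  n_runs <- as.integer(n_runs)
  if (n_runs < 1) stop("n_runs must be at least 1")
  if (grid_len < 2 * n_runs)
    stop(sprintf("infeasible run count: %d runs need at least %d samples",
                 n_runs, 2 * n_runs))
  kinds <- rep(c("flat", "sloped"), length.out = n_runs)
  n_nodes <- sum(kinds == "flat") + (kinds[n_runs] == "sloped")
  rng <- diff(level_range)
  .with_seed(seed, {
    # durations: 2-sample floor, remainder split by random weights
    w <- runif(n_runs, 0.7, 1.3)
    extra <- grid_len - 2L * n_runs
    add <- floor(extra * w / sum(w))
    short <- extra - sum(add)
    if (short > 0) {
      ord <- order(extra * w / sum(w) - add, decreasing = TRUE)
      add[ord[seq_len(short)]] <- add[ord[seq_len(short)]] + 1L
    }
    lens <- 2L + add
    if (is.null(levels)) {
      levels <- numeric(n_nodes)
      levels[1] <- runif(1, level_range[1], level_range[2])
      if (n_nodes > 1) for (k in 2:n_nodes) {
        for (try in 1:200) {
          cand <- runif(1, level_range[1], level_range[2])
          if (abs(cand - levels[k - 1]) >= 0.15 * rng) break
        }
        levels[k] <- cand
      }
    } else {
      levels <- as.numeric(levels)
      if (length(levels) != n_nodes)
        stop(sprintf("levels must have length %d for %d runs", n_nodes, n_runs))
    }
  })
  # trapezoidal construction: node values at run boundaries, linear between
  bounds <- c(1L, cumsum(lens))
  u <- numeric(n_runs + 1)
  node <- 1L
  u[1] <- levels[1]
  for (j in seq_len(n_runs)) {
    if (kinds[j] == "flat") {
      u[j + 1] <- levels[node]
    } else {
      node <- node + 1L
      u[j + 1] <- levels[node]
    }
  }
  vals <- approx(bounds, u, xout = seq_len(grid_len), rule = 2)$y
  # recorded flats: constant windows, including the final sample of the
  # sloped run that reaches the level
  fl <- which(kinds == "flat")
  flats <- data.frame(
    start = ifelse(fl == 1L, 1L, bounds[fl]),
    end = bounds[fl + 1L] + 1L,
    level = levels[cumsum(kinds == "flat")[fl]])
  structure(
    list(values = vals, flats = flats, kinds = kinds, run_bounds = bounds,
         rate_hz = rate_hz, stimulus_id = stimulus_id, seed = seed),
    class = "true_signal")
}

#' @export
print.true_signal <- function(x, ...) {
  cat(sprintf("<true_signal> stimulus %s: %d samples, %d runs (%d flats)\n",
              x$stimulus_id, length(x$values), length(x$kinds), nrow(x$flats)))
  invisible(x)
}

# Draw a strictly monotone 4-knot piecewise-linear perception map from the
# construct scale [0, 1] to the annotation scale [v_min, v_max]. Maps are
# compressive toward the top of the scale (y = x^gamma at the knots,
# gamma < 1): continuous raters typically exhaust the upper range early and
# then discriminate high construct levels poorly, while remaining strictly
# increasing.
.random_perception <- function(v_min, v_max, decreasing = FALSE) {
  repeat {
    xk <- c(0, sort(runif(2, 0.15, 0.85)), 1)
    if (min(diff(xk)) >= 0.08) break
  }
  gamma <- runif(1, 0.35, 0.85)
  yk <- xk^gamma
  if (decreasing) yk <- 1 - yk
  data.frame(x = xk, y = v_min + (v_max - v_min) * yk)
}

#' Construct an annotator model
#'
#' An annotator is a strictly monotone piecewise-linear perception map plus
#' a documented error structure: reaction lag, multiplicative overshoot at
#' trend changes, slow drift (a low-pass filtered random walk), and white
#' noise. An adversarial annotator has a strictly *decreasing* perception
#' map — a planted outlier for selection tests.
#'
#' @param annotator_id identifier.
#' @param lag_s reaction delay in seconds (>= 0).
#' @param overshoot_gain fraction of each trend's perceived value change
#'   added as a decaying pulse when the new level is reached.
#' @param drift_sd per-step standard deviation of the drift random walk, in
#'   annotation units, before low-pass filtering.
#' @param drift_cutoff_hz low-pass cutoff of the drift (default 0.02 Hz:
#'   revaluation wanders over tens of seconds, not sample to sample).
#' @param noise_sd valuation noise in annotation units, applied each time the
#'   annotator moves the trace.
#' @param deadzone input dead zone in annotation units: the annotator holds
#'   the current value until the perceived target departs from it by more
#'   than this, mimicking a changes-only interface where the trace is exactly
#'   constant between adjustments. Set 0 for continuous tracking.
#' @param v_min,v_max annotation scale bounds.
#' @param adversarial if `TRUE` the perception map is decreasing.
#' @param perception optional explicit perception map, a data.frame with
#'   strictly increasing `x` (construct scale) and monotone `y` (annotation
#'   scale) knots; `NULL` draws a random 4-knot map under `seed`.
#' @param seed integer seed for the random perception map.
#' @return An `annotator_model`.
#' @export
make_annotator <- function(annotator_id = "a1", lag_s = 1, overshoot_gain = 0.25,
                           drift_sd = 2, drift_cutoff_hz = 0.02, noise_sd = 1,
                           deadzone = 2, v_min = -100, v_max = 100,
                           adversarial = FALSE, perception = NULL, seed = 1) {
  stopifnot(lag_s >= 0, overshoot_gain >= 0, drift_sd >= 0, noise_sd >= 0,
            deadzone >= 0)
  if (is.null(perception)) {
    perception <- .with_seed(seed, .random_perception(v_min, v_max, adversarial))
  } else {
    stopifnot(is.data.frame(perception), all(c("x", "y") %in% names(perception)),
              all(diff(perception$x) > 0))
  }
  structure(
    list(annotator_id = as.character(annotator_id), perception = perception,
         lag_s = lag_s, overshoot_gain = overshoot_gain, drift_sd = drift_sd,
         drift_cutoff_hz = drift_cutoff_hz, noise_sd = noise_sd,
         deadzone = deadzone, v_min = v_min, v_max = v_max,
         adversarial = adversarial, seed = seed),
    class = "annotator_model")
}

#' @export
print.annotator_model <- function(x, ...) {
  cat(sprintf("<annotator_model> %s%s: lag %.2g s, overshoot %.2g, drift sd %.2g, noise sd %.2g\n",
              x$annotator_id, if (x$adversarial) " (adversarial)" else "",
              x$lag_s, x$overshoot_gain, x$drift_sd, x$noise_sd))
  invisible(x)
}

#' Draw a diverse annotator panel
#'
#' Good annotators get heterogeneous monotone perceptions, lags of 0.5-2.5 s,
#' overshoot gains of 0.2-0.5, random-walk drift of 2-5 units/step before
#' low-pass filtering (slow revaluation wander of roughly 5-20% of the
#' -100..100 scale, the dominant value-unreliability in crowd annotation),
#' move noise of 0.5-2 units, and dead zones of 1-3 units; adversarial
#' members differ only in their decreasing perception.
#'
#' @param n_annotators panel size.
#' @param n_adversarial how many of them are adversarial (planted outliers).
#' @param seed integer seed.
#' @param ... overrides passed to [make_annotator()] (scalar or per-annotator
#'   vectors).
#' @return list of `annotator_model`s; adversarial members last, ids
#'   `adv<k>`.
#' @export
sample_annotator_panel <- function(n_annotators = 8, n_adversarial = 0,
                                   seed = 1, ...) {
  n <- n_annotators + n_adversarial
  pars <- .with_seed(seed, data.frame(
    lag_s = runif(n, 0.5, 2.5),
    overshoot_gain = runif(n, 0.2, 0.5),
    drift_sd = runif(n, 2, 5),
    noise_sd = runif(n, 0.5, 2),
    deadzone = runif(n, 1, 3)))
  over <- list(...)
  for (nm in names(over)) pars[[nm]] <- rep(over[[nm]], length.out = n)
  ids <- c(sprintf("a%02d", seq_len(n_annotators)),
           if (n_adversarial) sprintf("adv%d", seq_len(n_adversarial)))
  lapply(seq_len(n), function(i) {
    make_annotator(ids[i], lag_s = pars$lag_s[i],
                   overshoot_gain = pars$overshoot_gain[i],
                   drift_sd = pars$drift_sd[i], noise_sd = pars$noise_sd[i],
                   deadzone = pars$deadzone[i],
                   adversarial = i > n_annotators, seed = seed * 1000 + i)
  })
}

#' Simulate one continuous annotation of a true signal
#'
#' The annotator's *intended* value is `P(T(t - lag))` plus a decaying
#' overshoot pulse after each trend reaches its level (amplitude
#' `overshoot_gain` times the perceived value change of the trend, 4-sample
#' exponential decay) plus low-pass filtered random-walk drift. The emitted
#' trace follows the intent through a motor model: the annotator holds the
#' current value until the intent departs from it by more than `deadzone`,
#' then moves to the intent plus valuation noise. Flat stretches are
#' therefore exactly constant (as a changes-only interface records them)
#' while values remain unreliable — trends survive, values do not.
#'
#' @param true_signal a `true_signal`.
#' @param annotator an `annotator_model`.
#' @param seed integer seed for drift and noise.
#' @param range_adapt if `TRUE` (default) the annotator calibrates to the
#'   stimulus: the perception map is applied to the construct levels
#'   rescaled over the range actually observed in this stimulus, so every
#'   stimulus is rated up to the top of the scale however mild it is in
#'   absolute terms. Set `FALSE` for an absolutely anchored rater.
#' @return An [annotation] at the signal's rate.
#' @export
simulate_annotation <- function(true_signal, annotator, seed = 1,
                                range_adapt = TRUE) {
  stopifnot(inherits(true_signal, "true_signal"),
            inherits(annotator, "annotator_model"))
  z <- true_signal$values
  n <- length(z)
  rate <- true_signal$rate_hz
  lag_n <- as.integer(round(annotator$lag_s * rate))
  z_lag <- z[pmax(1L, seq_len(n) - lag_n)]
  # Range adaptation: raters calibrate to the stimulus at hand, spreading
  # their response over the range of construct levels they actually observe
  # (every stimulus gets rated up to the top of the scale, however mild it
  # is in absolute terms). Within-stimulus monotonicity is untouched.
  if (range_adapt && diff(range(z_lag)) > 0) {
    lo <- min(annotator$perception$x)
    hi <- max(annotator$perception$x)
    z_lag <- lo + (hi - lo) * (z_lag - min(z_lag)) / diff(range(z_lag))
  }
  base <- approx(annotator$perception$x, annotator$perception$y,
                 xout = z_lag, rule = 2)$y
  # overshoot pulses where a trend reaches its new level
  pulse <- numeric(n)
  if (annotator$overshoot_gain > 0) {
    d <- diff(z_lag)
    s <- .sgn_tol(d, 1e-12)
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values != 0)) {
      onset <- ends[k] + 1L        # first sample at the new level
      change <- base[ends[k] + 1L] - base[starts[k]]
      idx <- onset + 0:3
      idx <- idx[idx <= n]
      pulse[idx] <- pulse[idx] +
        annotator$overshoot_gain * change * exp(-(seq_along(idx) - 1))
    }
  }
  .with_seed(seed, {
    drift <- if (annotator$drift_sd > 0) {
      rw <- cumsum(rnorm(n, 0, annotator$drift_sd))
      wc <- min(0.9, 2 * annotator$drift_cutoff_hz / rate)
      f <- if (n > 30) {
        bt <- signal::butter(2, wc)
        as.numeric(signal::filtfilt(bt$b, bt$a, rw))
      } else rw
      f - mean(f)
    } else numeric(n)
    eps <- if (annotator$noise_sd > 0) rnorm(n, 0, annotator$noise_sd) else numeric(n)
    intended <- base + pulse + drift
    vals <- numeric(n)
    vals[1] <- intended[1] + eps[1]
    for (t in 2:n) {
      vals[t] <- if (abs(intended[t] - vals[t - 1]) > annotator$deadzone)
        intended[t] + eps[t] else vals[t - 1]
    }
    vals <- pmin(annotator$v_max, pmax(annotator$v_min, vals))
    annotation(vals, rate_hz = rate, annotator_id = annotator$annotator_id,
               stimulus_id = true_signal$stimulus_id)
  })
}

#' Convert an annotation to a changes-only event log
#'
#' Emits an event at the first sample and at every sample whose value differs
#' from the previous one — the logging behavior of a changes-only annotation
#' interface.
#'
#' @param x an [annotation] without missing samples.
#' @return An [event_log].
#' @export
annotation_to_event_log <- function(x) {
  stopifnot(inherits(x, "annotation"))
  if (anyNA(x$values)) stop("cannot log an annotation with missing samples")
  tt <- annotation_times(x)
  keep <- c(TRUE, diff(x$values) != 0)
  # always keep the final sample so the log spans the full duration
  keep[length(keep)] <- TRUE
  event_log(data.frame(time_s = tt[keep], value = x$values[keep]),
            annotator_id = x$annotator_id, stimulus_id = x$stimulus_id,
            v_min = -max(abs(range(x$values)), 100),
            v_max = max(abs(range(x$values)), 100))
}

#' Remove events inside a window, creating a data lapse
#'
#' Deletes all logged events with `at_s < time <= at_s + duration_s`. If the
#' values on either side of the resulting gap differ, resampling flags the
#' interior grid points missing.
#'
#' @param log an [event_log].
#' @param at_s,duration_s window start and length in seconds.
#' @return The thinned [event_log].
#' @export
inject_lapse <- function(log, at_s, duration_s) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events
  drop <- ev$time_s > at_s & ev$time_s <= at_s + duration_s
  if (sum(!drop) < 2) stop("lapse would remove almost all events")
  event_log(ev[!drop, , drop = FALSE], annotator_id = log$annotator_id,
            stimulus_id = log$stimulus_id, v_min = log$v_min, v_max = log$v_max)
}

#' True construct level of each flat region
#'
#' The mean of the latent signal over the region window — what a perfect
#' judge of the excerpt would perceive.
#'
#' @param regions a `flat_regions` data.frame (possibly several stimuli).
#' @param signals a `true_signal` or named list of them (by stimulus id).
#' @return named numeric vector of levels by region id.
#' @export
region_true_levels <- function(regions, signals) {
  if (inherits(signals, "true_signal")) {
    signals <- stats::setNames(list(signals), signals$stimulus_id)
  }
  lv <- vapply(seq_len(nrow(regions)), function(i) {
    s <- signals[[regions$stimulus_id[i]]]
    if (is.null(s)) stop(sprintf("no true signal for stimulus %s",
                                 regions$stimulus_id[i]))
    mean(s$values[regions$start[i]:(regions$end[i] - 1L)])
  }, numeric(1))
  stats::setNames(lv, regions$region_id)
}

#' Pairwise comparison oracle
#'
#' Answers "which region is lower" from true levels: the truly lower region
#' is chosen with probability `1 / (1 + exp(-beta * |level difference|))`.
#' `beta = Inf` gives the noiseless oracle; `beta = 0` answers at chance.
#' Pairs with exactly equal levels are answered uniformly at random and
#' flagged.
#'
#' @param pairs data.frame with columns `region_a`, `region_b`.
#' @param levels named numeric vector of true levels (see
#'   [region_true_levels()]).
#' @param beta noise scale (>= 0 or `Inf`).
#' @param seed integer seed.
#' @return `pairs` with `lower`, `source = "oracle"`, and `flagged` columns.
#' @export
oracle_compare <- function(pairs, levels, beta = Inf, seed = 1) {
  stopifnot(beta >= 0)
  la <- levels[pairs$region_a]
  lb <- levels[pairs$region_b]
  if (anyNA(la) || anyNA(lb)) stop("every compared region needs a true level")
  dl <- abs(la - lb)
  p_correct <- ifelse(is.infinite(beta), 1, 1 / (1 + exp(-beta * dl)))
  .with_seed(seed, {
    u <- runif(nrow(pairs))
    tie <- dl == 0
    truly_lower <- ifelse(la <= lb, pairs$region_a, pairs$region_b)
    other <- ifelse(la <= lb, pairs$region_b, pairs$region_a)
    lower <- ifelse(u < p_correct, truly_lower, other)
    if (any(tie)) {
      flip <- runif(sum(tie)) < 0.5
      lower[tie] <- ifelse(flip, pairs$region_a[tie], pairs$region_b[tie])
    }
    cbind(pairs, data.frame(lower = lower, source = "oracle", flagged = tie,
                            stringsAsFactors = FALSE))
  })
}

#' Comparison source backed by the oracle
#'
#' Wraps [oracle_compare()] as a `comparison_source` for
#' [run_comparison_loop()]; each call advances an internal counter so
#' repeated batches stay deterministic under one seed without reusing draws.
#'
#' @param levels named true levels by region id.
#' @param beta oracle noise scale.
#' @param seed integer seed.
#' @return `function(pairs)` returning answered pairs.
#' @export
make_oracle_source <- function(levels, beta = Inf, seed = 1) {
  calls <- 0L
  function(pairs) {
    calls <<- calls + 1L
    oracle_compare(pairs, levels, beta = beta, seed = seed + calls)
  }
}

#' Simulate a full annotation study of one stimulus
#'
#' Generates a latent signal and a panel of annotators (optionally with
#' planted adversarial members) and simulates every annotation.
#'
#' @param n_annotators,n_adversarial panel composition.
#' @param n_runs,grid_len,level_range,rate_hz signal parameters.
#' @param seed integer seed driving signal, panel, and annotation noise.
#' @param stimulus_id identifier.
#' @param ... panel overrides passed to [sample_annotator_panel()].
#' @return list with `signal`, `annotators`, `annotations`.
#' @export
simulate_study <- function(n_annotators = 8, n_adversarial = 0, n_runs = 7,
                           grid_len = 120, level_range = c(0, 1), rate_hz = 1,
                           seed = 1, stimulus_id = "s1", ...) {
  signal <- generate_true_signal(n_runs, grid_len, level_range = level_range,
                                 seed = seed, rate_hz = rate_hz,
                                 stimulus_id = stimulus_id)
  annotators <- sample_annotator_panel(n_annotators, n_adversarial,
                                       seed = seed, ...)
  annotations <- lapply(seq_along(annotators), function(i) {
    simulate_annotation(signal, annotators[[i]], seed = seed * 131 + i)
  })
  list(signal = signal, annotators = annotators, annotations = annotations)
}
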