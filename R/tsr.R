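# Trapezoidal segmented regression (TSR) and trend codes (TSS).
#
# A TSR is a continuous piecewise-linear approximation whose segments
# strictly alternate between zero slope (flat) and free slope, with
# breakpoints restricted to sample positions. Trends read off the fit — a
# per-sample code in {-1, 0, +1} — are the only information carried forward
# by the fusion pipeline, in keeping with the principle that annotators
# capture trends reliably and values unreliably.

#' Fit a trapezoidal segmented regression
#'
#' Least-squares fit of a continuous, alternately flat/sloped piecewise-linear
#' signal with exactly `T` segments and breakpoints at sample positions. Both
#' parities (first segment flat or sloped) are searched and the better kept;
#' `T = 1` is the degenerate one-segment member of the class, the
#' least-squares constant. Small search spaces (at most `exact_limit`
#' breakpoint placements) are solved by exhaustive enumeration with exact
#' level solves; larger ones by a dynamic program over discretized breakpoint
#' values followed by an exact least-squares re-solve of the levels and
#' coordinate-descent refinement of the breakpoint positions.
#'
#' @param values numeric samples without missing values (fit per contiguous
#'   block upstream, see [tss_for_values()]).
#' @param T number of segments, `1 <= T <= length(values) - 1`.
#' @param n_levels size of the discretized value grid used by the large-case
#'   dynamic program.
#' @param exact_limit maximum number of enumerated placements for the exact
#'   engine.
#' @return A `tsr_model`: list with `breakpoints` (1-based sample indices,
#'   first = 1, last = `length(values)`), `values` (signal value at each
#'   breakpoint), `segment_kinds` (`"flat"`/`"sloped"`), `T`, `sse`, `n`,
#'   and `fitted`.
#' @export
fit_tsr <- function(values, T, n_levels = 25, exact_limit = 20000) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("fit_tsr requires complete samples; fit per contiguous block")
  n <- length(values)
  T <- as.integer(T)
  if (T < 1) stop("T must be at least 1")
  if (n < T + 1)
    stop(sprintf("segment budget too large: T = %d needs at least %d samples, got %d",
                 T, T + 1, n))
  rng <- range(values)
  levels <- if (diff(rng) == 0) rng[1] else seq(rng[1], rng[2], length.out = n_levels)
  fit <- .tsr_fit_cpp(values, T, levels, exact_limit)
  bp <- fit$breakpoints + 1L # to 1-based
  kinds <- vapply(seq_len(T), function(j) {
    flat_first <- fit$parity == 0
    if ((j %% 2 == 1) == flat_first) "flat" else "sloped"
  }, character(1))
  model <- structure(
    list(breakpoints = bp, values = fit$values, segment_kinds = kinds,
         T = T, sse = fit$sse, n = n, exact = fit$exact),
    class = "tsr_model")
  model$fitted <- predict_tsr(model)
  model
}

#' @export
print.tsr_model <- function(x, ...) {
  cat(sprintf("<tsr_model> T = %d segments (%s-first), sse = %.6g over %d samples\n",
              x$T, x$segment_kinds[1], x$sse, x$n))
  cat("breakpoints:", paste(x$breakpoints, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a TSR model on its sample grid
#'
#' Because flat segments carry equal values at both of their breakpoints, the
#' whole model is the linear interpolant of its (breakpoint, value) pairs.
#'
#' @param model a `tsr_model`.
#' @param at sample indices to evaluate (default: the full grid `1:n`).
#' @return numeric vector of fitted values.
#' @export
predict_tsr <- function(model, at = seq_len(model$n)) {
  stopifnot(inherits(model, "tsr_model"))
  approx(model$breakpoints, model$values, xout = at, rule = 2)$y
}

#' Serialize / restore a TSR model as JSON
#'
#' @param model a `tsr_model`.
#' @param path file path.
#' @return `path` invisibly; `read_tsr` returns the restored `tsr_model`.
#' @export
write_tsr <- function(model, path) {
  stopifnot(inherits(model, "tsr_model"))
  keep <- model[c("breakpoints", "values", "segment_kinds", "T", "sse", "n")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tsr
#' @export
read_tsr <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(
    list(breakpoints = as.integer(x$breakpoints), values = as.numeric(x$values),
         segment_kinds = as.character(x$segment_kinds), T = as.integer(x$T),
         sse = as.numeric(x$sse), n = as.integer(x$n)),
    class = "tsr_model")
  model$fitted <- predict_tsr(model)
  model
}

#' Estimate an initial segment budget from the signal shape
#'
#' Automated stand-in for counting peaks, valleys, plateaus and trends by
#' inspection: smooth the samples with a centered moving average, take first
#' differences, assign each step a sign (zero when its magnitude is below
#' `flat_frac` of the smoothed value range), demote trend runs whose total
#' value change is below `merge_frac` of the range to "no change" (a human
#' counting macro structure ignores small wiggles), and count the maximal
#' runs of equal sign that remain. A manual count can always be supplied
#' downstream instead.
#'
#' @param values numeric samples (>= 4, no missing values).
#' @param smooth_w moving-average window in samples (odd; default 5).
#' @param flat_frac fraction of the value range below which a single step
#'   counts as "no change" (default 0.005; slopes flatter than this over the
#'   whole range would take more than 200 samples to traverse it).
#' @param merge_frac fraction of the value range below which a whole trend
#'   run counts as insignificant (default 0.05).
#' @return integer run count, clipped to `[1, length(values) - 1]`.
#' @export
estimate_T_hat <- function(values, smooth_w = 5, flat_frac = 0.005,
                           merge_frac = 0.05) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("estimate_T_hat requires complete samples")
  n <- length(values)
  if (n < 4) stop("estimate_T_hat needs at least 4 samples")
  smooth_w <- max(1L, as.integer(smooth_w))
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - smooth_w %/% 2); hi <- min(n, i + smooth_w %/% 2)
    mean(values[lo:hi])
  }, numeric(1))
  d <- diff(sm)
  rng <- diff(range(sm))
  if (rng == 0) return(1L)
  s <- .sgn_tol(d, flat_frac * rng)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  total <- vapply(seq_along(ends), function(k) sum(d[starts[k]:ends[k]]),
                  numeric(1))
  r$values[abs(total) < merge_frac * rng] <- 0
  runs <- rle(inverse.rle(r))
  max(1L, min(n - 1L, length(runs$lengths)))
}

# Scan a profile upward from index `from`: the first index whose value is >=
# its successor (a plateau start or a peak); the last index counts as a local
# maximum, so a monotone profile selects its endpoint.
.first_local_max <- function(profile, from = 1L) {
  n <- length(profile)
  for (i in from:n) {
    if (i == n || profile[i] >= profile[i + 1]) return(i)
  }
  n
}

# The documented two-stage scan: first local max of the SDA profile from the
# low end, then the next local max of the tau profile from that index upward.
.select_from_profiles <- function(candidates, sda_profile, tau_profile) {
  i_sda <- .first_local_max(sda_profile, 1L)
  i_tau <- .first_local_max(tau_profile, i_sda)
  list(index = i_tau, T_prime = candidates[i_tau], sda_index = i_sda)
}

#' Select the segment budget by the SDA-then-tau heuristic
#'
#' Candidate budgets are `floor(4/5 * T_hat) ... ceiling(6/5 * T_hat)`
#' (floored at 1 and capped at the representable maximum). For each candidate
#' a TSR is fitted and its agreement with the raw samples measured by SDA and
#' Kendall's tau-b (ties on flat segments are expected, hence tau-b). The
#' budget is chosen by scanning upward to the first local maximum of the SDA
#' profile, then onward to the next local maximum of the tau profile; on a
#' monotone profile the scan end counts as the local maximum.
#'
#' @param values numeric samples without missing values.
#' @param T_hat initial budget estimate (e.g., from [estimate_T_hat()] or
#'   manual inspection).
#' @param zero_tol passed to [sda()].
#' @param ... passed to [fit_tsr()].
#' @return A `segment_budget`: list with `T_hat`, `candidates`, `T_prime`,
#'   `sda_profile`, `tau_profile`, and `models` (one `tsr_model` per
#'   candidate).
#' @export
select_segment_count <- function(values, T_hat, zero_tol = 1e-9, ...) {
  values <- as.numeric(values)
  T_hat <- as.integer(T_hat)
  if (T_hat < 1) stop("T_hat must be at least 1")
  n <- length(values)
  lo <- max(1L, as.integer(floor(4 / 5 * T_hat)))
  hi <- as.integer(ceiling(6 / 5 * T_hat))
  hi <- min(hi, n - 1L)
  lo <- min(lo, hi)
  candidates <- lo:hi
  models <- lapply(candidates, function(Tc) fit_tsr(values, Tc, ...))
  sda_profile <- vapply(models, function(m) sda(m$fitted, values, zero_tol = zero_tol),
                        numeric(1))
  tau_profile <- vapply(models, function(m) {
    if (sd(m$fitted) == 0 || sd(values) == 0) return(0)
    cor(m$fitted, values, method = "kendall")
  }, numeric(1))
  sel <- .select_from_profiles(candidates, sda_profile, tau_profile)
  structure(
    list(T_hat = T_hat, candidates = candidates, T_prime = sel$T_prime,
         sda_profile = sda_profile, tau_profile = tau_profile,
         models = models, selected = models[[sel$index]]),
    class = "segment_budget")
}

#' @export
print.segment_budget <- function(x, ...) {
  cat(sprintf("<segment_budget> T_hat = %d, candidates {%s}, selected T' = %d\n",
              x$T_hat, paste(x$candidates, collapse = ", "), x$T_prime))
  invisible(x)
}

#' Trend codes (TSS) of a TSR model
#'
#' Per-sample trend code: 0 on flat segments, the sign of the slope on sloped
#' segments. A boundary sample belongs to the segment starting at it
#' (half-open segments); the final sample belongs to the last segment.
#'
#' @param model a `tsr_model`.
#' @param grid_len length of the code sequence (default: the fitted grid).
#' @param source_id identifier recorded on the result.
#' @return A `tss`: list with integer `codes` over \{-1, 0, 1\} and
#'   `source_id`.
#' @export
to_tss <- function(model, grid_len = model$n, source_id = NA_character_) {
  stopifnot(inherits(model, "tsr_model"))
  if (grid_len < model$n) stop("grid shorter than the fitted model")
  bp <- model$breakpoints
  scale <- max(1, diff(range(model$values)))
  codes <- integer(grid_len)
  for (j in seq_len(model$T)) {
    a <- bp[j]; b <- bp[j + 1]
    idx <- if (j == model$T) a:min(grid_len, model$n) else a:(b - 1)
    if (model$segment_kinds[j] == "flat") {
      codes[idx] <- 0L
    } else {
      slope <- (model$values[j + 1] - model$values[j]) / (b - a)
      codes[idx] <- as.integer(.sgn_tol(slope, 1e-9 * scale))
    }
  }
  structure(list(codes = codes, source_id = source_id), class = "tss")
}

#' @export
print.tss <- function(x, ...) {
  tab <- table(factor(x$codes, levels = c(-1, 0, 1)))
  cat(sprintf("<tss> %d samples (down %d / flat %d / up %d), source %s\n",
              length(x$codes), tab[1], tab[2], tab[3], x$source_id))
  invisible(x)
}

#' TSS of raw samples with missing data
#'
#' Convenience wrapper around the full per-annotation trend chain: the TSR is
#' fitted on the longest contiguous block of non-missing samples (its segment
#' budget chosen by [estimate_T_hat()] and [select_segment_count()] unless
#' `T_hat` is given); samples outside that block receive code 0 and are
#' flagged.
#'
#' @param values numeric samples, `NA` allowed.
#' @param T_hat optional manual initial budget; `NULL` for the automated
#'   estimate.
#' @param source_id identifier recorded on the result.
#' @param ... passed to [select_segment_count()].
#' @return A `tss` with extra fields `block` (1-based `c(start, end)` of the
#'   fitted block), `model`, and `budget`.
#' @export
tss_for_values <- function(values, T_hat = NULL, source_id = NA_character_, ...) {
  values <- as.numeric(values)
  n <- length(values)
  ok <- !is.na(values)
  if (!any(ok)) stop("all samples missing")
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values)
  pick <- good[which.max(r$lengths[good])]
  a <- starts[pick]; b <- ends[pick]
  block <- values[a:b]
  if (is.null(T_hat)) T_hat <- estimate_T_hat(block)
  budget <- select_segment_count(block, T_hat, ...)
  tss_block <- to_tss(budget$selected, source_id = source_id)
  codes <- integer(n)
  codes[a:b] <- tss_block$codes
  structure(list(codes = codes, source_id = source_id, block = c(a, b),
                 model = budget$selected, budget = budget),
            class = "tss")
}
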