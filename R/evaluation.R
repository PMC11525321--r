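# Evaluation: scalar aggregation of ground truths, rank comparison against
# reference ratings, and recovery metrics against simulator truth.

#' Aggregate a ground truth to a scalar
#'
#' @param gt a `ground_truth` (or numeric vector).
#' @param fn one of `"min"`, `"max"`, `"mean"`, `"median"`, `"sum"`.
#' @return scalar over the non-missing samples.
#' @export
aggregate_gt <- function(gt, fn = c("max", "min", "mean", "median", "sum")) {
  fn <- match.arg(fn)
  v <- if (inherits(gt, "ground_truth")) gt$values else as.numeric(gt)
  v <- v[!is.na(v)]
  if (!length(v)) stop("cannot aggregate: all samples missing")
  switch(fn, min = min(v), max = max(v), mean = mean(v),
         median = median(v), sum = sum(v))
}

#' Spearman score of per-stimulus aggregates against reference ratings
#'
#' @param aggregates named numeric vector (by stimulus id).
#' @param ratings named numeric/ordinal reference ratings covering the same
#'   stimuli (e.g., a 1-5 authority rating).
#' @return Spearman rho (average ranks for ties).
#' @export
score_against_ratings <- function(aggregates, ratings) {
  common <- intersect(names(aggregates), names(ratings))
  if (length(common) < 3) stop("need at least 3 stimuli with both values")
  a <- as.numeric(aggregates[common])
  r <- as.numeric(ratings[common])
  if (sd(a) == 0 || sd(r) == 0)
    stop("Spearman correlation undefined for a constant vector")
  cor(a, r, method = "spearman")
}

#' Evaluation report over a set of ground truths
#'
#' Applies every aggregation function per stimulus and, when reference
#' ratings are given, scores each aggregate vector against them by Spearman
#' correlation. When simulator truth is given, also reports per-stimulus
#' Kendall tau and SDA of each ground truth against the latent signal.
#'
#' @param gts named list of `ground_truth` objects (by stimulus id).
#' @param ratings optional named reference ratings.
#' @param truths optional named list of `true_signal` objects.
#' @param zero_tol passed to [sda()] for the truth comparison.
#' @return An `evaluation_report`: list with `aggregates` (stimuli x
#'   functions data.frame), `spearman` (per aggregation function, if rated),
#'   and `recovery` (per stimulus, if truths given).
#' @export
evaluation_report <- function(gts, ratings = NULL, truths = NULL,
                              zero_tol = 1e-9) {
  stopifnot(is.list(gts), length(gts) >= 1)
  fns <- c("min", "max", "mean", "median", "sum")
  agg <- as.data.frame(lapply(fns, function(f)
    vapply(gts, aggregate_gt, numeric(1), fn = f)))
  names(agg) <- fns
  rownames(agg) <- names(gts)
  sp <- NULL
  if (!is.null(ratings)) {
    sp <- vapply(fns, function(f)
      score_against_ratings(stats::setNames(agg[[f]], rownames(agg)), ratings),
      numeric(1))
  }
  rec <- NULL
  if (!is.null(truths)) {
    rec <- do.call(rbind, lapply(names(gts), function(s) {
      tv <- truths[[s]]$values
      gv <- gts[[s]]$values
      data.frame(stimulus_id = s,
                 kendall_tau = if (sd(gv, na.rm = TRUE) == 0) NA_real_
                               else cor(gv, tv, method = "kendall",
                                        use = "complete.obs"),
                 sda = sda(gv, tv, zero_tol = zero_tol))
    }))
  }
  structure(list(aggregates = agg, spearman = sp, recovery = rec),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\naggregates:\n")
  print(round(x$aggregates, 4))
  if (!is.null(x$spearman)) {
    cat("Spearman vs ratings:\n")
    print(round(x$spearman, 4))
  }
  if (!is.null(x$recovery)) {
    cat("recovery vs latent truth:\n")
    print(x$recovery, digits = 4)
  }
  invisible(x)
}
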