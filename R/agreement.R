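# Agreement between annotations: signed differential agreement (SDA), which
# compares the *signs* of successive differences and is therefore invariant to
# any strictly increasing revaluation of either trace, plus the classical
# value-based measures used for reporting and inside the segment-budget
# heuristic.

.values_of <- function(x) {
  if (inherits(x, "annotation")) x$values else as.numeric(x)
}

.sgn_tol <- function(d, zero_tol) {
  s <- sign(d)
  s[abs(d) <= zero_tol] <- 0
  s
}

#' Signed differential agreement (SDA)
#'
#' The normalized sum of per-step agreement between the signs of successive
#' differences of two equally long signals:
#' `SDA = (1/M) * sum_t delta(sgn(x_t - x_{t-1}), sgn(y_t - y_{t-1}))` with
#' `delta(p, q) = +1` if `p == q` and `-1` otherwise. Differences of magnitude
#' at most `zero_tol` have sign 0. Steps touching a missing sample on either
#' signal are excluded and `M` counts only the valid steps. SDA ranges over
#' `[-1, 1]` and equals 1 for any pair related by a strictly increasing value
#' transform.
#'
#' @param x,y [annotation] objects or numeric vectors of equal length (>= 2).
#' @param zero_tol absolute tolerance below which a step counts as "no change".
#' @return SDA in `[-1, 1]`.
#' @export
sda <- function(x, y, zero_tol = 1e-9) {
  xv <- .values_of(x); yv <- .values_of(y)
  if (length(xv) != length(yv))
    stop(sprintf("length mismatch: %d vs %d samples", length(xv), length(yv)))
  if (length(xv) < 2) stop("SDA needs at least 2 samples")
  dx <- diff(xv); dy <- diff(yv)
  ok <- !is.na(dx) & !is.na(dy)
  if (!any(ok)) stop("SDA undefined: no step with all four samples present")
  agree <- .sgn_tol(dx[ok], zero_tol) == .sgn_tol(dy[ok], zero_tol)
  mean(ifelse(agree, 1, -1))
}

#' Pairwise SDA matrix over a set of annotations
#'
#' Each off-diagonal entry is the SDA of one unordered pair, computed once and
#' mirrored. A `pair_aligner` hook (e.g., a banded DTW, see
#' [dtw_align_pair()]) may be applied to each pair before SDA. Pairs with no
#' valid step yield `NA` entries; downstream selection treats those as zero
#' affinity.
#'
#' @param annotations list of [annotation] objects (>= 2) of one stimulus.
#' @param pair_aligner optional `function(x, y)` returning a list of the two
#'   aligned annotations.
#' @param zero_tol passed to [sda()].
#' @return An `agreement_matrix`: a symmetric numeric matrix with unit
#'   diagonal, annotator ids as dimnames, and attribute `metric_name = "sda"`.
#' @export
sda_matrix <- function(annotations, pair_aligner = NULL, zero_tol = 1e-9) {
  stopifnot(is.list(annotations), length(annotations) >= 2)
  n <- length(annotations)
  ids <- vapply(annotations, function(a) a$annotator_id, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      xi <- annotations[[i]]; yj <- annotations[[j]]
      if (!is.null(pair_aligner)) {
        pr <- pair_aligner(xi, yj)
        xi <- pr[[1]]; yj <- pr[[2]]
      }
      v <- tryCatch(sda(xi, yj, zero_tol = zero_tol),
                    error = function(e) NA_real_)
      m[i, j] <- m[j, i] <- v
    }
  }
  structure(m, metric_name = "sda", class = c("agreement_matrix", "matrix", "array"))
}

#' @export
print.agreement_matrix <- function(x, ...) {
  cat(sprintf("<agreement_matrix> metric %s, %d annotators\n",
              attr(x, "metric_name"), nrow(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Classical agreement and reliability measures
#'
#' Standard value-based measures over a set of annotations, used for reporting
#' and (Kendall's tau) inside the segment-budget heuristic. Rows with any
#' missing value are dropped (complete cases). Correlation metrics on more
#' than two annotations report the mean over unordered pairs.
#'
#' @param annotations list of [annotation] objects or a numeric matrix with
#'   one column per annotator.
#' @param metric one of `"kendall_tau"` (tau-b), `"pearson"`, `"spearman"`,
#'   `"cronbach_alpha"`, `"icc_3k"`, `"krippendorff_alpha_interval"`.
#' @return A single numeric value.
#' @export
classical_agreement <- function(annotations,
                                metric = c("kendall_tau", "pearson", "spearman",
                                           "cronbach_alpha", "icc_3k",
                                           "krippendorff_alpha_interval")) {
  metric <- match.arg(metric)
  if (is.list(annotations) && !is.data.frame(annotations)) {
    mat <- vapply(annotations, .values_of, numeric(length(.values_of(annotations[[1]]))))
  } else {
    mat <- as.matrix(annotations)
  }
  if (ncol(mat) < 2) stop("classical agreement needs at least 2 annotations")
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 2) stop("fewer than 2 complete-case samples")
  switch(metric,
    kendall_tau = .mean_pairwise_cor(mat, "kendall"),
    pearson = .mean_pairwise_cor(mat, "pearson"),
    spearman = .mean_pairwise_cor(mat, "spearman"),
    cronbach_alpha = .cronbach_alpha(mat),
    icc_3k = .icc_3k(mat),
    krippendorff_alpha_interval = .kripp_alpha_interval(mat))
}

.mean_pairwise_cor <- function(mat, method) {
  if (any(apply(mat, 2, sd) == 0))
    stop(sprintf("%s correlation undefined for constant input", method))
  cm <- cor(mat, method = method)
  mean(cm[upper.tri(cm)])
}

# alpha = k/(k-1) * (1 - sum of rater variances / variance of the sum)
.cronbach_alpha <- function(mat) {
  k <- ncol(mat)
  v_total <- var(rowSums(mat))
  if (v_total == 0) stop("Cronbach's alpha undefined: total score is constant")
  k / (k - 1) * (1 - sum(apply(mat, 2, var)) / v_total)
}

# ICC(3,k): two-way mixed model, consistency, average of k raters:
# (MS_rows - MS_error) / MS_rows, rows = time samples, columns = raters.
.icc_3k <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat); grand <- mean(mat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows == 0) stop("ICC(3,k) undefined: no between-sample variance")
  (ms_rows - ms_err) / ms_rows
}

# Krippendorff's alpha with the interval metric delta^2 = (v - v')^2.
# Units are time samples; only units rated by >= 2 annotators contribute to
# observed disagreement. alpha = 1 - Do/De with Do the pairable within-unit
# mean squared difference and De the pooled between-value mean squared
# difference.
.kripp_alpha_interval <- function(mat) {
  # mat: samples x raters, may contain NA (complete cases already applied by
  # caller for the generic path; handle NA anyway so the formula stands alone)
  units <- lapply(seq_len(nrow(mat)), function(i) mat[i, !is.na(mat[i, ])])
  units <- units[vapply(units, length, integer(1)) >= 2]
  if (!length(units)) stop("Krippendorff's alpha undefined: no pairable unit")
  n_u <- vapply(units, length, integer(1))
  n_tot <- sum(n_u)
  do_num <- vapply(units, function(v) {
    m <- length(v)
    sum(outer(v, v, function(a, b) (a - b)^2)) / (m - 1)
  }, numeric(1))
  Do <- sum(do_num) / n_tot
  pooled <- unlist(units)
  De <- sum(outer(pooled, pooled, function(a, b) (a - b)^2)) /
    (n_tot * (n_tot - 1))
  if (De == 0) stop("Krippendorff's alpha undefined: all pairable values equal")
  1 - Do / De
}
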