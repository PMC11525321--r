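# Temporal alignment of annotation pairs/sets and selection of the inlier
# consensus. Alignment uses dynamic time warping with a symmetric step
# pattern (diagonal weight 2) under a Sakoe-Chiba band that caps temporal
# distortion; selection bipartitions the SDA affinity with normalized
# spectral clustering and keeps the cluster with the highest mean SDA.

# Evaluate expr with a private RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Banded DTW of `query` onto `ref`. Symmetric step pattern
# (1,1) weight 2, (1,0) and (0,1) weight 1; local cost = squared difference;
# samples missing on either side contribute zero local cost. Returns the
# query warped onto the reference grid (path-mean composition) and the path.
.dtw_warp <- function(ref, query, band) {
  n <- length(ref); m <- length(query)
  if (abs(n - m) > band)
    stop(sprintf("alignment infeasible: length difference %d exceeds band of %d samples",
                 abs(n - m), band))
  big <- .Machine$double.xmax / 4
  D <- matrix(big, n + 1, m + 1)
  D[1, 1] <- 0
  lc <- function(i, j) {
    d <- (ref[i] - query[j])^2
    if (is.na(d)) 0 else d
  }
  for (i in seq_len(n)) {
    jlo <- max(1L, i - band); jhi <- min(m, i + band)
    for (j in jlo:jhi) {
      d <- lc(i, j)
      D[i + 1, j + 1] <- min(D[i, j] + 2 * d, D[i, j + 1] + d, D[i + 1, j] + d)
    }
  }
  if (D[n + 1, m + 1] >= big)
    stop("alignment infeasible: no path within the band")
  # backtrack
  i <- n; j <- m
  pi_ <- integer(n + m); pj <- integer(n + m); k <- 0L
  while (i >= 1 && j >= 1) {
    k <- k + 1L; pi_[k] <- i; pj[k] <- j
    if (i == 1 && j == 1) break
    d <- lc(i, j)
    steps <- c(if (i > 1 && j > 1) D[i - 1, j - 1] + 2 * d else big,
               if (i > 1) D[i - 1, j] + d else big,
               if (j > 1) D[i, j - 1] + d else big)
    mv <- which.min(steps)
    if (mv == 1) { i <- i - 1; j <- j - 1 }
    else if (mv == 2) i <- i - 1
    else j <- j - 1
  }
  path <- data.frame(ref_index = rev(pi_[1:k]), query_index = rev(pj[1:k]))
  warped <- vapply(seq_len(n), function(ii) {
    q <- query[path$query_index[path$ref_index == ii]]
    if (all(is.na(q))) NA_real_ else mean(q, na.rm = TRUE)
  }, numeric(1))
  list(warped = warped, path = path, distance = D[n + 1, m + 1])
}

#' Align one annotation pair by banded DTW
#'
#' One annotation of the pair is chosen uniformly at random (under `seed`) as
#' the reference; the other is warped onto the reference grid by dynamic time
#' warping with a symmetric step pattern and a Sakoe-Chiba band limiting the
#' temporal distortion to `band_s` seconds. Missing samples contribute zero
#' local cost; an annotation with more than 20% missing samples raises a
#' warning.
#'
#' @param x,y [annotation] objects of the same stimulus and rate.
#' @param band_s maximum temporal distortion in seconds (default 5, at least
#'   one sampling period).
#' @param seed integer seed governing the random reference choice.
#' @return list with elements `x`, `y` (both on the reference grid, reference
#'   unchanged), `reference_id`, `path`, and `band_s`.
#' @export
dtw_align_pair <- function(x, y, band_s = 5, seed = 1) {
  stopifnot(inherits(x, "annotation"), inherits(y, "annotation"))
  if (x$rate_hz != y$rate_hz) stop("annotations must share a sampling rate")
  if (band_s < x$delta) stop("band_s must be at least one sampling period")
  for (a in list(x, y))
    if (mean(is.na(a$values)) > 0.2)
      warning(sprintf("annotation %s has more than 20%% missing samples",
                      a$annotator_id))
  band <- max(1L, as.integer(round(band_s * x$rate_hz)))
  ref_is_x <- .with_seed(seed, runif(1) < 0.5)
  ref <- if (ref_is_x) x else y
  qry <- if (ref_is_x) y else x
  w <- .dtw_warp(ref$values, qry$values, band)
  warped <- annotation(w$warped, rate_hz = qry$rate_hz,
                       annotator_id = qry$annotator_id,
                       stimulus_id = qry$stimulus_id, t0 = ref$t0)
  out <- if (ref_is_x) list(x = ref, y = warped) else list(x = warped, y = ref)
  out$reference_id <- ref$annotator_id
  out$path <- w$path
  out$band_s <- band_s
  out
}

# Normalized spectral bipartition (Ng-Jordan-Weiss) of a nonnegative affinity
# matrix; deterministic under seed via seeded k-means with 10 restarts.
.spectral_bipartition <- function(W, seed) {
  n <- nrow(W)
  d <- rowSums(W)
  d[d <= 0] <- 1e-12
  S <- W / sqrt(d %o% d)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  U <- ev$vectors[, 1:2, drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  norms[norms == 0] <- 1
  U <- U / norms
  km <- .with_seed(seed, kmeans(U, centers = 2, nstart = 10))
  km$cluster
}

#' Select the inlier consensus among annotations
#'
#' Builds a pairwise SDA affinity (each pair DTW-aligned first, with a
#' per-pair random reference derived from `seed`), transforms it to
#' `(SDA + 1) / 2`, and bipartitions it with two-class normalized spectral
#' clustering. The cluster whose members have the highest mean SDA against
#' all other annotations becomes the inlier group (a coherent minority percept
#' agrees internally but not with the majority, so the consensus side wins). With three or fewer annotations (where a bipartition is
#' meaningless) or when clustering yields an empty/singleton group at that
#' size, all annotations are inliers. Undefined SDA entries are treated as
#' zero affinity.
#'
#' @param annotations list of >= 3 [annotation] objects of one stimulus.
#' @param band_s DTW band in seconds.
#' @param seed integer seed (reference choices and k-means restarts).
#' @param zero_tol passed to [sda()].
#' @return A `selection_result`: list with `inlier_ids`, `outlier_ids`,
#'   `cluster_mean_sda` (length-2, inlier cluster first), `sda` (the pairwise
#'   matrix), and `assignments`.
#' @export
select_inliers <- function(annotations, band_s = 5, seed = 1, zero_tol = 1e-9) {
  stopifnot(is.list(annotations), length(annotations) >= 3)
  n <- length(annotations)
  pair_counter <- 0L
  aligner <- function(a, b) {
    pair_counter <<- pair_counter + 1L
    pr <- dtw_align_pair(a, b, band_s = band_s, seed = seed + pair_counter)
    list(pr$x, pr$y)
  }
  M <- sda_matrix(annotations, pair_aligner = aligner, zero_tol = zero_tol)
  ids <- rownames(M)
  if (all(is.na(M[upper.tri(M)])))
    stop("selection impossible: all pairwise SDA values are undefined")
  A <- (unclass(M) + 1) / 2
  A[is.na(A)] <- 0
  cl <- .spectral_bipartition(A, seed = seed)
  # Cluster score: its members' mean SDA against every other annotation (not
  # only cluster-mates). A small coherent minority — e.g., two annotators of
  # an inverted percept — agrees internally but disagrees with everyone else,
  # so the consensus cluster wins.
  off <- unclass(M)
  diag(off) <- NA
  mean_sda <- vapply(1:2, function(k) {
    mean(off[cl == k, , drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  if (n <= 3 && min(table(factor(cl, levels = 1:2))) <= 1) {
    inl <- seq_len(n)
  } else {
    inl <- which(cl == which.max(mean_sda))
  }
  structure(
    list(inlier_ids = ids[inl],
         outlier_ids = setdiff(ids, ids[inl]),
         cluster_mean_sda = sort(mean_sda, decreasing = TRUE),
         sda = M,
         assignments = stats::setNames(cl, ids)),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d inliers (%s), %d outliers (%s)\n",
              length(x$inlier_ids), paste(x$inlier_ids, collapse = ", "),
              length(x$outlier_ids),
              if (length(x$outlier_ids)) paste(x$outlier_ids, collapse = ", ") else "-"))
  invisible(x)
}

#' Align inlier annotations to a common reference
#'
#' The inlier with the largest mean SDA agreement to the others becomes the
#' reference; every other inlier is DTW-warped onto its grid within `band_s`.
#'
#' @param inliers list of >= 2 [annotation] objects.
#' @param band_s DTW band in seconds.
#' @param sda_mat optional precomputed pairwise SDA matrix over `inliers`
#'   (e.g., from [select_inliers()]); computed without alignment when absent.
#' @param zero_tol passed to [sda()].
#' @return An `alignment_result`: list with `reference_id`, `annotations`
#'   (all on the reference grid, reference first), `warp_paths`, `band_s`.
#' @export
align_inliers <- function(inliers, band_s = 5, sda_mat = NULL, zero_tol = 1e-9) {
  stopifnot(is.list(inliers), length(inliers) >= 2)
  ids <- vapply(inliers, function(a) a$annotator_id, character(1))
  if (is.null(sda_mat)) sda_mat <- sda_matrix(inliers, zero_tol = zero_tol)
  idx <- match(ids, rownames(sda_mat))
  if (anyNA(idx)) stop("sda_mat ids do not cover the inlier set")
  Ms <- unclass(sda_mat)[idx, idx, drop = FALSE]
  diag(Ms) <- NA
  mean_agree <- rowMeans(Ms, na.rm = TRUE)
  ref_i <- which.max(mean_agree)
  ref <- inliers[[ref_i]]
  band <- max(1L, as.integer(round(band_s * ref$rate_hz)))
  warped <- list(ref)
  paths <- list(NULL)
  for (k in seq_along(inliers)[-ref_i]) {
    w <- .dtw_warp(ref$values, inliers[[k]]$values, band)
    warped <- c(warped, list(annotation(w$warped, rate_hz = ref$rate_hz,
                                        annotator_id = inliers[[k]]$annotator_id,
                                        stimulus_id = inliers[[k]]$stimulus_id,
                                        t0 = ref$t0)))
    paths <- c(paths, list(w$path))
  }
  structure(
    list(reference_id = ref$annotator_id, annotations = warped,
         warp_paths = paths, band_s = band_s),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d annotations on reference %s (band %g s)\n",
              length(x$annotations), x$reference_id, x$band_s))
  invisible(x)
}

# Mutual information between two numeric vectors after equal-width binning.
# Returns NA when either marginal is degenerate (a single occupied bin).
.binned_mi <- function(a, b, n_bins = 16) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) return(NA_real_)
  cut1 <- function(v) {
    r <- range(v)
    if (diff(r) == 0) return(NULL)
    findInterval(v, seq(r[1], r[2], length.out = n_bins + 1),
                 rightmost.closed = TRUE, all.inside = TRUE)
  }
  ia <- cut1(a); ib <- cut1(b)
  if (is.null(ia) || is.null(ib)) return(NA_real_)
  jt <- table(ia, ib) / length(a)
  pa <- rowSums(jt); pb <- colSums(jt)
  nz <- jt > 0
  sum(jt[nz] * log(jt[nz] / (pa[row(jt)[nz]] * pb[col(jt)[nz]])))
}

#' Uniform temporal shift alignment by mutual information
#'
#' An alternative to DTW: each annotation receives one integer-sample shift,
#' chosen by coordinate ascent to maximize the mean pairwise mutual
#' information between the shifted traces (values discretized into
#' `n_bins` equal-width bins). Failure — flat or otherwise degenerate traces
#' for which MI is undefined — is a legitimate outcome and reported via the
#' `success` flag; `improved` records whether any nonzero shift beat the
#' zero-shift objective.
#'
#' @param annotations list of >= 2 [annotation] objects on a common grid.
#' @param max_shift_s maximum |shift| in seconds.
#' @param n_bins number of equal-width value bins for the MI estimate.
#' @return list with `success`, `improved`, `shifts` (named, in samples),
#'   `objective`, and the shifted `annotations` (NA-padded).
#' @export
uniform_shift_align <- function(annotations, max_shift_s = 5, n_bins = 16) {
  stopifnot(is.list(annotations), length(annotations) >= 2)
  rate <- annotations[[1]]$rate_hz
  K <- max(1L, as.integer(round(max_shift_s * rate)))
  ids <- vapply(annotations, function(a) a$annotator_id, character(1))
  vals <- lapply(annotations, .values_of)
  n <- length(vals[[1]])
  shift_one <- function(v, s) {
    if (s == 0) return(v)
    if (s > 0) c(rep(NA_real_, s), v[1:(n - s)])
    else c(v[(1 - s):n], rep(NA_real_, -s))
  }
  objective <- function(shifts) {
    sv <- Map(shift_one, vals, shifts)
    prs <- combn(length(sv), 2)
    mis <- apply(prs, 2, function(p) .binned_mi(sv[[p[1]]], sv[[p[2]]], n_bins))
    if (all(is.na(mis))) NA_real_ else mean(mis, na.rm = TRUE)
  }
  shifts <- rep(0L, length(vals))
  base <- objective(shifts)
  if (is.na(base))
    return(list(success = FALSE, improved = FALSE, shifts = stats::setNames(shifts, ids),
                objective = NA_real_, annotations = annotations))
  cur <- base
  for (sweep in 1:10) {
    changed <- FALSE
    for (i in seq_along(vals)) {
      cand <- vapply(-K:K, function(s) {
        sh <- shifts; sh[i] <- s
        objective(sh)
      }, numeric(1))
      best <- which.max(cand)
      if (!is.na(cand[best]) && cand[best] > cur + 1e-12) {
        shifts[i] <- (-K:K)[best]
        cur <- cand[best]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  shifted <- Map(function(a, s) {
    annotation(shift_one(.values_of(a), s), rate_hz = a$rate_hz,
               annotator_id = a$annotator_id, stimulus_id = a$stimulus_id,
               t0 = a$t0)
  }, annotations, shifts)
  list(success = TRUE, improved = cur > base + 1e-12,
       shifts = stats::setNames(as.integer(shifts), ids),
       objective = cur, annotations = shifted)
}
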