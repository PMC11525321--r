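# Ordinal fusion: merge per-annotator trend codes by majority vote, extract
# flat regions (stimulus excerpts of approximately constant construct value),
# turn pairwise "which is lower" judgements into dummy-reference triplets,
# embed the regions on a single construct axis with 1-D t-STE, and
# reconstruct a trapezoidal ground truth. Also provides the sample-wise
# averaging baseline.

#' Merge trend codes by majority vote
#'
#' Per-sample plurality over \{-1, 0, +1\}; ties (including two-way ties for
#' the top count) resolve to 0, the conservative choice that feeds the
#' region-level ordinal correction rather than asserting a trend.
#'
#' @param tss_list list of `tss` objects (equal lengths, >= 1).
#' @return A `merged_tss`: list with `codes` and per-sample `vote_margins`
#'   (top count minus runner-up count; 0 on a tie).
#' @export
trend_vote <- function(tss_list) {
  stopifnot(is.list(tss_list), length(tss_list) >= 1)
  lens <- vapply(tss_list, function(x) length(x$codes), integer(1))
  if (length(unique(lens)) != 1)
    stop(sprintf("TSS length mismatch: %s", paste(unique(lens), collapse = " vs ")))
  M <- vapply(tss_list, function(x) as.integer(x$codes), integer(lens[1]))
  M <- matrix(M, nrow = lens[1])
  codes <- integer(nrow(M))
  margins <- integer(nrow(M))
  for (i in seq_len(nrow(M))) {
    counts <- tabulate(M[i, ] + 2L, nbins = 3L) # -1, 0, +1
    ord <- order(counts, decreasing = TRUE)
    if (counts[ord[1]] == counts[ord[2]]) {
      codes[i] <- 0L
      margins[i] <- 0L
    } else {
      codes[i] <- c(-1L, 0L, 1L)[ord[1]]
      margins[i] <- counts[ord[1]] - counts[ord[2]]
    }
  }
  structure(list(codes = codes, vote_margins = margins), class = "merged_tss")
}

#' Extract flat regions from a merged TSS
#'
#' Maximal all-zero runs of the merged trend codes, kept when at least
#' `min_len_samples` long. Windows are half-open in 1-based sample indices:
#' `[start, end)` covers samples `start .. end - 1`.
#'
#' @param merged a `merged_tss` (or any list with integer `codes`).
#' @param min_len_samples minimum region length in samples (default 2: a
#'   one-sample excerpt cannot be shown as a clip).
#' @param stimulus_id identifier stamped on the regions.
#' @return A `flat_regions` data.frame with columns `region_id`,
#'   `stimulus_id`, `start`, `end`, ordered by `start`; zero rows allowed.
#' @export
extract_flat_regions <- function(merged, min_len_samples = 2, stimulus_id = "s1") {
  codes <- merged$codes
  r <- rle(codes == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len_samples)
  out <- data.frame(
    region_id = if (length(keep)) sprintf("%s_f%02d", stimulus_id, seq_along(keep))
                else character(0),
    stimulus_id = rep(stimulus_id, length(keep)),
    start = starts[keep],
    end = ends[keep] + 1L,
    stringsAsFactors = FALSE)
  class(out) <- c("flat_regions", "data.frame")
  out
}

.canon_pair <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Sample unasked region pairs uniformly
#'
#' Uniform sampling without replacement among the unordered region pairs not
#' yet asked, deterministic under `seed`.
#'
#' @param regions a `flat_regions` data.frame (>= 2 rows).
#' @param n_pairs number of pairs to draw.
#' @param seed integer seed.
#' @param already_asked optional data.frame with columns `region_a`,
#'   `region_b` of previously drawn pairs (order-insensitive).
#' @return data.frame with columns `region_a`, `region_b`.
#' @export
sample_pairs <- function(regions, n_pairs, seed = 1, already_asked = NULL) {
  ids <- regions$region_id
  if (length(ids) < 2) stop("need at least 2 regions to form pairs")
  all_pairs <- t(combn(ids, 2))
  keys <- .canon_pair(all_pairs[, 1], all_pairs[, 2])
  if (!is.null(already_asked) && nrow(already_asked)) {
    asked <- .canon_pair(already_asked$region_a, already_asked$region_b)
    keep <- !(keys %in% asked)
    all_pairs <- all_pairs[keep, , drop = FALSE]
  }
  if (n_pairs > nrow(all_pairs))
    stop(sprintf("pairs exhausted: %d requested but only %d unasked pairs remain",
                 n_pairs, nrow(all_pairs)))
  pick <- .with_seed(seed, sample.int(nrow(all_pairs), n_pairs))
  data.frame(region_a = all_pairs[pick, 1], region_b = all_pairs[pick, 2],
             stringsAsFactors = FALSE)
}

#' Convert pairwise comparisons to dummy-reference triplets
#'
#' Each "which is lower" judgement between regions j and k becomes the
#' triplet (anchor = dummy r, near = the lower one, far = the other),
#' encoding that the lower region is more similar to a hypothetical excerpt
#' of minimal construct value than the other is. Contradictory duplicates
#' are emitted as-is; the embedder absorbs the noise. The triplet count
#' always equals the comparison count.
#'
#' @param comparisons data.frame with columns `region_a`, `region_b`, and
#'   `lower` (the id judged lower of the two).
#' @param dummy_id id for the dummy reference; must differ from all region
#'   ids.
#' @return data.frame with columns `anchor`, `near`, `far`.
#' @export
pairs_to_triplets <- function(comparisons, dummy_id = ".dummy_r") {
  if (nrow(comparisons) == 0)
    return(data.frame(anchor = character(0), near = character(0),
                      far = character(0), stringsAsFactors = FALSE))
  stopifnot(all(c("region_a", "region_b", "lower") %in% names(comparisons)))
  if (dummy_id %in% c(comparisons$region_a, comparisons$region_b))
    stop("dummy_id collides with a region id")
  bad <- comparisons$lower != comparisons$region_a &
    comparisons$lower != comparisons$region_b
  if (any(bad)) stop("'lower' must name one of the two compared regions")
  far <- ifelse(comparisons$lower == comparisons$region_a,
                comparisons$region_b, comparisons$region_a)
  data.frame(anchor = dummy_id, near = comparisons$lower, far = far,
             stringsAsFactors = FALSE)
}

# t-STE negative log-likelihood and gradient for a 1-D configuration, with an
# L2 penalty that keeps the optimum finite: on a satisfiable triplet set the
# unpenalized likelihood increases without bound as the configuration spreads.
# K(d^2) = (1 + d^2/alpha)^(-(alpha+1)/2); p_t = K_an / (K_an + K_af).
.tste_obj_grad <- function(z, ai, ni, fi, alpha, lambda = 0) {
  dan <- z[ai] - z[ni]
  daf <- z[ai] - z[fi]
  kan <- (1 + dan^2 / alpha)^(-(alpha + 1) / 2)
  kaf <- (1 + daf^2 / alpha)^(-(alpha + 1) / 2)
  s <- kan + kaf
  p <- kan / s
  loss <- -sum(log(pmax(p, 1e-300))) + lambda * sum(z^2)
  # d log K_ij / d z_j = -(alpha+1) (z_j - z_i) / (alpha + d_ij^2)
  gan <- -(alpha + 1) * (-dan) / (alpha + dan^2) # d log kan / d z[ni]
  gaf <- -(alpha + 1) * (-daf) / (alpha + daf^2) # d log kaf / d z[fi]
  wan <- 1 - p # weight on d log kan
  waf <- -kaf / s
  g <- numeric(length(z))
  # contributions to near, far, anchor
  g_n <- wan * gan
  g_f <- waf * gaf
  g_a <- wan * (-gan) + waf * (-gaf)
  for (upd in list(list(ni, g_n), list(fi, g_f), list(ai, g_a))) {
    acc <- rowsum(upd[[2]], upd[[1]])
    g[as.integer(rownames(acc))] <- g[as.integer(rownames(acc))] + acc[, 1]
  }
  list(loss = loss, grad = -g + 2 * lambda * z)
}

#' 1-D t-stochastic triplet embedding
#'
#' Places items on a single construct axis by maximizing the t-STE
#' log-likelihood of the triplet constraints with gradient descent (adaptive
#' step size, best of `restarts` seeded initializations; the one-dimensional
#' landscape is multimodal under contradictory triplets, so restarts are
#' deliberately generous). With a dummy
#' reference present the axis is oriented so the dummy takes the minimal
#' value, after which the dummy is dropped from the returned values.
#'
#' @param triplets data.frame with columns `anchor`, `near`, `far` (ids).
#' @param item_ids ids of the items to embed (regions); the dummy id is
#'   appended automatically when it appears in `triplets` but not here.
#' @param dummy_id id of the dummy reference used for orientation, or `NULL`.
#' @param alpha degrees of freedom of the heavy-tailed kernel; 1 is the
#'   appropriate choice in one embedding dimension.
#' @param lambda L2 penalty weight. On a satisfiable triplet set the
#'   unpenalized likelihood has no finite maximizer (the configuration
#'   spreads indefinitely, with geometrically growing gaps), so a small
#'   penalty pins a well-defined, evenly behaved optimum. It is scaled
#'   internally by the triplet-to-item ratio so its effect is comparable
#'   across problem sizes. Positions remain identified only up to monotone
#'   transforms either way.
#' @param seed integer seed for the restarts.
#' @param restarts,max_iter,tol optimization controls.
#' @return An `embedding`: list with `values` (named by item id, dummy
#'   removed), `loss` (negative log-likelihood), `converged`,
#'   `satisfied_fraction` of triplets, and `isolated` (ids in no triplet).
#' @export
tste_embed <- function(triplets, item_ids, dummy_id = ".dummy_r", alpha = 1,
                       lambda = 0.01, seed = 1, restarts = 30,
                       max_iter = 2000, tol = 1e-7) {
  if (nrow(triplets) == 0) stop("no triplets: embedding carries no information")
  ids <- as.character(item_ids)
  if (!is.null(dummy_id) && dummy_id %in% triplets$anchor && !(dummy_id %in% ids))
    ids <- c(ids, dummy_id)
  used <- unique(c(triplets$anchor, triplets$near, triplets$far))
  if (!all(used %in% ids)) stop("triplets reference unknown item ids")
  isolated <- setdiff(ids, used)
  ai <- match(triplets$anchor, ids)
  ni <- match(triplets$near, ids)
  fi <- match(triplets$far, ids)
  n <- length(ids)
  lam_eff <- lambda * max(1, nrow(triplets) / n)
  best <- NULL
  for (r in seq_len(restarts)) {
    z <- .with_seed(seed + r - 1, rnorm(n, sd = 0.1))
    lr <- 0.5
    og <- .tste_obj_grad(z, ai, ni, fi, alpha, lam_eff)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      z_new <- z - lr * og$grad
      og_new <- .tste_obj_grad(z_new, ai, ni, fi, alpha, lam_eff)
      if (og_new$loss <= og$loss) {
        if (abs(og$loss - og_new$loss) < tol * (1 + abs(og$loss)) && lr < 1e4) {
          z <- z_new; og <- og_new
          converged <- TRUE
          break
        }
        z <- z_new; og <- og_new
        lr <- lr * 1.05
      } else {
        lr <- lr / 2
        if (lr < 1e-12) { converged <- TRUE; break }
      }
    }
    if (is.null(best) || og$loss < best$loss)
      best <- list(z = z, loss = og$loss, converged = converged)
  }
  z <- best$z
  if (!is.null(dummy_id) && dummy_id %in% ids) {
    # With dummy-anchored triplets the likelihood depends on each item only
    # through its distance to the dummy, leaving per-item signs free; folding
    # onto that distance is the orientation that places the dummy at the
    # minimum, after which the dummy is dropped.
    di <- match(dummy_id, ids)
    if (all(triplets$anchor == dummy_id)) {
      z <- abs(z - z[di])
    } else if (mean(z[di] > z[-di]) > 0.5) {
      z <- -z # mixed anchors: plain reflection
    }
    sat <- mean(abs(z[ai] - z[ni]) < abs(z[ai] - z[fi]))
    vals <- stats::setNames(z[-di], ids[-di])
  } else {
    sat <- mean(abs(z[ai] - z[ni]) < abs(z[ai] - z[fi]))
    vals <- stats::setNames(z, ids)
  }
  structure(
    list(values = vals, loss = best$loss, converged = best$converged,
         satisfied_fraction = sat, isolated = isolated,
         n_triplets = nrow(triplets)),
    class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d items from %d triplets; %.1f%% satisfied; loss %.4g%s\n",
              length(x$values), x$n_triplets, 100 * x$satisfied_fraction,
              x$loss, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Reconstruct a trapezoidal ground truth from embedded flat regions
#'
#' The ground truth is constant on each flat region at that region's embedded
#' value; samples between consecutive regions are connected by linear
#' interpolation from the last sample of one region to the first sample of
#' the next, and samples before the first / after the last region hold the
#' nearest region's value.
#'
#' @param regions a `flat_regions` data.frame for one stimulus (disjoint,
#'   ordered).
#' @param embedding an `embedding` (or a named numeric vector) providing one
#'   value per region id.
#' @param grid_len length of the output sample grid.
#' @param rate_hz sampling rate recorded on the result.
#' @return A `ground_truth`: list with `stimulus_id`, `values`, `regions`
#'   (with their values), `rate_hz`, and `method = "ordinal"`.
#' @export
reconstruct <- function(regions, embedding, grid_len, rate_hz = 1) {
  if (nrow(regions) == 0) stop("reconstruction impossible: no flat regions")
  vals <- if (inherits(embedding, "embedding")) embedding$values else embedding
  miss <- setdiff(regions$region_id, names(vals))
  if (length(miss))
    stop(sprintf("no embedded value for region(s) %s", paste(miss, collapse = ", ")))
  regions <- regions[order(regions$start), , drop = FALSE]
  if (any(regions$start[-1] < regions$end[-nrow(regions)]))
    stop("regions must be disjoint")
  if (max(regions$end - 1) > grid_len) stop("regions exceed the grid")
  level <- as.numeric(vals[regions$region_id])
  # anchor points: every sample inside a region pinned to its level
  xs <- unlist(Map(function(s, e) s:(e - 1), regions$start, regions$end))
  ys <- rep(level, regions$end - regions$start)
  out <- approx(xs, ys, xout = seq_len(grid_len), rule = 2)$y
  structure(
    list(stimulus_id = regions$stimulus_id[1], values = out,
         regions = cbind(regions, value = level), rate_hz = rate_hz,
         method = "ordinal"),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> stimulus %s (%s): %d samples, %d flat regions\n",
              x$stimulus_id, x$method, length(x$values),
              if (is.null(x$regions)) 0L else nrow(x$regions)))
  invisible(x)
}

#' Sample-wise averaging baseline
#'
#' Per-sample mean over the non-missing values of the aligned inlier
#' annotations; a sample missing everywhere stays missing.
#'
#' @param aligned_inliers list of >= 1 [annotation] objects on one grid, or
#'   an `alignment_result`.
#' @return A `ground_truth` with `method = "baseline_average"`.
#' @export
baseline_average <- function(aligned_inliers) {
  if (inherits(aligned_inliers, "alignment_result"))
    aligned_inliers <- aligned_inliers$annotations
  stopifnot(is.list(aligned_inliers), length(aligned_inliers) >= 1)
  M <- vapply(aligned_inliers, .values_of,
              numeric(length(.values_of(aligned_inliers[[1]]))))
  M <- matrix(M, ncol = length(aligned_inliers))
  vals <- rowMeans(M, na.rm = TRUE)
  vals[!is.finite(vals)] <- NA_real_
  structure(
    list(stimulus_id = aligned_inliers[[1]]$stimulus_id, values = vals,
         regions = NULL, rate_hz = aligned_inliers[[1]]$rate_hz,
         method = "baseline_average"),
    class = "ground_truth")
}

#' Batched comparison collection with a stability stopping rule
#'
#' Draws unasked region pairs in batches, obtains a judgement for each from
#' `comparison_source`, and after every batch embeds all comparisons
#' collected so far and reconstructs a candidate ground truth per stimulus.
#' Collection stops once the Spearman correlation between consecutive
#' candidates reaches `rho_stop` for every stimulus, or when the pairs are
#' exhausted (the final partial batch is used).
#'
#' @param regions a `flat_regions` data.frame (possibly spanning several
#'   stimuli; the embedding is joint, making values comparable across
#'   stimuli).
#' @param comparison_source `function(pairs)` returning the pairs with a
#'   `lower` column appended (a human-answer lookup or a simulator oracle).
#' @param grid_lens named vector/list: grid length per stimulus id.
#' @param batch_size comparisons per batch (the study-scale default is 5000).
#' @param rho_stop Spearman stability threshold (default 0.8, "very strong").
#' @param seed integer seed (pair draws and embedding restarts).
#' @param rate_hz sampling rate stamped on the ground truths.
#' @param ... passed to [tste_embed()].
#' @return list with `ground_truths` (named by stimulus), `embedding`,
#'   `comparisons`, and `history` (one row per batch: comparisons so far and
#'   the minimum between-candidate Spearman rho, `NA` for the first batch).
#' @export
run_comparison_loop <- function(regions, comparison_source, grid_lens,
                                batch_size = 5000, rho_stop = 0.8, seed = 1,
                                rate_hz = 1, ...) {
  stopifnot(nrow(regions) >= 2)
  stim_ids <- unique(regions$stimulus_id)
  grid_lens <- unlist(grid_lens)
  if (!all(stim_ids %in% names(grid_lens)))
    stop("grid_lens must name every stimulus present in regions")
  n_all <- choose(nrow(regions), 2)
  comparisons <- NULL
  prev <- NULL
  history <- list()
  batch <- 0L
  embedding <- NULL
  gts <- NULL
  repeat {
    remaining <- n_all - if (is.null(comparisons)) 0L else nrow(comparisons)
    if (remaining == 0) break
    batch <- batch + 1L
    b <- min(batch_size, remaining)
    pairs <- sample_pairs(regions, b, seed = seed + batch,
                          already_asked = comparisons)
    answered <- comparison_source(pairs)
    if (!("lower" %in% names(answered)))
      stop("comparison_source must append a 'lower' column")
    comparisons <- rbind(comparisons,
                         answered[, c("region_a", "region_b", "lower")])
    triplets <- pairs_to_triplets(comparisons)
    embedding <- tste_embed(triplets, item_ids = regions$region_id,
                            seed = seed, ...)
    gts <- lapply(stim_ids, function(s) {
      reconstruct(regions[regions$stimulus_id == s, , drop = FALSE],
                  embedding, grid_len = grid_lens[[s]], rate_hz = rate_hz)
    })
    names(gts) <- stim_ids
    rho <- NA_real_
    if (!is.null(prev)) {
      rhos <- vapply(stim_ids, function(s) {
        suppressWarnings(cor(gts[[s]]$values, prev[[s]]$values,
                             method = "spearman"))
      }, numeric(1))
      rho <- if (all(is.na(rhos))) NA_real_ else min(rhos, na.rm = TRUE)
    }
    history[[batch]] <- data.frame(batch = batch,
                                   n_comparisons = nrow(comparisons),
                                   rho = rho)
    if (!is.null(prev) && !is.na(rho) && rho >= rho_stop) break
    prev <- gts
  }
  list(ground_truths = gts, embedding = embedding, comparisons = comparisons,
       history = do.call(rbind, history))
}
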