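# End-to-end orchestration: selection and alignment, per-annotation trend
# extraction, trend voting and flat regions per stimulus, then one joint
# comparison/embedding/reconstruction pass across stimuli.

#' Trend consensus for one stimulus
#'
#' Runs annotation selection (spectral bipartition of the DTW-aligned SDA
#' affinity), inlier alignment to the most-agreeing reference, per-inlier
#' trapezoidal segmentation with the SDA-then-tau budget heuristic, trend
#' voting, and flat-region extraction.
#'
#' @param annotations list of >= 3 [annotation] objects of one stimulus.
#' @param band_s DTW band in seconds.
#' @param seed integer seed.
#' @param min_len_samples minimum flat-region length.
#' @param T_hat optional manual segment-budget estimate applied to every
#'   inlier; `NULL` for the automated estimate.
#' @param zero_tol SDA tolerance.
#' @return list with `selection`, `alignment`, `tss_list`, `merged`,
#'   `regions`, `grid_len`, `baseline` (the averaging ground truth), and
#'   `stimulus_id`.
#' @export
fuse_stimulus_trends <- function(annotations, band_s = 5, seed = 1,
                                 min_len_samples = 2, T_hat = NULL,
                                 zero_tol = 1e-9) {
  stimulus_id <- annotations[[1]]$stimulus_id
  sel <- select_inliers(annotations, band_s = band_s, seed = seed,
                        zero_tol = zero_tol)
  ids <- vapply(annotations, function(a) a$annotator_id, character(1))
  inliers <- annotations[ids %in% sel$inlier_ids]
  aln <- align_inliers(inliers, band_s = band_s, sda_mat = sel$sda,
                       zero_tol = zero_tol)
  tss_list <- lapply(aln$annotations, function(a)
    tss_for_values(a$values, T_hat = T_hat, source_id = a$annotator_id))
  merged <- trend_vote(tss_list)
  regions <- extract_flat_regions(merged, min_len_samples = min_len_samples,
                                  stimulus_id = stimulus_id)
  list(selection = sel, alignment = aln, tss_list = tss_list, merged = merged,
       regions = regions, grid_len = length(merged$codes),
       baseline = baseline_average(aln$annotations),
       stimulus_id = stimulus_id)
}

#' Ordinal ground truth across one or more stimuli
#'
#' The full pipeline: per-stimulus trend consensus ([fuse_stimulus_trends()]),
#' then a joint ordinal pass over the pooled flat regions — batched pairwise
#' comparisons, dummy-reference triplets, 1-D t-STE embedding, and
#' trapezoidal reconstruction — which makes ground-truth values comparable
#' across stimuli.
#'
#' @param stim_annotations named list (stimulus id -> list of annotations).
#' @param comparison_source `function(pairs)` answering pairs with a `lower`
#'   column, or `NULL` if `comparison_source_factory` is given.
#' @param comparison_source_factory optional `function(regions)` building the
#'   source once regions are known (e.g., an oracle needing region levels).
#' @param band_s,seed,min_len_samples,T_hat,zero_tol see
#'   [fuse_stimulus_trends()].
#' @param batch_size,rho_stop see [run_comparison_loop()].
#' @param ... passed to [tste_embed()] via the comparison loop.
#' @return An `ogt_result`: list with `ground_truths` and `baselines` (named
#'   by stimulus), `regions`, `embedding`, `history`, `comparisons`, and
#'   `stages` (the per-stimulus trend consensus objects).
#' @export
ordinal_ground_truth <- function(stim_annotations, comparison_source = NULL,
                                 comparison_source_factory = NULL, band_s = 5,
                                 seed = 1, min_len_samples = 2, T_hat = NULL,
                                 zero_tol = 1e-9, batch_size = 5000,
                                 rho_stop = 0.8, ...) {
  stopifnot(is.list(stim_annotations), length(stim_annotations) >= 1)
  if (is.null(names(stim_annotations)))
    names(stim_annotations) <- vapply(stim_annotations,
                                      function(x) x[[1]]$stimulus_id, character(1))
  stages <- lapply(seq_along(stim_annotations), function(k)
    fuse_stimulus_trends(stim_annotations[[k]], band_s = band_s,
                         seed = seed + 1000 * k,
                         min_len_samples = min_len_samples, T_hat = T_hat,
                         zero_tol = zero_tol))
  names(stages) <- names(stim_annotations)
  regions <- do.call(rbind, lapply(stages, `[[`, "regions"))
  rownames(regions) <- NULL
  class(regions) <- c("flat_regions", "data.frame")
  if (nrow(regions) < 2)
    stop("fewer than 2 flat regions across all stimuli; nothing to compare")
  grid_lens <- stats::setNames(vapply(stages, `[[`, integer(1), "grid_len"),
                               names(stages))
  if (is.null(comparison_source)) {
    if (is.null(comparison_source_factory))
      stop("provide comparison_source or comparison_source_factory")
    comparison_source <- comparison_source_factory(regions)
  }
  loop <- run_comparison_loop(regions, comparison_source, grid_lens,
                              batch_size = batch_size, rho_stop = rho_stop,
                              seed = seed,
                              rate_hz = stim_annotations[[1]][[1]]$rate_hz, ...)
  structure(
    list(ground_truths = loop$ground_truths,
         baselines = lapply(stages, `[[`, "baseline"),
         regions = regions, embedding = loop$embedding,
         history = loop$history, comparisons = loop$comparisons,
         stages = stages),
    class = "ogt_result")
}

#' @export
print.ogt_result <- function(x, ...) {
  cat(sprintf("<ogt_result> %d stimuli, %d flat regions, %d comparisons in %d batch(es)\n",
              length(x$ground_truths), nrow(x$regions), nrow(x$comparisons),
              nrow(x$history)))
  invisible(x)
}
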