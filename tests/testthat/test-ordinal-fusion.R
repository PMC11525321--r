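# Trend voting, flat regions, pair sampling, triplets, embedding,
# reconstruction, baseline, and the batched comparison loop.

mk_tss <- function(codes, id = "x") structure(list(codes = codes, source_id = id),
                                              class = "tss")

test_that("trend voting takes the plurality and resolves ties to flat", {
  m <- trend_vote(list(mk_tss(c(1, 1)), mk_tss(c(1, -1)), mk_tss(c(0, -1))))
  expect_equal(m$codes[1], 1)
  expect_equal(m$vote_margins[1], 1)
  expect_equal(m$codes[2], -1)
  tie <- trend_vote(list(mk_tss(1), mk_tss(-1)))
  expect_equal(tie$codes, 0)
  expect_equal(tie$vote_margins, 0)
})

test_that("voting on identical TSS is the identity (idempotence)", {
  set.seed(3)
  codes <- sample(c(-1L, 0L, 1L), 30, replace = TRUE)
  m <- trend_vote(lapply(1:5, function(i) mk_tss(codes)))
  expect_equal(m$codes, codes)
  single <- trend_vote(list(mk_tss(codes)))
  expect_equal(single$codes, codes)
  expect_error(trend_vote(list(mk_tss(1:3 * 0L), mk_tss(c(0L, 0L)))), "mismatch")
})

test_that("flat regions are maximal zero runs above the minimum length", {
  m <- list(codes = c(0, 0, 1, 0, 0, 0, -1, 0))
  r <- extract_flat_regions(m, min_len_samples = 2, stimulus_id = "s1")
  expect_equal(r$start, c(1, 4))
  expect_equal(r$end, c(3, 7))
  all0 <- extract_flat_regions(list(codes = rep(0, 6)), stimulus_id = "s1")
  expect_equal(nrow(all0), 1)
  expect_equal(c(all0$start, all0$end), c(1, 7))
  none <- extract_flat_regions(list(codes = c(0, 0, 1, 0, 0)), min_len_samples = 3)
  expect_equal(nrow(none), 0)
})

test_that("pair sampling is exhaustive, duplicate-free, and errs when spent", {
  regions <- extract_flat_regions(list(codes = rep(0, 8)), min_len_samples = 1)
  regions <- do.call(rbind, lapply(1:4, function(i) {
    r <- regions; r$region_id <- paste0("r", i); r
  }))
  p6 <- sample_pairs(regions, 6, seed = 5)
  expect_equal(nrow(unique(t(apply(p6, 1, sort)))), 6)
  expect_error(sample_pairs(regions, 7, seed = 5), "exhausted")
  p3 <- sample_pairs(regions, 3, seed = 5)
  p_rest <- sample_pairs(regions, 3, seed = 6, already_asked = p3)
  key <- function(df) paste(pmin(df[[1]], df[[2]]), pmax(df[[1]], df[[2]]))
  expect_length(intersect(key(p3), key(p_rest)), 0)
})

test_that("comparisons map to dummy-reference triplets one-to-one", {
  comps <- data.frame(region_a = c("j", "k"), region_b = c("k", "j"),
                      lower = c("j", "j"))
  tri <- pairs_to_triplets(comps)
  expect_equal(nrow(tri), nrow(comps))
  expect_true(all(tri$anchor == ".dummy_r"))
  expect_equal(tri$near, c("j", "j"))
  expect_equal(tri$far, c("k", "k"))
  expect_equal(nrow(pairs_to_triplets(comps[0, ])), 0)
  # contradictory duplicates are both emitted
  contra <- data.frame(region_a = c("j", "j"), region_b = c("k", "k"),
                       lower = c("j", "k"))
  expect_equal(nrow(pairs_to_triplets(contra)), 2)
  expect_error(pairs_to_triplets(data.frame(region_a = "a", region_b = "b",
                                            lower = "c")), "must name")
})

test_that("a single comparison orients the embedded pair", {
  comps <- data.frame(region_a = "j", region_b = "k", lower = "j")
  emb <- tste_embed(pairs_to_triplets(comps), c("j", "k"), seed = 2)
  expect_lt(emb$values["j"], emb$values["k"])
})

test_that("consistent triplets from a total order are fully recovered", {
  ids <- sprintf("r%02d", 1:10)
  comps <- all_pair_comparisons(ids, setNames(1:10, ids))
  emb <- tste_embed(pairs_to_triplets(comps), ids, seed = 1)
  expect_equal(emb$satisfied_fraction, 1)
  expect_equal(unname(cor(emb$values[ids], 1:10, method = "spearman")), 1)
  expect_true(emb$converged)
  expect_error(tste_embed(pairs_to_triplets(comps[0, ]), ids), "no triplets")
})

test_that("reconstruction interpolates between embedded flat regions", {
  regions <- data.frame(region_id = c("a", "b"), stimulus_id = "s1",
                        start = c(1L, 6L), end = c(4L, 9L))
  class(regions) <- c("flat_regions", "data.frame")
  gt <- reconstruct(regions, c(a = 0.1, b = 0.9), grid_len = 8)
  expect_equal(gt$values[1:3], rep(0.1, 3))
  expect_equal(gt$values[6:8], rep(0.9, 3))
  expect_equal(gt$values[4:5], 0.1 + (1:2) / 3 * 0.8)
  one <- regions[1, ]; one$end <- 9L
  gt1 <- reconstruct(one, c(a = 0.4), grid_len = 8)
  expect_equal(gt1$values, rep(0.4, 8))
  expect_error(reconstruct(regions[0, ], numeric(0), 8), "no flat regions")
})

test_that("reconstruction commutes with affine revaluation of the embedding", {
  regions <- data.frame(region_id = c("a", "b", "c"), stimulus_id = "s1",
                        start = c(1L, 5L, 11L), end = c(3L, 8L, 13L))
  class(regions) <- c("flat_regions", "data.frame")
  v <- c(a = 0.2, b = 0.9, c = 0.5)
  gt <- reconstruct(regions, v, 12)
  gt2 <- reconstruct(regions, 3 * v + 1, 12)
  expect_equal(gt2$values, 3 * gt$values + 1)
  # a monotone (nonlinear) transform preserves region-sample order
  gt3 <- reconstruct(regions, exp(v), 12)
  reg_idx <- unlist(Map(seq, regions$start, regions$end - 1))
  expect_equal(rank(gt3$values[reg_idx]), rank(gt$values[reg_idx]))
})

test_that("the averaging baseline is the sample-wise mean over present values", {
  a <- annotation(c(0, 2, NA), annotator_id = "a")
  b <- annotation(c(2, 0, 4), annotator_id = "b")
  gt <- baseline_average(list(a, b))
  expect_equal(gt$values, c(1, 1, 4))
  one <- baseline_average(list(a))
  expect_equal(one$values, a$values)
  allna <- baseline_average(list(annotation(c(1, NA)), annotation(c(2, NA))))
  expect_equal(allna$values, c(1.5, NA))
})

test_that("the comparison loop stops at the stability threshold", {
  set.seed(41)
  regions <- data.frame(region_id = sprintf("r%02d", 1:12), stimulus_id = "s1",
                        start = seq(1, 56, 5), end = seq(4, 59, 5))
  class(regions) <- c("flat_regions", "data.frame")
  levels <- setNames(runif(12), regions$region_id)
  src <- make_oracle_source(levels, beta = Inf, seed = 3)
  res <- run_comparison_loop(regions, src, grid_lens = c(s1 = 60),
                             batch_size = 20, rho_stop = 0.8, seed = 7)
  expect_equal(nrow(res$history), 2)
  expect_gte(res$history$rho[2], 0.8)
  expect_true(is.na(res$history$rho[1]))
  expect_equal(nrow(res$comparisons), 40)
})

test_that("an unattainable threshold runs to pair exhaustion", {
  set.seed(43)
  regions <- data.frame(region_id = sprintf("r%d", 1:5), stimulus_id = "s1",
                        start = seq(1, 21, 5), end = seq(4, 24, 5))
  class(regions) <- c("flat_regions", "data.frame")
  levels <- setNames(runif(5), regions$region_id)
  src <- make_oracle_source(levels, beta = Inf, seed = 3)
  res <- run_comparison_loop(regions, src, grid_lens = c(s1 = 24),
                             batch_size = 4, rho_stop = 1.01, seed = 7)
  expect_equal(nrow(res$comparisons), choose(5, 2))
  # the final batch is the partial remainder: 4 + 4 + 2
  expect_equal(diff(res$history$n_comparisons), c(4, 2))
  key <- function(df) paste(pmin(df$region_a, df$region_b),
                            pmax(df$region_a, df$region_b))
  expect_equal(anyDuplicated(key(res$comparisons)), 0)
})
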