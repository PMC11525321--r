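# Independent oracles used across the suite.

# Brute-force trapezoidal segmented regression: enumerate every breakpoint
# placement and parity, solve the level least squares through an explicit
# design matrix and lm.fit (a code path fully disjoint from the package's
# prefix-sum / normal-equation engine), and return the minimal sse.
oracle_tsr_sse <- function(v, T) {
  n <- length(v)
  if (T == 1) return(sum((v - mean(v))^2))
  best <- Inf
  combs <- combn(2:(n - 1), T - 1)
  for (parity in 0:1) {
    for (ci in seq_len(ncol(combs))) {
      bp <- c(1, combs[, ci], n)
      kinds <- vapply(1:T, function(j)
        if ((j %% 2 == 1) == (parity == 0)) "flat" else "sloped", character(1))
      var <- integer(T + 1)
      var[1] <- 1
      nv <- 1
      for (j in 1:T) {
        if (kinds[j] == "flat") var[j + 1] <- var[j]
        else { nv <- nv + 1; var[j + 1] <- nv }
      }
      X <- matrix(0, n, nv)
      for (j in 1:T) {
        a <- bp[j]; b <- bp[j + 1]
        idx <- if (j == T) a:n else a:(b - 1)
        w <- (idx - a) / (b - a)
        X[cbind(idx, var[j])] <- X[cbind(idx, var[j])] + (1 - w)
        X[cbind(idx, var[j + 1])] <- X[cbind(idx, var[j + 1])] + w
      }
      sse <- sum(lm.fit(X, v)$residuals^2)
      if (sse < best) best <- sse
    }
  }
  best
}

# Naive Krippendorff alpha (interval): literal double loop over the
# coincidence definitions.
oracle_kripp_interval <- function(mat) {
  vals <- list()
  for (i in seq_len(nrow(mat))) {
    row <- mat[i, !is.na(mat[i, ])]
    if (length(row) >= 2) vals[[length(vals) + 1]] <- row
  }
  n_tot <- sum(lengths(vals))
  do_sum <- 0
  for (row in vals) {
    m <- length(row)
    for (a in seq_len(m)) for (b in seq_len(m)) if (a != b)
      do_sum <- do_sum + (row[a] - row[b])^2 / (m - 1)
  }
  Do <- do_sum / n_tot
  pooled <- unlist(vals)
  de_sum <- 0
  for (a in seq_along(pooled)) for (b in seq_along(pooled)) if (a != b)
    de_sum <- de_sum + (pooled[a] - pooled[b])^2
  De <- de_sum / (n_tot * (n_tot - 1))
  1 - Do / De
}

# ICC(3,k) through R's ANOVA machinery (two-way, consistency, average
# measure) rather than the package's closed-form sums of squares.
oracle_icc_3k <- function(mat) {
  df <- data.frame(y = as.vector(mat),
                   target = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                   rater = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  av <- anova(stats::lm(y ~ target + rater, data = df))
  msr <- av["target", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / msr
}

# SDA recomputed step by step from its definition (no vectorized diff logic).
oracle_sda <- function(x, y, zero_tol = 1e-9) {
  sg <- function(d) if (abs(d) <= zero_tol) 0 else sign(d)
  acc <- 0; m <- 0
  for (t in 2:length(x)) {
    q <- c(x[t - 1], x[t], y[t - 1], y[t])
    if (anyNA(q)) next
    m <- m + 1
    acc <- acc + if (sg(x[t] - x[t - 1]) == sg(y[t] - y[t - 1])) 1 else -1
  }
  if (m == 0) stop("no valid step")
  acc / m
}

# Build noiseless "which is lower" comparisons for all pairs of items with
# known values.
all_pair_comparisons <- function(ids, values) {
  pairs <- t(combn(ids, 2))
  va <- values[match(pairs[, 1], ids)]
  vb <- values[match(pairs[, 2], ids)]
  data.frame(region_a = pairs[, 1], region_b = pairs[, 2],
             lower = ifelse(va < vb, pairs[, 1], pairs[, 2]),
             stringsAsFactors = FALSE)
}

# Flip the stated number of comparisons (chosen at random) to the opposite
# answer.
flip_comparisons <- function(comps, n_flip, seed) {
  set.seed(seed)
  idx <- sample.int(nrow(comps), n_flip)
  comps$lower[idx] <- ifelse(comps$lower[idx] == comps$region_a[idx],
                             comps$region_b[idx], comps$region_a[idx])
  comps
}
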