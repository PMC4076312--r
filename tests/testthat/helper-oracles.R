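# Independent oracles used across the test files. These deliberately use
# plain loops and textbook formulas, not the package's code paths.

# Brute-force re-implementation of the bootstrap HFLI resampling schedule:
# sorted suprathreshold values, n_iter resamples per hemisphere (each
# hemisphere's index stream restarted from the seed), every pairwise
# sum-based laterality index, trimmed mean.
oracle_hfli <- function(left_vals, right_vals, k = 0.25, min_sample = 5,
                        max_sample = 1000, n_iter = 100, trim = 0.25,
                        seed = 1) {
  lv <- sort(left_vals)
  rv <- sort(right_vals)
  ml <- min(max(as.integer(round(k * length(lv))), min_sample), max_sample)
  mr <- min(max(as.integer(round(k * length(rv))), min_sample), max_sample)
  set.seed(seed)
  sums_l <- numeric(n_iter)
  for (j in seq_len(n_iter)) sums_l[j] <- sum(lv[sample.int(length(lv), ml, replace = TRUE)])
  set.seed(seed)
  sums_r <- numeric(n_iter)
  for (j in seq_len(n_iter)) sums_r[j] <- sum(rv[sample.int(length(rv), mr, replace = TRUE)])
  li <- numeric(n_iter^2)
  idx <- 1L
  for (jr in seq_len(n_iter)) {
    for (jl in seq_len(n_iter)) {
      li[idx] <- 100 * (sums_l[jl] - sums_r[jr]) / (sums_l[jl] + sums_r[jr])
      idx <- idx + 1L
    }
  }
  li <- sort(li)
  drop <- floor(trim * length(li))
  mean(li[(drop + 1):(length(li) - drop)])
}

# Closed-form mixture lower-tail probability P(X < q).
oracle_mixture_tail <- function(q, mean, sd, weight) {
  sum(weight * pnorm(q, mean, sd))
}

# Two-sided Fisher exact p for a 2x2 table by direct hypergeometric
# summation over the support (textbook definition: sum of point
# probabilities not exceeding the observed one).
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Spearman rho with midranks, plus the asymptotic t-approximation p-value.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p = 2 * pt(-abs(tstat), n - 2))
}

# Closed-form mean of a normal clipped (censored) to [lo, hi]:
# E = lo*P(X<lo) + hi*P(X>hi) + E[X; lo<X<hi].
oracle_clipped_normal_mean <- function(mu, sigma, lo = -100, hi = 100) {
  zl <- (lo - mu) / sigma; zh <- (hi - mu) / sigma
  lo * pnorm(zl) + hi * (1 - pnorm(zh)) +
    mu * (pnorm(zh) - pnorm(zl)) - sigma * (dnorm(zh) - dnorm(zl))
}

# Deterministic cohort expanded from per-cell counts (one row per subject).
# `counts` has columns handedness, lat_type, n, hfli (a representative value).
cohort_from_counts <- function(counts) {
  purrr::pmap_dfr(counts, function(handedness, lat_type, n, hfli) {
    tibble::tibble(
      handedness = rep(handedness, n),
      lat_type = factor(rep(lat_type, n),
                        levels = c("Typical", "Ambilateral",
                                   "Strongly-atypical")),
      hfli = rep(hfli, n))
  })
}
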