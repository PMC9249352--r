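# Independent oracles used across the suite.

# Exhaustive least squares for efficiency ~ a * p^d by iteratively refined
# grid search over (a, p); independent of nls.
grid_ls_oracle <- function(d, e, a_range = c(1e-4, 2), p_range = c(1e-4, 1),
                           n_grid = 101L, n_zoom = 14L) {
  rss <- function(a, p) sum((e - a * p^d)^2)
  for (z in seq_len(n_zoom)) {
    as <- seq(a_range[1], a_range[2], length.out = n_grid)
    ps <- seq(p_range[1], p_range[2], length.out = n_grid)
    r <- outer(as, ps, Vectorize(rss))
    ij <- arrayInd(which.min(r), dim(r))
    a_best <- as[ij[1]]; p_best <- ps[ij[2]]
    # shrink slowly around the incumbent: the (a, p) surface has a long
    # curved valley that an aggressive zoom can lock out
    ha <- 0.15 * diff(a_range); hp <- 0.15 * diff(p_range)
    a_range <- c(max(a_best - ha, 1e-6), a_best + ha)
    p_range <- c(max(p_best - hp, 1e-6), min(p_best + hp, 1))
  }
  list(a = a_best, p = p_best, rss = rss(a_best, p_best))
}

# Two-sided Fisher p by full enumeration of all tables with the observed
# margins: sum point (hypergeometric) probabilities <= observed, with the
# usual 1 + 1e-7 relative tolerance.
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Noiseless replicate table generated straight from the biphasic law.
noiseless_dataset <- function(k = 0.71, p1 = 0.935, p2 = 0.995, T_kb = 36,
                              distances = c(10, 26, 36, 41, 46, 57, 117,
                                            166, 291, 338, 398),
                              replicates = 3L) {
  d <- rep(distances, each = replicates)
  data.frame(locus = sprintf("locus-%g", d), distance_kb = d,
             efficiency = predict_efficiency(
               list(k = k, p1 = p1, p2 = p2, T_kb = T_kb), d))
}
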