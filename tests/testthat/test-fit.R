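paper_model <- list(k = 0.71, p1 = 0.935, p2 = 0.995, T_kb = 36)

test_that("predicted efficiency follows the biphasic survival law", {
  m <- paper_model
  expect_equal(predict_efficiency(m, 0), m$k)                 # exponent zero
  expect_equal(predict_efficiency(list(k = 0.4, p1 = 1, p2 = 1, T_kb = 20),
                                  c(0, 7, 500)), rep(0.4, 3)) # no disruption
  expect_equal(predict_efficiency(m, 36), 0.71 * 0.935^36)    # phase boundary
  expect_equal(predict_efficiency(m, 117), 0.71 * 0.935^36 * 0.995^81)
  # continuity at T
  eps <- 1e-9
  expect_equal(predict_efficiency(m, m$T_kb - eps),
               predict_efficiency(m, m$T_kb + eps), tolerance = 1e-6)
  # non-increasing whenever p1, p2 <= 1
  d <- seq(0, 400, by = 0.5)
  expect_true(all(diff(predict_efficiency(m, d)) <= 0))
  expect_error(predict_efficiency(m, -1), ">= 0")
})

test_that("single-segment fit recovers exact exponentials and boundaries", {
  d <- c(5, 15, 30, 60)
  s <- fit_exponential(d, 0.7 * 0.95^d)
  expect_equal(s$amplitude, 0.7, tolerance = 1e-7)
  expect_equal(s$per_kb_prob, 0.95, tolerance = 1e-7)

  const <- fit_exponential(c(1, 5, 9, 14), rep(0.3, 4))
  expect_equal(const$amplitude, 0.3)
  expect_equal(const$per_kb_prob, 1)
  expect_equal(const$rss, 0)

  expect_error(fit_exponential(c(1, 2), c(0.1, 0.2)), "at least 3")
  expect_error(fit_exponential(c(3, 3, 3), c(0.1, 0.2, 0.3)), "distinct")
})

test_that("least-squares optimum matches the grid-search oracle", {
  set.seed(3)
  for (i in 1:5) {
    d <- sort(sample(1:120, 6))
    e <- 0.6 * 0.96^d + rnorm(6, 0, 0.02)
    e[e < 0] <- 0
    s <- fit_exponential(d, e)
    g <- grid_ls_oracle(d, e)
    expect_lte(s$rss, g$rss * (1 + 1e-9))
    expect_lt(abs(s$rss - g$rss) / g$rss, 1e-9)
  }
})

test_that("zero observations stay in the least squares untransformed", {
  d <- c(2, 10, 40, 90, 200)
  e <- c(0.5, 0.4, 0.1, 0, 0)
  s <- fit_exponential(d, e)
  expect_equal(s$rss, sum((e - s$amplitude * s$per_kb_prob^d)^2))
  expect_equal(s$n_points, 5L)
})

test_that("two-segment fit recovers a noiseless biphasic truth", {
  dat <- noiseless_dataset(k = 0.7, p1 = 0.93, p2 = 0.99, T_kb = 35,
                           replicates = 2L)
  out <- fit_two_segment(dat, split_index = 2L)  # distances <= 35: 10, 26
  expect_equal(out$model$k, 0.7, tolerance = 1e-5)
  expect_equal(out$model$p1, 0.93, tolerance = 1e-5)
  expect_equal(out$model$p2, 0.99, tolerance = 1e-5)
  expect_equal(out$model$T_kb, 35, tolerance = 1e-4)
  expect_error(fit_two_segment(dat, 1L), "split_index")
  expect_error(fit_two_segment(dat, 10L), "split_index")
})

test_that("intersection threshold solves a1*p1^T = a2*p2^T", {
  s1 <- structure(list(amplitude = 0.71, per_kb_prob = 0.935, rss = 1e-3,
                       n_points = 10L), class = "bir_segment")
  a2 <- 0.71 * (0.935 / 0.995)^36
  s2 <- structure(list(amplitude = a2, per_kb_prob = 0.995, rss = 1e-3,
                       n_points = 10L), class = "bir_segment")
  expect_equal(intersection_threshold(s1, s2), 36)
  expect_error(intersection_threshold(s1, s1), "equal per-kb")
  expect_warning(intersection_threshold(s1, s2, data_range = c(50, 400)),
                 "outside")
})

test_that("AIC follows the Gaussian nls convention", {
  set.seed(9)
  d <- rep(c(5, 20, 60, 120), each = 4)
  e <- 0.6 * 0.97^d + rnorm(length(d), 0, 0.02)
  s <- fit_exponential(d, e)
  # cross-check against stats::AIC on the underlying nls fit
  expect_equal(bir_aic(s), AIC(s$fit))
  # scaling every residual by 2 multiplies rss by 4, shifting AIC by n*log(4)
  s4 <- s; s4$rss <- 4 * s$rss
  expect_equal(bir_aic(s4) - bir_aic(s), s$n_points * log(4))
  # degenerate zero-residual fit refuses an AIC
  s0 <- s; s0$rss <- 0
  expect_error(bir_aic(s0), "degenerate")
  # two-segment combination sums the per-segment AICs
  expect_equal(bir_aic(s, s4), bir_aic(s) + bir_aic(s4))
})

test_that("logLik method reproduces the bir_aic convention via stats::AIC", {
  dat <- simulate_experiment(bir_sim_config(seed = 3, replicates = 4L))
  f <- bir_fit(efficiency ~ distance_kb, dat)
  expect_equal(AIC(f), bir_aic(f$segments$seg1, f$segments$seg2))
  expect_equal(AIC(f), f$table$aic[match(f$selected, f$table$model)])
})

test_that("breakpoint scan finds a true break and reports near-ties", {
  # strong break after the 6th distance (T = 57): low-noise simulation
  cfg <- bir_sim_config(k = 0.7, p1 = 0.93, p2 = 0.998, T_kb = 57,
                        attempts = 2000, replicates = 6L, seed = 21)
  dat <- simulate_experiment(cfg)
  f <- bir_fit(efficiency ~ distance_kb, dat)
  expect_true(f$selected != "single")
  expect_lte(abs(f$model$split_index - 6L), 1L)
  tab <- f$table
  expect_true(all(tab$near_tie[!is.na(tab$delta_aic) & tab$delta_aic <= 1]))
  # scan never aborts: failed splits would appear as non-converged rows
  expect_true(all(c("single", "split_2") %in% tab$model))
})

test_that("no spurious breakpoint preference under pooled-variance AIC", {
  # single-phase truth: the two-segment model should not beat the single
  # exponential by a meaningful pooled-AIC margin
  gaps <- vapply(1:8, function(i) {
    cfg <- bir_sim_config(p1 = 0.995, p2 = 0.995, T_kb = 36,
                          replicates = 6L, seed = 300 + i)
    f <- bir_fit(efficiency ~ distance_kb, simulate_experiment(cfg),
                 aic = "pooled")
    tab <- f$table
    tab$aic[tab$model == "single"] -
      min(tab$aic[tab$model != "single"], na.rm = TRUE)
  }, 0)
  expect_lte(median(gaps), 2)
})

test_that("refitting on the model's own predictions is idempotent", {
  dat <- noiseless_dataset(replicates = 2L)
  f1 <- bir_fit(efficiency ~ distance_kb, dat, split = 3L)
  dat2 <- dat
  dat2$efficiency <- predict(f1, dat)
  f2 <- bir_fit(efficiency ~ distance_kb, dat2, split = 3L)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-8)
})

test_that("disruption probabilities derive from the continuation terms", {
  d <- disruption_probabilities(list(p1 = 0.935, p2 = 0.995))
  expect_equal(d$disruption_p1, 0.065)
  expect_equal(d$disruption_p2, 0.005)
  expect_equal(d$ratio, 13)
  expect_identical(disruption_probabilities(list(p1 = 0.9, p2 = 1))$ratio, Inf)
})

test_that("fit object methods are coherent", {
  dat <- simulate_experiment(bir_sim_config(seed = 8, replicates = 4L))
  f <- bir_fit(efficiency ~ distance_kb, dat)
  expect_s3_class(f, "bir_fit")
  expect_named(coef(f), c("k", "p1", "p2", "T_kb"))
  expect_equal(residuals(f), dat$efficiency[order(dat$distance_kb)] - fitted(f))
  expect_output(print(f), "two segments")
  expect_output(print(summary(f)), "Model comparison")
  sims <- simulate(f, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "data.frame")
})
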