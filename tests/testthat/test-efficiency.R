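test_that("efficiency is the per-experiment transformant ratio", {
  expect_identical(bir_efficiency(0, 100), 0)
  expect_identical(bir_efficiency(50, 100), 0.5)
  expect_equal(bir_efficiency(71, 100), 0.71)
  expect_error(bir_efficiency(5, 0), "experiment\\(s\\) 1")
  expect_error(bir_efficiency(-1, 10), "non-negative")
  expect_warning(bir_efficiency(120, 100), "exceeds 1")
})

test_that("efficiency is scale-equivariant in the counts", {
  set.seed(11)
  for (i in 1:25) {
    a <- sample(0:50, 1); b <- sample(1:200, 1); m <- sample(1:9, 1)
    expect_equal(suppressWarnings(bir_efficiency(a * m, b * m)),
                 suppressWarnings(bir_efficiency(a, b)))
  }
})

test_that("datasets validate, recompute efficiency and round-trip via CSV", {
  df <- data.frame(locus = c("L2", "L1", "L3"), distance_kb = c(26, 10, 117),
                   linear_count = c(20L, 50L, 3L),
                   control_count = c(100L, 100L, 100L),
                   condition = "wt")
  ds <- as_efficiency_dataset(df)
  expect_equal(ds$distance_kb, c(10, 26, 117))      # sorted by distance
  expect_equal(ds$efficiency, c(0.5, 0.2, 0.03))    # recomputed from counts
  expect_false(attr(ds, "counts_absent"))

  path <- withr::local_tempfile(fileext = ".csv")
  write_efficiency(ds, path)
  back <- read_efficiency(path)
  expect_equal(back$efficiency, ds$efficiency)
  expect_equal(back$linear_count, ds$linear_count)
  expect_equal(back$locus, ds$locus)

  # precomputed efficiency without counts is accepted and flagged
  eff_only <- as_efficiency_dataset(
    data.frame(locus = "L1", distance_kb = 10, efficiency = 0.4))
  expect_true(attr(eff_only, "counts_absent"))
})

test_that("malformed tables are rejected with the offending row named", {
  expect_error(as_efficiency_dataset(data.frame(distance_kb = 1)),
               "locus")
  expect_error(as_efficiency_dataset(
    data.frame(locus = "Lz", distance_kb = 10,
               linear_count = 5L, control_count = 0L)),
    "row\\(s\\) 1.*Lz")
  expect_error(as_efficiency_dataset(
    data.frame(locus = "L", distance_kb = -4, efficiency = 0.1)),
    ">= 0")
})

test_that("per-locus summaries average per-experiment ratios", {
  df <- as_efficiency_dataset(data.frame(
    locus = rep(c("A", "B"), c(3, 2)), distance_kb = rep(c(10, 26), c(3, 2)),
    efficiency = c(0.25, 0.25, 0.25, 0.2, 0.3)))
  s <- summarize_by_locus(df)
  expect_equal(s$mean_efficiency, c(0.25, 0.25))
  expect_equal(s$sd_efficiency, c(0, sd(c(0.2, 0.3))))
  expect_equal(s$n, c(3L, 2L))

  one <- summarize_by_locus(as_efficiency_dataset(
    data.frame(locus = "A", distance_kb = 5, efficiency = 0.1)))
  expect_true(is.na(one$sd_efficiency))
  expect_error(summarize_by_locus(df[0, ]), "empty")
})

test_that("ratio-of-means and mean-of-ratios are kept distinct", {
  # experiments with very different plate yields: pooling weights by yield
  df <- as_efficiency_dataset(data.frame(
    locus = "A", distance_kb = 10,
    linear_count = c(1L, 90L), control_count = c(10L, 100L)))
  expect_equal(summarize_by_locus(df)$mean_efficiency, mean(c(0.1, 0.9)))
  expect_equal(pooled_efficiency(df)$pooled_efficiency, 91 / 110)
  expect_false(isTRUE(all.equal(summarize_by_locus(df)$mean_efficiency,
                                pooled_efficiency(df)$pooled_efficiency)))
})
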