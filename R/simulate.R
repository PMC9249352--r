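#' Configuration of the mechanistic BIR simulator
#'
#' Collects the generative parameters of the per-kb survival chain: the
#' initiation probability `k`, the per-kb continuation probabilities `p1`
#' and `p2`, the phase-switch threshold `T_kb`, the locus distances to
#' simulate, the expected number of transformation-competent events per
#' plate and the number of replicate experiments per locus. The defaults
#' are the fitted parameters of the chromosome fragmentation assay
#' (k = 0.71, p1 = 0.935, p2 = 0.995, T = 36 kb) at the assay's eleven
#' distinct locus distances (10-398 kb from the telomere, the three
#' largest obtained by reciprocal translocation), with 8 replicates per
#' locus and an expected 200 competent events per plate.
#'
#' @param k initiation probability in (0, 1].
#' @param p1,p2 per-kb continuation probabilities in \[0, 1\].
#' @param T_kb phase-switch threshold (kb); `Inf` gives a single-phase
#'   model.
#' @param distances_kb locus distances to telomere (kb).
#' @param attempts expected transformation-competent events per plate
#'   (Poisson mean).
#' @param replicates independent experiments per locus.
#' @param seed integer seed; the same seed and config give byte-identical
#'   datasets.
#' @param shared_attempts if TRUE the linear and control platings of one
#'   experiment share the same competent-cell number; by default they are
#'   independent Poisson draws, emulating day-to-day competence variation.
#' @return object of class `bir_sim_config`.
#' @export
bir_sim_config <- function(k = 0.71, p1 = 0.935, p2 = 0.995, T_kb = 36,
                           distances_kb = c(10, 26, 36, 41, 46, 57, 117,
                                            166, 291, 338, 398),
                           attempts = 200, replicates = 8L, seed = 1L,
                           shared_attempts = FALSE) {
  stopifnot(k >= 0, k <= 1, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1,
            T_kb > 0, all(distances_kb >= 0), attempts > 0, replicates >= 0)
  structure(list(k = k, p1 = p1, p2 = p2, T_kb = T_kb,
                 distances_kb = sort(distances_kb), attempts = attempts,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 shared_attempts = shared_attempts),
            class = "bir_sim_config")
}

#' @export
print.bir_sim_config <- function(x, ...) {
  cat(sprintf(
    "BIR simulator: k=%g p1=%g p2=%g T=%g kb | %d loci x %d replicates, ~%g attempts, seed %d\n",
    x$k, x$p1, x$p2, x$T_kb, length(x$distances_kb), x$replicates,
    x$attempts, x$seed))
  invisible(x)
}

## kb-by-kb binomial thinning of n attempts: each kb is one Bernoulli
## survival per attempt, a fractional last kb uses the fractional exponent
.survive_chain <- function(n, len_kb, p) {
  if (n == 0L || len_kb <= 0) return(n)
  for (i in seq_len(floor(len_kb))) {
    n <- stats::rbinom(1L, n, p)
    if (n == 0L) return(0L)
  }
  frac <- len_kb - floor(len_kb)
  if (frac > 0) n <- stats::rbinom(1L, n, p^frac)
  n
}

#' Simulate BIR attempts through the per-kb survival chain
#'
#' Each attempt initiates BIR with probability `k`, then must survive every
#' kilobase of synthesis: with probability `p1` per kb up to
#' `min(dist, T)`, and `p2` per kb beyond. The marginal success probability
#' is exactly `predict_efficiency()` at the same parameters; this function
#' walks the chain kb by kb rather than using the closed form, so it serves
#' as a mechanistic cross-check of it.
#'
#' Draws from the current RNG stream unless `seed` is given.
#'
#' @param n number of attempts.
#' @param dist_kb distance to telomere (kb).
#' @param config a [bir_sim_config()].
#' @param seed optional integer seed.
#' @return integer number of successful attempts.
#' @examples
#' cfg <- bir_sim_config()
#' simulate_bir_attempts(1000, 117, cfg, seed = 1)
#' @export
simulate_bir_attempts <- function(n, dist_kb, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(dist_kb >= 0, n >= 0)
  alive <- stats::rbinom(1L, n, config$k)
  alive <- .survive_chain(alive, min(dist_kb, config$T_kb), config$p1)
  .survive_chain(alive, max(dist_kb - config$T_kb, 0), config$p2)
}

#' Simulate a replicate set of transformation experiments
#'
#' For every locus distance and replicate, the number of
#' transformation-competent events on the control plate is drawn
#' Poisson(`attempts`); the linear plating receives its own independent
#' Poisson draw (or the same number with `shared_attempts`), each of whose
#' events succeeds through the per-kb survival chain of
#' [simulate_bir_attempts()]. Efficiencies are then the per-experiment
#' ratios. Control plates that drew zero events are redrawn, as a plate
#' without control transformants yields no ratio and would be repeated at
#' the bench.
#'
#' The run is seeded from `config$seed`: identical configs give identical
#' datasets.
#'
#' @param config a [bir_sim_config()].
#' @return an efficiency dataset (see [as_efficiency_dataset()]) with one
#'   row per locus x replicate, loci labelled `"locus-<distance>"`.
#' @export
simulate_experiment <- function(config) {
  set.seed(config$seed)
  if (config$replicates == 0L || !length(config$distances_kb))
    return(as_efficiency_dataset(
      data.frame(locus = character(), distance_kb = numeric(),
                 linear_count = integer(), control_count = integer(),
                 efficiency = numeric(), condition = character())[0, ]))
  rows <- list()
  for (d in config$distances_kb) {
    for (r in seq_len(config$replicates)) {
      control <- stats::rpois(1L, config$attempts)
      while (control == 0L) control <- stats::rpois(1L, config$attempts)
      n_lin <- if (config$shared_attempts) control
               else stats::rpois(1L, config$attempts)
      lin <- simulate_bir_attempts(n_lin, d, config)
      rows[[length(rows) + 1L]] <-
        data.frame(locus = sprintf("locus-%g", d), distance_kb = d,
                   linear_count = lin, control_count = control,
                   condition = sprintf("replicate_%d", r))
    }
  }
  suppressWarnings(as_efficiency_dataset(do.call(rbind, rows)))
}

#' Parameter-recovery study for the biphasic fit
#'
#' Simulates `n_datasets` replicate-level datasets from `config`, refits
#' each with [bir_fit()] at the true split (the number of simulated
#' distances at or below `T_kb`), and tabulates how well the estimator
#' recovers `k`, `p1` and `p2`. With `scan = TRUE` each dataset is
#' additionally scanned over all admissible splits and the AIC-selected
#' split recorded.
#'
#' @param config a [bir_sim_config()]; `config$seed` seeds the whole study.
#' @param n_datasets number of simulated datasets (>= 50 recommended for
#'   stable summaries).
#' @param scan also run the breakpoint scan per dataset.
#' @return list of class `bir_recovery`: `table` (per-parameter truth, mean
#'   estimate, bias, median absolute error, RMSE), `estimates` (per-dataset
#'   parameter draws), `n_failed` (datasets excluded for fit failure),
#'   `selected_splits` and `true_split` (when `scan = TRUE`).
#' @export
parameter_recovery_study <- function(config, n_datasets = 200L, scan = FALSE) {
  true_split <- sum(config$distances_kb <= config$T_kb)
  est <- matrix(NA_real_, n_datasets, 3L,
                dimnames = list(NULL, c("k", "p1", "p2")))
  sel <- rep(NA_integer_, n_datasets)
  failed <- 0L
  for (i in seq_len(n_datasets)) {
    cfg <- config
    cfg$seed <- config$seed + i
    dat <- simulate_experiment(cfg)
    f <- tryCatch(bir_fit(efficiency ~ distance_kb, dat, split = true_split),
                  error = function(err) NULL)
    if (is.null(f) || f$selected == "single") { failed <- failed + 1L; next }
    est[i, ] <- c(f$model$k, f$model$p1, f$model$p2)
    if (scan) {
      fs <- tryCatch(bir_fit(efficiency ~ distance_kb, dat),
                     error = function(err) NULL)
      if (!is.null(fs) && fs$selected != "single")
        sel[i] <- fs$model$split_index
    }
  }
  truth <- c(k = config$k, p1 = config$p1, p2 = config$p2)
  ok <- stats::complete.cases(est)
  tab <- data.frame(
    parameter = colnames(est), truth = unname(truth),
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - truth,
    median_abs_error = apply(abs(sweep(est[ok, , drop = FALSE], 2, truth)), 2,
                             stats::median),
    rmse = sqrt(colMeans(sweep(est[ok, , drop = FALSE], 2, truth)^2)))
  rownames(tab) <- NULL
  structure(list(table = tab, estimates = est, n_failed = failed,
                 selected_splits = if (scan) sel else NULL,
                 true_split = true_split, config = config),
            class = "bir_recovery")
}

#' @export
print.bir_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d datasets (%d failed fits)\n",
              nrow(x$estimates), x$n_failed))
  print(transform(x$table, mean_estimate = signif(mean_estimate, 4),
                  bias = signif(bias, 3),
                  median_abs_error = signif(median_abs_error, 3),
                  rmse = signif(rmse, 3)), row.names = FALSE)
  if (!is.null(x$selected_splits)) {
    ok <- !is.na(x$selected_splits)
    cat(sprintf("Breakpoint scan: %.0f%% of runs within one index of the true split (%d)\n",
                100 * mean(abs(x$selected_splits[ok] - x$true_split) <= 1),
                x$true_split))
  }
  invisible(x)
}
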