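#' Predicted BIR efficiency under the biphasic per-kb survival model
#'
#' The model: a transformed linear vector initiates BIR with probability
#' `k`; synthesis then proceeds kb by kb, surviving each of the first
#' `T_kb` kilobases with probability `p1` (low-processivity phase) and each
#' subsequent kilobase with probability `p2` (high-processivity phase).
#' The expected efficiency at distance `d` is therefore
#' `k * p1^d` for `d <= T_kb` and `k * p1^T_kb * p2^(d - T_kb)` beyond,
#' continuous at `T_kb`.
#'
#' @param model a fitted [bir_fit] object, or a named list/vector with
#'   elements `k`, `p1`, `p2`, `T_kb` (a single-phase model may omit `p2`
#'   and `T_kb`).
#' @param dist_kb numeric vector of distances to telomere (kb, >= 0).
#' @return numeric vector of expected efficiencies.
#' @examples
#' m <- list(k = 0.71, p1 = 0.935, p2 = 0.995, T_kb = 36)
#' predict_efficiency(m, c(0, 16, 36, 117))
#' @export
predict_efficiency <- function(model, dist_kb) {
  if (inherits(model, "bir_fit")) model <- model$model
  model <- as.list(model)
  k <- model$k; p1 <- model$p1
  p2 <- if (is.null(model$p2) || is.na(model$p2)) p1 else model$p2
  T_kb <- if (is.null(model$T_kb) || is.na(model$T_kb)) Inf else model$T_kb
  if (any(dist_kb < 0)) stop("dist_kb must be >= 0")
  k * p1^pmin(dist_kb, T_kb) * p2^pmax(dist_kb - T_kb, 0)
}

## deterministic jitter factors for optimizer restarts, independent of the
## caller's RNG stream
.restart_jitters <- function(n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(48151L)
  matrix(stats::rnorm(2L * n), ncol = 2L)
}

#' Fit a single exponential decay segment by nonlinear least squares
#'
#' Least-squares fit of `efficiency ~ amplitude * per_kb_prob^distance`,
#' the single-phase survival law. Starting values are the maximum observed
#' efficiency for the amplitude and `exp(slope)` of a log-linear regression
#' of the positive efficiencies for the base; up to 20 deterministically
#' jittered restarts are attempted before declaring non-convergence.
#' Observations with efficiency 0 stay in the least squares (the data are
#' never log-transformed for fitting). Constant data are handled as the
#' boundary fit `per_kb_prob = 1`.
#'
#' @param dist_kb,efficiency numeric vectors of equal length; at least 3
#'   observations spanning at least 2 distinct distances.
#' @return object of class `bir_segment`: a list with `amplitude`,
#'   `per_kb_prob`, `rss`, `n_points`, standard errors `se` (NA for
#'   degenerate fits) and the underlying `nls` fit (or NULL).
#' @export
fit_exponential <- function(dist_kb, efficiency) {
  ok <- is.finite(dist_kb) & is.finite(efficiency)
  d <- dist_kb[ok]; e <- efficiency[ok]
  if (length(e) < 3L) stop("need at least 3 observations")
  if (length(unique(d)) < 2L) stop("need at least 2 distinct distances")

  seg <- function(a, p, rss, fit = NULL, se = c(a = NA_real_, p = NA_real_))
    structure(list(amplitude = a, per_kb_prob = p, rss = rss,
                   n_points = length(e), se = se, fit = fit),
              class = "bir_segment")
  rss_at <- function(a, p) sum((e - a * p^d)^2)

  if (stats::sd(e) == 0)               # constant data: boundary fit
    return(seg(e[1L], 1, 0))

  pos <- e > 0
  a_ll <- NULL
  if (sum(pos) >= 2L && length(unique(d[pos])) >= 2L) {
    ll <- stats::lm(log(e[pos]) ~ d[pos])
    p0 <- exp(stats::coef(ll)[[2L]])
    a_ll <- exp(stats::coef(ll)[[1L]])
  } else p0 <- 0.99
  p0 <- min(max(p0, 1e-4), 1)
  a0 <- max(e)

  # exact-model data: the log-linear solution already attains the optimum
  # (nls cannot iterate on a zero-residual problem)
  if (!is.null(a_ll) && rss_at(a_ll, p0) <= 1e-20 * max(1, sum(e^2)))
    return(seg(a_ll, p0, rss_at(a_ll, p0)))

  jit <- .restart_jitters(20L)
  starts <- rbind(c(0, 0), jit * rep(c(0.3, 0.02), each = nrow(jit)))
  fit <- NULL
  for (i in seq_len(nrow(starts))) {
    a_i <- a0 * exp(starts[i, 1L])
    p_i <- min(max(p0 * exp(starts[i, 2L]), 1e-4), 0.999999)
    fit <- tryCatch(
      stats::nls(e ~ a * p^d, start = list(a = a_i, p = p_i),
                 control = stats::nls.control(maxiter = 500, warnOnly = FALSE)),
      error = function(err) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("exponential fit did not converge after 20 restarts (last start a=",
         signif(a_i, 4), ", p=", signif(p_i, 4), ")")
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(err) c(NA_real_, NA_real_))
  names(se) <- c("a", "p")
  seg(cf[["a"]], cf[["p"]], sum(stats::resid(fit)^2), fit, se)
}

#' @export
print.bir_segment <- function(x, ...) {
  cat(sprintf("Exponential segment: %.4g * %.4g^dist  (rss %.4g, n %d)\n",
              x$amplitude, x$per_kb_prob, x$rss, x$n_points))
  invisible(x)
}

#' Gaussian AIC of one or two fitted segments
#'
#' Akaike Information Criterion under a Gaussian likelihood with the
#' maximum-likelihood residual variance:
#' `AIC = n * (log(2*pi) + 1 + log(rss / n)) + 2 * (p + 1)`, with `p = 2`
#' curve parameters per segment plus 1 for the variance. This is exactly the
#' value `stats::AIC()` reports for an `nls` fit. For a two-segment
#' combination the default is the sum of the two segments' AICs, each with
#' its own variance (the segments are independent fits); `method = "pooled"`
#' instead uses one common residual variance across both segments, for
#' sensitivity analysis.
#'
#' @param seg1 a `bir_segment` (from [fit_exponential()]).
#' @param seg2 optional second `bir_segment`.
#' @param method `"independent"` (sum of per-segment AICs) or `"pooled"`
#'   (single shared variance).
#' @return the AIC, a single number.
#' @export
bir_aic <- function(seg1, seg2 = NULL, method = c("independent", "pooled")) {
  method <- match.arg(method)
  one <- function(s) {
    if (s$rss <= 0) stop("degenerate fit: zero residual sum of squares")
    n <- s$n_points
    n * (log(2 * pi) + 1 + log(s$rss / n)) + 2 * 3
  }
  if (is.null(seg2)) return(one(seg1))
  if (method == "independent") return(one(seg1) + one(seg2))
  n <- seg1$n_points + seg2$n_points
  rss <- seg1$rss + seg2$rss
  if (rss <= 0) stop("degenerate fit: zero residual sum of squares")
  n * (log(2 * pi) + 1 + log(rss / n)) + 2 * (4 + 1)
}

#' Threshold length where two fitted exponential segments intersect
#'
#' The phase-switch threshold `T` is taken as the distance at which the two
#' fitted curves meet: the unique solution of
#' `a1 * p1^T = a2 * p2^T`, i.e. `T = log(a2 / a1) / log(p1 / p2)`.
#'
#' @param seg1,seg2 `bir_segment` fits of the short- and long-distance
#'   phases.
#' @param data_range optional numeric range of fitted distances; a `T`
#'   outside it (or <= 0) is returned with a warning.
#' @return the intersection distance in kb.
#' @export
intersection_threshold <- function(seg1, seg2, data_range = NULL) {
  p1 <- seg1$per_kb_prob; p2 <- seg2$per_kb_prob
  if (isTRUE(all.equal(p1, p2, tolerance = 1e-12)))
    stop("segments have equal per-kb probabilities: curves do not intersect")
  T_kb <- log(seg2$amplitude / seg1$amplitude) / log(p1 / p2)
  if (!is.finite(T_kb))
    stop("segments do not intersect (parallel curves)")
  if (T_kb <= 0 || (!is.null(data_range) &&
                    (T_kb < data_range[1L] || T_kb > data_range[2L])))
    warning("intersection threshold ", signif(T_kb, 4),
            " kb lies outside the fitted data range")
  T_kb
}

#' Fit the two phases on either side of a candidate breakpoint
#'
#' Segment 1 is fitted on all replicates of the `split_index` smallest
#' distinct distances, segment 2 on the rest, each by independent least
#' squares with no continuity constraint; the threshold `T` is derived
#' afterwards as the intersection of the two curves (that the curves meet
#' near the boundary is an emergent property of the data, not an imposed
#' one). The assembled biphasic model takes `k` and `p1` from segment 1 and
#' `p2` from segment 2.
#'
#' @param data efficiency dataset (or any data frame with `distance_kb` and
#'   `efficiency`).
#' @param split_index integer: number of smallest distinct distances
#'   assigned to segment 1; each segment must retain >= 2 distinct
#'   distances.
#' @return list with `seg1`, `seg2` (class `bir_segment`) and `model`
#'   (named list `k`, `p1`, `p2`, `T_kb`, `a2`, `split_index`; `T_kb` is NA
#'   with a diagnostic if the curves do not intersect).
#' @export
fit_two_segment <- function(data, split_index) {
  dists <- sort(unique(data$distance_kb))
  nd <- length(dists)
  if (split_index < 2L || split_index > nd - 2L)
    stop("split_index must leave >= 2 distinct distances in each segment")
  in1 <- data$distance_kb <= dists[split_index]
  seg1 <- fit_exponential(data$distance_kb[in1], data$efficiency[in1])
  seg2 <- fit_exponential(data$distance_kb[!in1], data$efficiency[!in1])
  T_kb <- tryCatch(intersection_threshold(seg1, seg2, range(data$distance_kb)),
                   error = function(err) NA_real_)
  list(seg1 = seg1, seg2 = seg2,
       model = list(k = seg1$amplitude, p1 = seg1$per_kb_prob,
                    p2 = seg2$per_kb_prob, a2 = seg2$amplitude,
                    T_kb = T_kb, split_index = split_index))
}

#' Fit the biphasic exponential model of BIR efficiency versus distance
#'
#' Fits replicate-level efficiencies against the length of DNA to
#' synthesize with (i) a single exponential `a * p^dist` and (ii)
#' two-segment combinations splitting the distinct distances, in increasing
#' order, into a first phase of `x` distances and a second phase of the
#' rest, for every `x` in `scan`. Candidates are compared by Gaussian AIC
#' ([bir_aic()]); the fit with the lowest AIC is selected, exact ties going
#' to the smaller split, and every candidate within 1 AIC unit of the
#' minimum is flagged as statistically indistinguishable from it.
#'
#' Fitting uses every replicate observation, not per-locus means: each
#' transformation experiment is an independent draw around the model curve,
#' and collapsing to means would discard the replication that the AIC
#' comparison relies on.
#'
#' @param formula model formula, `efficiency ~ distance_kb` by default.
#' @param data efficiency dataset (see [as_efficiency_dataset()]) or any
#'   data frame with the formula's variables.
#' @param split single integer to fit one fixed breakpoint instead of
#'   scanning.
#' @param scan integer vector of candidate splits; default `2:(nd - 2)`
#'   where `nd` is the number of distinct distances.
#' @param aic `"independent"` or `"pooled"`, see [bir_aic()].
#' @return object of class `bir_fit` with components `model` (selected
#'   parameters `k`, `p1`, `p2`, `T_kb`, `split_index`), `segments`,
#'   `single` (the single-exponential baseline), `candidates` (full fits per
#'   split) and `table` (the AIC comparison). Methods: `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot`, `simulate`,
#'   `logLik`/`AIC`.
#' @examples
#' cfg <- bir_sim_config(seed = 7)
#' dat <- simulate_experiment(cfg)
#' fit <- bir_fit(efficiency ~ distance_kb, dat)
#' coef(fit)
#' @export
bir_fit <- function(formula = efficiency ~ distance_kb, data,
                    split = NULL, scan = NULL,
                    aic = c("independent", "pooled")) {
  aic <- match.arg(aic)
  mf <- stats::model.frame(formula, data)
  df <- data.frame(efficiency = mf[[1L]], distance_kb = mf[[2L]])
  df <- df[order(df$distance_kb), ]
  dists <- sort(unique(df$distance_kb))
  nd <- length(dists)
  if (nd < 4L) stop("need at least 4 distinct distances for a two-segment fit")

  single <- fit_exponential(df$distance_kb, df$efficiency)
  aic_single <- tryCatch(bir_aic(single), error = function(err) NA_real_)

  splits <- if (!is.null(split)) as.integer(split)
            else if (!is.null(scan)) as.integer(scan) else 2:(nd - 2L)
  splits <- splits[splits >= 2L & splits <= nd - 2L]
  if (!length(splits)) stop("no admissible split indices")

  # the scan deliberately probes poor splits, whose intersection may fall
  # outside the data range; that diagnostic is kept in the table, not raised
  candidates <- lapply(splits, function(x) {
    out <- tryCatch(suppressWarnings(fit_two_segment(df, x)),
                    error = function(err) err)
    if (inherits(out, "error"))
      return(list(model = list(split_index = x), error = conditionMessage(out),
                  aic = NA_real_))
    out$aic <- tryCatch(bir_aic(out$seg1, out$seg2, method = aic),
                        error = function(err) NA_real_)
    out
  })
  names(candidates) <- paste0("split_", splits)

  tab <- data.frame(
    model = c("single", names(candidates)),
    split_index = c(NA_integer_, splits),
    k = c(single$amplitude, vapply(candidates, function(c.) c.$model$k %||% NA_real_, 0)),
    p1 = c(single$per_kb_prob, vapply(candidates, function(c.) c.$model$p1 %||% NA_real_, 0)),
    p2 = c(NA_real_, vapply(candidates, function(c.) c.$model$p2 %||% NA_real_, 0)),
    T_kb = c(NA_real_, vapply(candidates, function(c.) c.$model$T_kb %||% NA_real_, 0)),
    aic = c(aic_single, vapply(candidates, function(c.) c.$aic, 0)),
    converged = c(TRUE, vapply(candidates, function(c.) is.null(c.$error), TRUE)))
  best <- min(tab$aic, na.rm = TRUE)
  tab$delta_aic <- tab$aic - best
  tab$near_tie <- !is.na(tab$delta_aic) & tab$delta_aic <= 1

  # lowest AIC wins; exact ties go to the smaller split (single sorts first)
  sel_i <- which(!is.na(tab$aic))
  sel_i <- sel_i[order(tab$aic[sel_i])][1L]
  selected <- tab$model[sel_i]

  if (selected == "single") {
    model <- list(k = single$amplitude, p1 = single$per_kb_prob,
                  p2 = NA_real_, T_kb = NA_real_, split_index = NA_integer_)
    segments <- NULL
  } else {
    chosen <- candidates[[selected]]
    model <- chosen$model
    segments <- list(seg1 = chosen$seg1, seg2 = chosen$seg2)
  }

  structure(list(call = match.call(), data = df, distances = dists,
                 model = model, segments = segments, single = single,
                 candidates = candidates, table = tab, selected = selected,
                 aic_method = aic),
            class = "bir_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-kb disruption probabilities of a fitted biphasic model
#'
#' `1 - p1` and `1 - p2` are the probabilities that ongoing BIR synthesis is
#' irreversibly disrupted within one kilobase during the first and second
#' phase; their ratio measures how much more processive the second phase is.
#'
#' @param model a [bir_fit] object or named list with `p1` and `p2`.
#' @return list with `disruption_p1`, `disruption_p2` and `ratio`
#'   (`Inf` when `p2 = 1`).
#' @examples
#' disruption_probabilities(list(p1 = 0.935, p2 = 0.995))
#' @export
disruption_probabilities <- function(model) {
  if (inherits(model, "bir_fit")) model <- model$model
  d1 <- 1 - model$p1; d2 <- 1 - model$p2
  list(disruption_p1 = d1, disruption_p2 = d2,
       ratio = if (d2 == 0) Inf else d1 / d2)
}
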