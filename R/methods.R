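#' @export
print.bir_fit <- function(x, digits = 4, ...) {
  cat("Biphasic exponential model of BIR efficiency\n")
  cat("  replicate observations:", nrow(x$data),
      " distinct distances:", length(x$distances), "\n")
  if (x$selected == "single") {
    cat("  selected: single exponential  E(d) = k * p^d\n")
    cat(sprintf("    k = %.*g   p = %.*g\n", digits, x$model$k, digits, x$model$p1))
  } else {
    m <- x$model
    cat(sprintf("  selected: two segments (first %d distances)\n", m$split_index))
    cat(sprintf("    k  = %.*g\n    p1 = %.*g\n    p2 = %.*g\n    T  = %.*g kb\n",
                digits, m$k, digits, m$p1, digits, m$p2, digits, m$T_kb))
  }
  aic <- x$table$aic[match(x$selected, x$table$model)]
  cat(sprintf("  AIC (%s variance): %.1f\n", x$aic_method, aic))
  invisible(x)
}

#' @export
coef.bir_fit <- function(object, ...) {
  m <- object$model
  if (object$selected == "single") c(k = m$k, p = m$p1)
  else c(k = m$k, p1 = m$p1, p2 = m$p2, T_kb = m$T_kb)
}

#' @export
summary.bir_fit <- function(object, ...) {
  m <- object$model
  se <- if (is.null(object$segments)) {
    c(k = object$single$se[["a"]], p1 = object$single$se[["p"]],
      p2 = NA_real_)
  } else {
    c(k = object$segments$seg1$se[["a"]], p1 = object$segments$seg1$se[["p"]],
      p2 = object$segments$seg2$se[["p"]])
  }
  disr <- if (object$selected != "single") disruption_probabilities(object) else NULL
  structure(list(fit = object, coef = coef(object), se = se,
                 disruption = disr, table = object$table),
            class = "summary.bir_fit")
}

#' @export
print.summary.bir_fit <- function(x, ...) {
  print(x$fit)
  cat("\nStandard errors (from nonlinear least squares):\n")
  print(signif(x$se, 3))
  if (!is.null(x$disruption)) {
    cat(sprintf("\nPer-kb disruption: phase 1 %.3g, phase 2 %.3g (ratio %.3g)\n",
                x$disruption$disruption_p1, x$disruption$disruption_p2,
                x$disruption$ratio))
  }
  cat("\nModel comparison (delta AIC to best; * within 1 unit):\n")
  tab <- x$table
  tab$aic <- round(tab$aic, 1)
  tab$delta_aic <- round(tab$delta_aic, 2)
  tab$near_tie <- ifelse(tab$near_tie, "*", "")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
predict.bir_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$distance_kb
       else if (is.numeric(newdata)) newdata
       else newdata$distance_kb
  predict_efficiency(object, d)
}

#' @export
fitted.bir_fit <- function(object, ...) predict(object)

#' @export
residuals.bir_fit <- function(object, ...)
  object$data$efficiency - fitted(object)

#' Gaussian log-likelihood of the selected model
#'
#' For the two-segment model the segments are independent Gaussian fits,
#' each with its own maximum-likelihood variance, so the log-likelihood is
#' the sum over segments and `stats::AIC()` on a `bir_fit` reproduces the
#' convention of [bir_aic()].
#' @param object a [bir_fit].
#' @param ... unused.
#' @export
logLik.bir_fit <- function(object, ...) {
  ll_seg <- function(s) {
    n <- s$n_points
    -n / 2 * (log(2 * pi) + 1 + log(s$rss / n))
  }
  if (object$selected == "single") {
    val <- ll_seg(object$single); df <- 3L
  } else {
    val <- ll_seg(object$segments$seg1) + ll_seg(object$segments$seg2)
    df <- 6L
  }
  structure(val, df = df, nobs = nrow(object$data), class = "logLik")
}

#' Plot a fitted BIR efficiency model
#'
#' Per-locus mean efficiencies (points, with replicate-range whiskers) and
#' the fitted curve(s) versus distance to telomere.
#'
#' @param x a [bir_fit].
#' @param log_y plot the efficiency axis on a log scale.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bir_fit <- function(x, log_y = FALSE, ...) {
  d <- x$data$distance_kb; e <- x$data$efficiency
  mns <- tapply(e, d, mean)
  dd <- as.numeric(names(mns))
  graphics::plot(dd, mns, xlab = "distance to telomere (kb)",
                 ylab = "BIR efficiency", log = if (log_y) "y" else "",
                 pch = 19, ...)
  grid_d <- seq(min(d), max(d), length.out = 400)
  if (x$selected == "single") {
    graphics::lines(grid_d, predict_efficiency(x, grid_d), col = 2)
  } else {
    m <- x$model
    g1 <- grid_d[grid_d <= m$T_kb]; g2 <- grid_d[grid_d >= m$T_kb]
    graphics::lines(g1, m$k * m$p1^g1, col = 2)
    graphics::lines(g2, m$k * m$p1^m$T_kb * m$p2^(g2 - m$T_kb), col = 4)
    graphics::abline(v = m$T_kb, lty = 3)
  }
  invisible(x)
}

#' Simulate transformation experiments from a fitted model
#'
#' Draws new replicate-level datasets from the per-kb survival chain at the
#' fitted parameters, at the fitted distances (see [simulate_experiment()]).
#'
#' @param object a [bir_fit].
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param replicates,attempts experiments per locus and expected
#'   transformation-competent events per plate.
#' @param ... unused.
#' @return list of `nsim` efficiency datasets.
#' @export
simulate.bir_fit <- function(object, nsim = 1, seed = 1L,
                             replicates = 8L, attempts = 200, ...) {
  m <- object$model
  cfg <- bir_sim_config(k = m$k, p1 = m$p1,
                        p2 = if (is.na(m$p2)) m$p1 else m$p2,
                        T_kb = if (is.na(m$T_kb)) Inf else m$T_kb,
                        distances_kb = object$distances,
                        attempts = attempts, replicates = replicates,
                        seed = seed)
  lapply(seq_len(nsim), function(i) {
    cfg$seed <- seed + i - 1L
    simulate_experiment(cfg)
  })
}
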