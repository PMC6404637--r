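#' Correlation magnitude between excitatory and inhibitory current traces
#'
#' The standard product-moment correlation, reported as an absolute value
#' (excitatory and inhibitory inputs are anticorrelated in sign; the
#' magnitude measures how closely inhibition tracks excitation).
#' `method = "variance_sum"` divides the covariance by the sum of the two
#' variances instead of the product of the standard deviations; it is kept
#' for audit only, as it is not bounded by 1.
#'
#' @param e_trace,i_trace equal-length numeric series (length >= 3).
#' @param method `"pearson"` (default) or `"variance_sum"`.
#' @return `|rho|`, or `NA` (with a warning) if either series is constant.
#' @examples
#' ei_correlation(1:10, -2 * (1:10))  # 1
#' @export
ei_correlation <- function(e_trace, i_trace,
                           method = c("pearson", "variance_sum")) {
  method <- match.arg(method)
  if (length(e_trace) != length(i_trace))
    stop("current traces must have equal length")
  if (length(e_trace) < 3) stop("need at least 3 samples")
  if (sd(e_trace) == 0 || sd(i_trace) == 0) {
    warning("constant current trace: correlation undefined")
    return(NA_real_)
  }
  if (method == "pearson") abs(cor(e_trace, i_trace))
  else abs(cov(e_trace, i_trace) / (var(e_trace) + var(i_trace)))
}

#' Per-population excitatory/inhibitory current balance
#'
#' For every recorded neuron, correlates its excitatory against its
#' inhibitory input-current trace over `window` and summarises `|rho|`
#' per population.  Channel composition: with `variant = "total"` the
#' excitatory trace is recurrent excitation plus external drive and the
#' inhibitory trace is recurrent inhibition plus leak (set
#' `include_leak = FALSE` to drop the leak); with
#' `variant = "recurrent_only"` only the two recurrent channels enter.
#'
#' @param result a [run_simulation()] result with recorded currents.
#' @param variant `"total"` or `"recurrent_only"`.
#' @param window `c(start, end)` ms; default the full run.
#' @param include_leak include the leak current on the inhibitory side of
#'   the `"total"` variant.
#' @return An object of class `balance_metrics`: `per_neuron` (data frame
#'   `neuron`, `population`, `rho`) and `summary` (per-population mean,
#'   SD, n of `|rho|`), plus the variant and window.
#' @export
population_balance <- function(result, variant = c("total", "recurrent_only"),
                               window = NULL, include_leak = TRUE) {
  stopifnot(inherits(result, "sim_result"))
  variant <- match.arg(variant)
  cur <- result$currents
  if (is.null(cur))
    stop("no current traces recorded; rerun with `record_currents`")
  for (ch in c("rec_exc", "rec_inh", "external", "leak"))
    if (is.null(cur[[ch]])) stop("missing current channel: ", ch)
  if (is.null(window)) window <- c(0, result$duration)
  keep <- cur$time >= window[1] & cur$time <= window[2]
  if (sum(keep) < 3) stop("analysis window shorter than 3 current bins")

  e_mat <- cur$rec_exc[keep, , drop = FALSE]
  i_mat <- cur$rec_inh[keep, , drop = FALSE]
  if (variant == "total") {
    e_mat <- e_mat + cur$external[keep, , drop = FALSE]
    if (include_leak) i_mat <- i_mat + cur$leak[keep, , drop = FALSE]
  }
  rho <- vapply(seq_len(ncol(e_mat)), function(j) {
    if (sd(e_mat[, j]) == 0 || sd(i_mat[, j]) == 0) return(NA_real_)
    abs(cor(e_mat[, j], i_mat[, j]))
  }, 0)
  pn <- data.frame(neuron = cur$neurons,
                   population = result$layout$labels[cur$neurons],
                   rho = rho)
  agg <- do.call(rbind, lapply(split(pn$rho, droplevels(pn$population)),
                               function(v) {
    v <- v[is.finite(v)]
    data.frame(mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               n = length(v))
  }))
  agg$population <- rownames(agg)
  rownames(agg) <- NULL
  structure(list(per_neuron = pn,
                 summary = agg[, c("population", "mean", "sd", "n")],
                 variant = variant, window = window),
            class = "balance_metrics")
}

#' @export
print.balance_metrics <- function(x, ...) {
  cat(sprintf("<balance_metrics> variant = %s, window = [%g, %g] ms\n",
              x$variant, x$window[1], x$window[2]))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Coefficient of variation of inter-spike intervals
#'
#' Per-neuron inter-spike intervals within `window` are pooled (or the CV
#' is averaged per neuron) and the coefficient of variation `sd/mean` of
#' the interval distribution is returned.  A perfectly periodic train has
#' CV 0, a Poisson train CV 1; larger CV marks more irregular, balanced
#' activity.
#'
#' @param spikes a data frame with `time` and `neuron` columns (e.g. from
#'   [population_spikes()]), or a bare numeric vector of spike times of a
#'   single train.
#' @param window optional `c(start, end)` ms restriction.
#' @param per_neuron if `TRUE`, compute one CV per neuron (needing >= 2
#'   intervals) and average; default pools all intervals.
#' @return An object of class `isi_stats`: `cv`, `mean`, `sd`, `n`
#'   (number of intervals), `isi` (the pooled intervals).
#' @examples
#' isi_cv(seq(0, 1000, by = 10))$cv  # periodic -> 0
#' @export
isi_cv <- function(spikes, window = NULL, per_neuron = FALSE) {
  if (is.numeric(spikes)) spikes <- data.frame(time = spikes, neuron = 1L)
  if (!is.null(window))
    spikes <- spikes[spikes$time > window[1] & spikes$time <= window[2], ]
  isi_by_neuron <- lapply(split(spikes$time, spikes$neuron),
                          function(t) diff(sort(t)))
  pooled <- unlist(isi_by_neuron, use.names = FALSE)
  if (length(pooled) < 1) stop("no inter-spike intervals in the window")
  if (per_neuron) {
    cvs <- vapply(isi_by_neuron, function(v)
      if (length(v) >= 2) sd(v) / mean(v) else NA_real_, 0)
    cv <- mean(cvs, na.rm = TRUE)
  } else {
    cv <- if (length(pooled) >= 2) sd(pooled) / mean(pooled) else 0
  }
  structure(list(cv = cv, mean = mean(pooled), sd = sd(pooled),
                 n = length(pooled), isi = pooled), class = "isi_stats")
}

#' @export
print.isi_stats <- function(x, ...) {
  cat(sprintf("<isi_stats> CV = %.4g (mean %.4g ms, n = %d intervals)\n",
              x$cv, x$mean, x$n))
  invisible(x)
}
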