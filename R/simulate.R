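#' Memory-specific stimulus
#'
#' During the stimulus the target population's external mean drive is
#' multiplied by the contrast factor `A_cue` while its standard deviation
#' is unchanged.
#'
#' @param population target population label (e.g. `"Es1"`).
#' @param onset stimulus onset (ms).
#' @param duration stimulus duration (ms, >= 0).
#' @param contrast contrast factor `A_cue >= 1` (reference strengths:
#'   1.10 and 1.15).
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(population, onset, duration, contrast = 1.10) {
  if (duration < 0) stop("`duration` must be >= 0")
  if (contrast < 1) stop("`contrast` must be >= 1")
  if (onset < 0) stop("`onset` must be >= 0")
  structure(list(population = population, onset = onset,
                 duration = duration, contrast = contrast),
            class = "stimulus_protocol")
}

#' Simulate the network
#'
#' Integrates the leaky integrate-and-fire dynamics with delayed delta
#' synapses, Gaussian external drive, and presynaptic short-term
#' facilitation/depression on all E-to-E synapses, by forward Euler at
#' step `dt`.  The dopamine factors `A_EE` and `A_EI` multiply all E-to-E
#' and E-to-I efficacies; I-to-E and I-to-I are never scaled.
#'
#' @param spec a [network_spec()].
#' @param synapses a [sample_connectivity()] result built with the same
#'   `dt`.
#' @param A_EE,A_EI dopamine scaling factors (dimensionless multipliers).
#' @param stimuli a [stimulus_protocol()] or list of them (or `NULL`).
#' @param duration simulated time (ms), a multiple of `dt`.
#' @param dt integration step (ms); default 0.1.
#' @param seed integer seed (mandatory; identical inputs and seed give a
#'   bit-identical raster).
#' @param record_currents neuron indices (1-based) whose decomposed input
#'   currents are recorded, or `NULL` for none.
#' @param sample_ms bin width (ms) for current and short-term-plasticity
#'   traces.
#' @param v_guard abort with a diagnostic if any `|V|` exceeds this bound
#'   (mV).
#' @return An object of class `sim_result`: `spikes` (data frame `time`,
#'   `neuron`, `population`), `currents` (list of bin-summed matrices
#'   `rec_exc`, `rec_inh`, `external`, `leak`, rows = bins, columns =
#'   recorded neurons, plus `neurons` and `time`), `stp` (per-E-population
#'   mean `u` and `x` traces), `layout`, `duration`, `dt`, `seed`,
#'   `A_EE`, `A_EI`.
#' @examples
#' spec <- network_spec(N_E = 200, N_I = 50, c = 0.2)
#' lay <- build_layout(spec)
#' syn <- sample_connectivity(spec, lay, seed = 1)
#' res <- run_simulation(spec, syn, duration = 300, seed = 1)
#' nrow(res$spikes)
#' @export
run_simulation <- function(spec, synapses, A_EE = 1, A_EI = 1,
                           stimuli = NULL, duration = 2000, dt = 0.1,
                           seed, record_currents = NULL, sample_ms = 5,
                           v_guard = 1e3) {
  stopifnot(inherits(spec, "network_spec"),
            inherits(synapses, "synapse_table"))
  if (missing(seed) || length(seed) != 1 || !is.finite(seed) ||
      seed != round(seed))
    stop("`seed` must be a single integer (reproducibility contract)")
  if (dt <= 0) stop("`dt` must be positive")
  if (abs(duration / dt - round(duration / dt)) > 1e-6)
    stop("`duration` must be a multiple of `dt`")
  if (abs(synapses$dt - dt) > 1e-12)
    stop("synapse table was quantized at dt = ", synapses$dt,
         " ms; rebuild it for dt = ", dt)
  layout <- build_layout(spec)
  if (length(synapses$ptr) - 1L != layout$n)
    stop("synapse table size does not match the network spec")

  if (inherits(stimuli, "stimulus_protocol")) stimuli <- list(stimuli)
  stim_mat <- matrix(0, nrow = length(stimuli), ncol = 4)
  for (k in seq_along(stimuli)) {
    s <- stimuli[[k]]
    stopifnot(inherits(s, "stimulus_protocol"))
    row <- layout$table[layout$table$label == s$population, ]
    if (nrow(row) != 1) stop("unknown stimulus population: ", s$population)
    stim_mat[k, ] <- c(row$pop, s$onset, s$onset + s$duration, s$contrast)
  }

  is_E <- layout$pop < spec$p + 1L
  cls <- ifelse(is_E, 1L, 2L)  # 1 = E, 2 = I
  rec <- if (is.null(record_currents)) integer(0) else {
    rc <- as.integer(record_currents)
    if (any(rc < 1 | rc > layout$n)) stop("`record_currents` out of range")
    rc - 1L
  }

  raw <- cpp_run_network(unclass(synapses), layout$pop, spec$N_E,
                         spec$p + 1L,
                         spec$theta[cls], spec$V_r[cls], spec$tau_m[cls],
                         spec$mu_ext[cls], spec$sigma_ext[cls],
                         A_EE, A_EI, stim_mat, duration, dt,
                         spec$tau_arp, spec$U, spec$X,
                         spec$tau_u, spec$tau_x,
                         rec, sample_ms, seed, v_guard)

  neuron <- raw$spike_id + 1L
  spikes <- data.frame(time = raw$spike_t, neuron = neuron,
                       population = layout$labels[neuron])
  bin_t <- (seq_len(raw$n_bins) - 0.5) * raw$sample_ms
  pops_E <- layout$table$label[seq_len(spec$p + 1L)]
  colnames(raw$u_mean) <- colnames(raw$x_mean) <- pops_E
  currents <- NULL
  stp_rec <- NULL
  if (length(rec)) {
    currents <- list(rec_exc = raw$cur_rec_exc, rec_inh = raw$cur_rec_inh,
                     external = raw$cur_external, leak = raw$cur_leak,
                     neurons = rec + 1L, time = bin_t)
    is_rec_E <- rec + 1L <= spec$N_E
    u_rec <- raw$u_rec; x_rec <- raw$x_rec
    u_rec[, !is_rec_E] <- NA_real_; x_rec[, !is_rec_E] <- NA_real_
    stp_rec <- list(u = u_rec, x = x_rec, neurons = rec + 1L, time = bin_t)
  }
  structure(list(spikes = spikes, currents = currents,
                 stp = list(u = raw$u_mean, x = raw$x_mean, time = bin_t),
                 stp_rec = stp_rec,
                 V_final = raw$V_final,
                 layout = layout, duration = duration, dt = dt,
                 sample_ms = raw$sample_ms, seed = as.integer(seed),
                 A_EE = A_EE, A_EI = A_EI,
                 stimuli = stimuli), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %g ms at dt = %g ms, %d neurons, %d spikes (seed %d)\n",
              x$duration, x$dt, x$layout$n, nrow(x$spikes), x$seed))
  cat(sprintf("  A_EE = %.4g, A_EI = %.4g\n", x$A_EE, x$A_EI))
  invisible(x)
}

#' Mean firing rate of a population over a time window
#'
#' @param result a [run_simulation()] result.
#' @param population population label.
#' @param window `c(start, end)` in ms; default the full run.
#' @return Rate in Hz (spikes per neuron per second).
#' @export
population_rate <- function(result, population, window = NULL) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(window)) window <- c(0, result$duration)
  idx <- population_neurons(result$layout, population)
  if (!length(idx)) return(NA_real_)
  sp <- result$spikes
  n <- sum(sp$neuron %in% idx & sp$time > window[1] & sp$time <= window[2])
  n / length(idx) / (diff(window) / 1000)
}

#' Sliding-window rate trace of a population
#'
#' @inheritParams population_rate
#' @param width window width (ms).
#' @param step window step (ms).
#' @return Data frame `time` (window centre, ms), `rate` (Hz).
#' @export
rate_trace <- function(result, population, width = 100, step = 20) {
  stopifnot(inherits(result, "sim_result"))
  idx <- population_neurons(result$layout, population)
  sp <- result$spikes
  t <- sp$time[sp$neuron %in% idx]
  starts <- seq(0, max(result$duration - width, 0), by = step)
  rate <- vapply(starts, function(s)
    sum(t > s & t <= s + width) / length(idx) / (width / 1000), 0)
  data.frame(time = starts + width / 2, rate = rate)
}

#' Restrict spike times to one population and window
#'
#' @inheritParams population_rate
#' @return Data frame `time`, `neuron` (sorted by time).
#' @export
population_spikes <- function(result, population, window = NULL) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(window)) window <- c(0, result$duration)
  idx <- population_neurons(result$layout, population)
  sp <- result$spikes
  keep <- sp$neuron %in% idx & sp$time > window[1] & sp$time <= window[2]
  out <- sp[keep, c("time", "neuron")]
  out[order(out$time), ]
}

#' Write / read a spike raster as delimited text
#'
#' Tab-separated with header `time_ms`, `neuron_id`, `population`; floats
#' at full precision.
#'
#' @param result a [run_simulation()] result (or a data frame with those
#'   columns).
#' @param path file path.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns
#'   the data frame.
#' @export
write_raster <- function(result, path) {
  df <- if (inherits(result, "sim_result")) {
    data.frame(time_ms = result$spikes$time, neuron_id = result$spikes$neuron,
               population = result$spikes$population)
  } else result
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
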