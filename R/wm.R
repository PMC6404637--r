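# System-level working-memory protocols: phase classification and sweeps,
# loading/updating trials, stimulus-duration thresholds, and the internal
# state metrics of the stimulated population.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 104729 * k) %% 2147483647)
}

#' Most active selective population
#'
#' @param result a [run_simulation()] result.
#' @param window `c(start, end)` ms; default everything after a 200 ms
#'   burn-in.
#' @return Label of the selective (Es) population with the highest mean
#'   firing rate in the window.
#' @export
most_active_es <- function(result, window = NULL) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(window)) window <- c(min(200, result$duration / 2),
                                   result$duration)
  labs <- paste0("Es", seq_len(result$layout$p))
  rates <- vapply(labs, function(l) population_rate(result, l, window), 0)
  labs[which.max(rates)]
}

#' Classify the resting regime of a run
#'
#' `phase1` is the quiescent regime (sparse noise-driven firing); `phase2`
#' the regime in which a selective population reverberates at high rate
#' without an external stimulus (self-sustained activity, including
#' transient spontaneous reactivations - "imaginary memory").  The run is
#' `phase2` iff some selective population sustains a mean rate at or
#' above `rate_threshold` (inclusive boundary) in at least one sliding
#' sub-window of width `sustain_ms` inside the final evaluation window.
#'
#' The defaults (12 Hz sustained over a 500 ms window) mark the clearly
#' separated self-sustained regime: the marginal reverberation band that
#' borders the transition (~8-12 Hz) produces only brief fluctuation
#' peaks above 12 Hz, never a sustained half-second of them.
#'
#' @param result a [run_simulation()] result covering a stimulus-free
#'   interval at its end.
#' @param rate_threshold phase2 rate criterion (Hz).
#' @param window_ms length of the final evaluation window (ms); defaults
#'   to everything after a 200 ms burn-in.
#' @param sustain_ms width of the sliding sub-window an ignition must
#'   fill (ms).
#' @return `"phase1"` or `"phase2"`.
#' @export
classify_phase <- function(result, rate_threshold = 12, window_ms = NULL,
                           sustain_ms = 500) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(window_ms)) window_ms <- result$duration - 200
  if (window_ms > result$duration)
    stop("evaluation window longer than the simulation")
  from <- result$duration - window_ms
  labs <- paste0("Es", seq_len(result$layout$p))
  for (l in labs) {
    tr <- rate_trace(result, l, width = sustain_ms, step = sustain_ms / 4)
    tr <- tr[tr$time - sustain_ms / 2 >= from, ]
    if (nrow(tr) && max(tr$rate) >= rate_threshold) return("phase2")
  }
  "phase1"
}

#' Sweep the EE-EI plane for the phase map
#'
#' Runs one resting simulation per grid cell of dopamine scaling factors
#' and records the rate of the most active selective population, the
#' branching parameter of its avalanches, and the phase label.  Per-cell
#' failures are recorded (`NA` entries) without aborting the sweep.
#'
#' @param spec,synapses network and connectivity (see
#'   [sample_connectivity()]).
#' @param A_EE_grid,A_EI_grid numeric grids of scaling factors.
#' @param duration per-cell simulation length (ms).
#' @param seed base seed; each cell runs with a seed derived from it.
#' @param burn_in interval (ms) discarded before analysis.
#' @param rate_threshold phase2 criterion (Hz).
#' @param dt_bin avalanche bin width (ms).
#' @return A data frame of class `phase_map`: `A_EE`, `A_EI`, `rate`
#'   (Hz), `sigma`, `phase`.
#' @export
sweep_phase_map <- function(spec, synapses, A_EE_grid, A_EI_grid,
                            duration = 1500, seed = 1, burn_in = 200,
                            rate_threshold = 12, dt_bin = 0.3) {
  grid <- expand.grid(A_EE = A_EE_grid, A_EI = A_EI_grid)
  grid$rate <- NA_real_; grid$sigma <- NA_real_
  grid$phase <- NA_character_
  for (k in seq_len(nrow(grid))) {
    cell <- try({
      res <- run_simulation(spec, synapses, A_EE = grid$A_EE[k],
                            A_EI = grid$A_EI[k], duration = duration,
                            seed = derive_seed(seed, k))
      lab <- most_active_es(res)
      sp <- population_spikes(res, lab, c(burn_in, duration))
      av <- detect_avalanches(sp$time, dt_bin)
      list(rate = population_rate(res, lab,
                                  c(duration - 500, duration)),
           sigma = if (length(av$sizes)) branching_parameter(av)$sigma
                   else NA_real_,
           phase = classify_phase(res, rate_threshold))
    }, silent = TRUE)
    if (!inherits(cell, "try-error")) {
      grid$rate[k] <- cell$rate
      grid$sigma[k] <- cell$sigma
      grid$phase[k] <- cell$phase
    }
  }
  class(grid) <- c("phase_map", "data.frame")
  grid
}

#' One working-memory loading (or updating) trial
#'
#' Timeline: a burn-in resting interval, then a contrast stimulus of
#' duration `stim_duration` to `target`, then `post` ms without stimulus.
#' If `prior` is given, that population is first driven into the active
#' state by a separate strong loading stimulus, turning the trial into an
#' updating trial.
#'
#' Success criteria (configurable, stated here as the defaults):
#' *loaded* requires the target population's rate to stay at or above
#' `load_rate` (5 Hz, separating the quiescent rate, well under 2 Hz, from
#' the reverberating attractor rate of roughly 8-11 Hz) in every sliding
#' 100-ms window from 200 ms after
#' stimulus offset to the trial end; *updated* additionally requires the
#' previously active population's rate to fall below `off_rate` (3 Hz)
#' over the final 300 ms.
#'
#' @param spec,synapses network and connectivity.
#' @param A_EE,A_EI dopamine scaling factors.
#' @param target stimulated population label.
#' @param stim_duration stimulus duration (ms).
#' @param contrast stimulus contrast factor.
#' @param seed integer seed.
#' @param prior label of a population to load first (updating trials), or
#'   `NULL`.
#' @param prior_duration,prior_contrast loading stimulus for `prior`.
#' @param burn_in resting interval before the (first) stimulus (ms).
#' @param gap interval between the prior loading stimulus and the target
#'   stimulus (ms).
#' @param post interval simulated after stimulus offset (ms).
#' @param load_rate,off_rate,settle success-criterion parameters: minimal
#'   persistent rate (Hz), maximal rate of the switched-off population
#'   (Hz), and the delay after offset before persistence is assessed (ms).
#' @param win_width,win_step sliding rate window (ms).
#' @return An object of class `wm_trial`: flags `loaded` and `updated`,
#'   the target rate trace, the offset time, and the criterion parameters.
#' @export
wm_trial <- function(spec, synapses, A_EE, A_EI, target = "Es1",
                     stim_duration, contrast = 1.10, seed,
                     prior = NULL, prior_duration = 300,
                     prior_contrast = 1.15,
                     burn_in = 200, gap = 500, post = 1000,
                     load_rate = 5, off_rate = 3, settle = 200,
                     win_width = 100, win_step = 20) {
  stims <- list()
  t0 <- burn_in
  if (!is.null(prior)) {
    stims <- c(stims, list(stimulus_protocol(prior, t0, prior_duration,
                                             prior_contrast)))
    t0 <- t0 + prior_duration + gap
  }
  onset <- t0
  offset <- onset + stim_duration
  if (stim_duration > 0)
    stims <- c(stims, list(stimulus_protocol(target, onset, stim_duration,
                                             contrast)))
  duration <- offset + post
  res <- run_simulation(spec, synapses, A_EE = A_EE, A_EI = A_EI,
                        stimuli = if (length(stims)) stims else NULL,
                        duration = duration, seed = seed)
  trace <- rate_trace(res, target, width = win_width, step = win_step)
  eval_from <- offset + settle
  persist <- trace[trace$time - win_width / 2 >= eval_from, ]
  loaded <- nrow(persist) > 0 && all(persist$rate >= load_rate)
  updated <- NA
  if (!is.null(prior)) {
    prior_rate <- population_rate(res, prior, c(duration - 300, duration))
    updated <- loaded && prior_rate < off_rate
  }
  structure(list(loaded = loaded, updated = updated, trace = trace,
                 offset = offset, duration = duration,
                 criteria = list(load_rate = load_rate, off_rate = off_rate,
                                 settle = settle, win_width = win_width,
                                 win_step = win_step),
                 result = res), class = "wm_trial")
}

# Majority success over k seeds for a probe duration.
probe_success <- function(T, k, seed, trial_fun) {
  if (T <= 0) return(FALSE)
  ok <- vapply(seq_len(k), function(r) trial_fun(T, derive_seed(seed, r)), NA)
  sum(ok) > k / 2
}

# Shared search machinery: minimal duration for which majority success
# holds, at `resolution` ms.  Success is not guaranteed monotone in the
# duration (an overlong stimulus depletes synaptic resources and the
# trace can collapse at offset), so the succeeding upper bound is located
# by doubling from the resolution upward before bisecting the monotone
# low region between the last failure and the first success.
bisect_duration <- function(bounds, resolution, k, seed, trial_fun) {
  lo <- bounds[1]
  probe <- max(resolution, 1)
  hi <- NA_real_
  while (probe <= bounds[2]) {
    if (probe_success(probe, k, seed, trial_fun)) { hi <- probe; break }
    lo <- probe
    probe <- probe * 2
  }
  if (is.na(hi) && probe / 2 < bounds[2]) {
    if (probe_success(bounds[2], k, seed, trial_fun)) hi <- bounds[2]
    else lo <- bounds[2]
  }
  if (is.na(hi)) return(NA_real_)
  while (hi - lo > resolution) {
    mid <- round((lo + hi) / 2)
    if (probe_success(mid, k, seed, trial_fun)) hi <- mid else lo <- mid
  }
  hi
}

#' Minimal stimulus duration to load an item (T_sens)
#'
#' Bisects the stimulus duration between a failing lower and a succeeding
#' upper bound; success at a probe duration is decided by majority over
#' `n_probe_seeds` independent trials.  The resting network must be in
#' phase1 (otherwise the regime produces "imaginary memory" and loading is
#' ill-defined).  WM sensitivity is `1 / T_sens`.
#'
#' @inheritParams wm_trial
#' @param bounds `c(lower, upper)` search interval (ms); the upper bound
#'   must load, else the sentinel `NA` ("not loadable at this dopamine
#'   level") is returned.
#' @param resolution bisection resolution (ms).
#' @param n_probe_seeds trials per probe duration (majority vote).
#' @param check_rest verify the resting state is phase1 first.
#' @param ... further arguments passed to [wm_trial()].
#' @return `T_sens` in ms, or `NA` if the upper bound never loads.
#' @export
measure_t_sens <- function(spec, synapses, A_EE, A_EI, target = "Es1",
                           contrast = 1.10, bounds = c(0, 400),
                           resolution = 1, n_probe_seeds = 3, seed = 1,
                           check_rest = TRUE, ...) {
  if (check_rest) {
    rest <- run_simulation(spec, synapses, A_EE = A_EE, A_EI = A_EI,
                           duration = 1000, seed = derive_seed(seed, 999))
    if (classify_phase(rest) == "phase2")
      stop("resting state is phase2 (imaginary-memory regime); ",
           "T_sens is undefined")
  }
  trial_fun <- function(T, s)
    wm_trial(spec, synapses, A_EE, A_EI, target = target,
             stim_duration = T, contrast = contrast, seed = s, ...)$loaded
  bisect_duration(bounds, resolution, n_probe_seeds, seed, trial_fun)
}

#' Minimal stimulus duration to update a held item (T_flexi)
#'
#' An item is first loaded into `prior`; the minimal duration of a
#' stimulus to `target` after which `target` is persistently active and
#' `prior` has shut down is then bisected.  WM flexibility is the
#' reciprocal of `T_flexi` normalized by its minimum over the dopamine
#' grid.
#'
#' @inheritParams measure_t_sens
#' @param prior the initially loaded population.
#' @return `T_flexi` in ms, or `NA` if the upper bound never updates.
#' @export
measure_t_flexi <- function(spec, synapses, A_EE, A_EI, target = "Es2",
                            prior = "Es1", contrast = 1.10,
                            bounds = c(0, 400), resolution = 1,
                            n_probe_seeds = 3, seed = 1, ...) {
  trial_fun <- function(T, s) {
    tr <- wm_trial(spec, synapses, A_EE, A_EI, target = target,
                   stim_duration = T, contrast = contrast, seed = s,
                   prior = prior, ...)
    isTRUE(tr$updated)
  }
  bisect_duration(bounds, resolution, n_probe_seeds, seed, trial_fun)
}

#' Internal state metrics of a stimulated population
#'
#' Means over neurons and time, within `window`, of the firing rate `f`,
#' utilization `u`, available resources `x`, the transmitter released per
#' spike `ux`, and the total transmitter turnover `uxf` of one population.
#' Per-neuron standard deviations accompany every mean (the run must
#' record currents/STP for the population's neurons, see
#' `record_currents` in [run_simulation()]).
#'
#' @param result a [run_simulation()] result with per-neuron STP
#'   recording covering the population.
#' @param population population label (excitatory).
#' @param window `c(start, end)` ms.
#' @return A one-row data frame with columns `f`, `u`, `x`, `ux`, `uxf`
#'   and their `*_sd` companions.
#' @export
wm_state_metrics <- function(result, population, window) {
  stopifnot(inherits(result, "sim_result"))
  if (window[2] <= window[1]) stop("empty analysis window")
  idx <- population_neurons(result$layout, population)
  sp <- result$spikes
  counts <- tabulate(match(sp$neuron[sp$time > window[1] &
                                       sp$time <= window[2]], idx),
                     nbins = length(idx))
  f_i <- counts / (diff(window) / 1000)          # Hz per neuron
  if (is.null(result$stp_rec) ||
      !all(idx %in% result$stp_rec$neurons))
    stop("per-neuron STP traces not recorded for population ", population,
         "; rerun with record_currents covering it")
  cols <- match(idx, result$stp_rec$neurons)
  keep <- result$stp_rec$time >= window[1] & result$stp_rec$time <= window[2]
  u_i <- colMeans(result$stp_rec$u[keep, cols, drop = FALSE])
  x_i <- colMeans(result$stp_rec$x[keep, cols, drop = FALSE])
  ux_i <- colMeans(result$stp_rec$u[keep, cols, drop = FALSE] *
                     result$stp_rec$x[keep, cols, drop = FALSE])
  uxf_i <- ux_i * f_i
  data.frame(f = mean(f_i), f_sd = sd(f_i),
             u = mean(u_i), u_sd = sd(u_i),
             x = mean(x_i), x_sd = sd(x_i),
             ux = mean(ux_i), ux_sd = sd(ux_i),
             uxf = mean(uxf_i), uxf_sd = sd(uxf_i))
}

#' Dose-response of working memory over a dopamine grid
#'
#' For each activation level the scaling factors are evaluated and the
#' requested measurements are run: `T_sens` (with sensitivity
#' `1/T_sens`), `T_flexi` (with its normalized form, minimum exactly 1
#' over the grid, and flexibility = its reciprocal), and the internal
#' metrics of the stimulated population under a fixed reference stimulus.
#'
#' @param spec,synapses network and connectivity.
#' @param params a [da_params()].
#' @param D_grid activation levels to evaluate.
#' @param contrast stimulus contrast factor.
#' @param measure character subset of `c("t_sens", "t_flexi", "metrics")`.
#' @param metric_stim_duration duration (ms) of the fixed stimulus used
#'   for the internal metrics.
#' @param seed base seed.
#' @param ... passed to [measure_t_sens()] / [measure_t_flexi()].
#' @return A data frame of class `dose_response` with one row per
#'   activation level.
#' @export
dose_response <- function(spec, synapses, params, D_grid = seq(0, 2, 0.1),
                          contrast = 1.10,
                          measure = c("t_sens"),
                          metric_stim_duration = 200, seed = 1, ...) {
  sf <- scaling_factors(D_grid, params)
  out <- sf
  if ("t_sens" %in% measure) {
    out$T_sens <- vapply(seq_along(D_grid), function(i)
      tryCatch(measure_t_sens(spec, synapses, sf$A_EE[i], sf$A_EI[i],
                              contrast = contrast,
                              seed = derive_seed(seed, i), ...),
               error = function(e) NA_real_), 0)
    out$sensitivity <- 1 / out$T_sens
  }
  if ("t_flexi" %in% measure) {
    out$T_flexi <- vapply(seq_along(D_grid), function(i)
      tryCatch(measure_t_flexi(spec, synapses, sf$A_EE[i], sf$A_EI[i],
                               contrast = contrast,
                               seed = derive_seed(seed, 500 + i), ...),
               error = function(e) NA_real_), 0)
    mn <- suppressWarnings(min(out$T_flexi, na.rm = TRUE))
    out$T_flexi_norm <- out$T_flexi / mn
    out$flexibility <- 1 / out$T_flexi_norm
  }
  if ("metrics" %in% measure) {
    lay <- build_layout(spec)
    rec <- population_neurons(lay, "Es1")
    met <- lapply(seq_along(D_grid), function(i) {
      tr <- tryCatch({
        stim <- stimulus_protocol("Es1", 200, metric_stim_duration, contrast)
        res <- run_simulation(spec, synapses, A_EE = sf$A_EE[i],
                              A_EI = sf$A_EI[i], stimuli = stim,
                              duration = 200 + metric_stim_duration + 100,
                              seed = derive_seed(seed, 900 + i),
                              record_currents = rec)
        wm_state_metrics(res, "Es1",
                         c(200, 200 + metric_stim_duration))
      }, error = function(e) NULL)
      if (is.null(tr)) data.frame(f = NA, f_sd = NA, u = NA, u_sd = NA,
                                  x = NA, x_sd = NA, ux = NA, ux_sd = NA,
                                  uxf = NA, uxf_sd = NA)
      else tr
    })
    out <- cbind(out, do.call(rbind, met))
  }
  class(out) <- c("dose_response", "data.frame")
  out
}
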