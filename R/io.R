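# Configuration handling, experiment orchestration, and serialization.

#' Assemble and validate an experiment configuration
#'
#' A configuration fully determines an experiment together with its seeds:
#' it bundles the network parameters, the dopamine-modulation parameters,
#' protocol settings, and analysis settings.  Field names mirror the
#' constructor arguments of [network_spec()] and [da_params()].
#'
#' @param network named list of [network_spec()] arguments (defaults used
#'   for omitted fields).
#' @param dopamine named list of [da_params()] arguments.
#' @param protocol named list: `duration` (ms), `dt` (ms), `burn_in` (ms),
#'   `contrast`, `D_grid`.
#' @param analysis named list: `dt_bin` (ms), `rate_threshold` (Hz),
#'   `sample_ms` (ms).
#' @param seed base integer seed.
#' @return An object of class `experiment_config` (validated: the network
#'   and dopamine blocks are instantiated, so invalid fields fail here
#'   with the offending name).
#' @export
experiment_config <- function(network = list(), dopamine = list(),
                              protocol = list(), analysis = list(),
                              seed = 1) {
  bad <- setdiff(names(network), names(formals(network_spec)))
  if (length(bad)) stop("unknown network field(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(names(dopamine), names(formals(da_params)))
  if (length(bad)) stop("unknown dopamine field(s): ",
                        paste(bad, collapse = ", "))
  spec <- do.call(network_spec, network)     # validates (e.g. f * N_E integral)
  pars <- do.call(da_params, dopamine)
  proto <- utils::modifyList(list(duration = 2000, dt = 0.1, burn_in = 200,
                                  contrast = 1.10,
                                  D_grid = c(0.6, 0.8, 1.0, 1.2, 1.4)),
                             protocol)
  ana <- utils::modifyList(list(dt_bin = 0.3, rate_threshold = 10,
                                sample_ms = 5), analysis)
  structure(list(network = network, dopamine = dopamine, protocol = proto,
                 analysis = ana, seed = as.integer(seed),
                 spec = spec, da = pars), class = "experiment_config")
}

#' Read / write an experiment configuration (YAML)
#'
#' @param path file path.
#' @return `read_config` returns a validated [experiment_config()];
#'   `write_config` returns `path` invisibly.  Configurations round-trip
#'   losslessly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  experiment_config(network = raw$network %||% list(),
                    dopamine = raw$dopamine %||% list(),
                    protocol = raw$protocol %||% list(),
                    analysis = raw$analysis %||% list(),
                    seed = raw$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_config
#' @param config an [experiment_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(list(network = config$network,
                        dopamine = config$dopamine,
                        protocol = config$protocol,
                        analysis = config$analysis,
                        seed = config$seed), path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run a configured experiment end to end
#'
#' Executes the requested stages against one sampled connectivity and
#' writes every artifact (delimited-text rasters and curves, JSON fits)
#' plus a manifest recording the configuration hash, seeds, package
#' version, and per-stage status.
#'
#' Stages: `simulate` (resting run + raster export), `phase-sweep`
#' (EE-EI grid), `dose-response` (T_sens over the configured dopamine
#' grid), `avalanche-fit` (avalanche detection, power-law fit, branching
#' parameter on the resting run), `balance` (E/I current correlation and
#' inter-spike-interval CV on the resting run).
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stage names.
#' @return The manifest (invisibly), as written to `manifest.json`.
#' @export
run_experiment <- function(config, out_dir,
                           stages = c("simulate", "avalanche-fit")) {
  stopifnot(inherits(config, "experiment_config"))
  known <- c("simulate", "phase-sweep", "dose-response", "avalanche-fit",
             "balance")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- config$spec; da <- config$da
  proto <- config$protocol; ana <- config$analysis
  lay <- build_layout(spec)
  syn <- sample_connectivity(spec, lay, seed = config$seed, dt = proto$dt)
  A0 <- scaling_factors(da$D_0, da)

  manifest <- list(package = "pfcwm",
                   version = as.character(utils::packageVersion("pfcwm")),
                   config_hash = config_hash(config),
                   seed = config$seed, stages = list())
  rest <- NULL
  rest_run <- function() {
    if (is.null(rest))
      rest <<- run_simulation(spec, syn, A_EE = A0$A_EE, A_EI = A0$A_EI,
                              duration = proto$duration, dt = proto$dt,
                              seed = derive_seed(config$seed, 1),
                              sample_ms = ana$sample_ms)
    rest
  }
  add_stage <- function(name, files, note = NULL) {
    manifest$stages[[name]] <<- list(status = "ok", files = files,
                                     note = note)
  }
  for (st in stages) {
    outcome <- try(switch(st,
      "simulate" = {
        f <- file.path(out_dir, "raster.tsv")
        write_raster(rest_run(), f)
        add_stage(st, "raster.tsv",
                  note = sprintf("%d spikes", nrow(rest_run()$spikes)))
      },
      "phase-sweep" = {
        tr <- build_trajectory(da, grid_step = 0.25)
        pm <- sweep_phase_map(spec, syn,
                              A_EE_grid = unique(round(tr$A_EE, 3)),
                              A_EI_grid = unique(round(tr$A_EI, 3)),
                              duration = proto$duration,
                              seed = config$seed,
                              burn_in = proto$burn_in,
                              rate_threshold = ana$rate_threshold,
                              dt_bin = ana$dt_bin)
        f <- file.path(out_dir, "phase_map.tsv")
        write.table(pm, f, sep = "\t", row.names = FALSE, quote = FALSE)
        add_stage(st, "phase_map.tsv",
                  note = sprintf("%d cells", nrow(pm)))
      },
      "dose-response" = {
        dr <- dose_response(spec, syn, da, D_grid = proto$D_grid,
                            contrast = proto$contrast,
                            seed = config$seed)
        f <- file.path(out_dir, "dose_response.tsv")
        write.table(dr, f, sep = "\t", row.names = FALSE, quote = FALSE)
        add_stage(st, "dose_response.tsv")
      },
      "avalanche-fit" = {
        r <- rest_run()
        lab <- most_active_es(r)
        av <- detect_avalanches(
          population_spikes(r, lab, c(proto$burn_in, proto$duration))$time,
          ana$dt_bin)
        fit <- fit_power_law(av$sizes)
        br <- branching_parameter(av)
        out <- list(population = lab, n_avalanches = length(av$sizes),
                    alpha = fit$alpha, ks = fit$ks, s_range = fit$s_range,
                    n = fit$n, low_count = fit$low_count,
                    sigma = br$sigma)
        f <- file.path(out_dir, "avalanche_fit.json")
        jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA)
        add_stage(st, "avalanche_fit.json")
      },
      "balance" = {
        r <- rest_run()
        lab <- most_active_es(r)
        cv <- isi_cv(population_spikes(r, lab,
                                       c(proto$burn_in, proto$duration)))
        out <- list(population = lab, cv = cv$cv, mean_isi = cv$mean,
                    n_isi = cv$n)
        f <- file.path(out_dir, "balance.json")
        jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA)
        add_stage(st, "balance.json")
      }), silent = TRUE)
    if (inherits(outcome, "try-error"))
      manifest$stages[[st]] <- list(status = "error",
                                    message = as.character(outcome))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
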