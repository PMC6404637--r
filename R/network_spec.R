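#' Structural, cellular, and synaptic parameters of the network
#'
#' Bundles every structural parameter of the working-memory network: an
#' excitatory pool split into `p` item-selective populations (each a
#' fraction `f` of the excitatory neurons) plus one non-selective
#' population, one inhibitory population, random connectivity with
#' probability `c`, the four synaptic weight classes, leaky
#' integrate-and-fire cell constants per class, the external-drive
#' statistics, and the short-term-plasticity constants shared by all
#' excitatory-to-excitatory synapses.
#'
#' Defaults reproduce the reference prefrontal working-memory
#' parameterisation: 8,000 excitatory / 2,000 inhibitory neurons, five
#' memory items with coding fraction 0.10, connection probability 0.20,
#' potentiated / baseline E-to-E efficacies of 0.45 / 0.10 mV, and
#' facilitation-dominated short-term plasticity (utilization recovers with
#' 1,500 ms, resources with 200 ms).
#'
#' @param N_E,N_I number of excitatory / inhibitory neurons.
#' @param p number of memory items (selective populations).
#' @param f coding fraction: each selective population has `f * N_E`
#'   neurons; `f * N_E` must be an integer and `p * f <= 1`.
#' @param c connection probability for every ordered neuron pair.
#' @param gamma probability that an E-to-E synapse touching the
#'   non-selective population takes the potentiated strength.
#' @param J_b,J_p baseline / potentiated E-to-E efficacy (mV).
#' @param J_EI,J_IE,J_II static efficacies E-to-I, I-to-E, I-to-I (mV,
#'   magnitudes; inhibitory deposits are applied with negative sign).
#' @param theta,V_r,tau_m spike threshold (mV), reset potential (mV) and
#'   membrane time constant (ms); length-2 vectors named `E` and `I`.
#' @param tau_arp absolute refractory period (ms).
#' @param mu_ext,sigma_ext mean and SD of the external Gaussian drive
#'   (mV); length-2 vectors named `E` and `I`.
#' @param U,X baseline utilization and resource of the
#'   facilitation/depression dynamics.
#' @param tau_u,tau_x recovery time constants (ms) of the utilization
#'   factor (facilitation, slow) and of the synaptic resources
#'   (depression, fast).
#' @param max_delay upper bound of the uniform synaptic delay (ms).
#'
#' @return An object of class `network_spec`.
#' @examples
#' spec <- network_spec()
#' spec$N_E
#' small <- scale_network(network_spec(), 4)  # in-degree-preserving reduction
#' small$c
#' @export
network_spec <- function(N_E = 8000L, N_I = 2000L, p = 5L, f = 0.10,
                         c = 0.20, gamma = 0.10,
                         J_b = 0.10, J_p = 0.45,
                         J_EI = 0.135, J_IE = 0.25, J_II = 0.20,
                         theta = c(E = 20, I = 20),
                         V_r = c(E = 16, I = 13),
                         tau_m = c(E = 15, I = 10),
                         tau_arp = 2,
                         mu_ext = c(E = 23.8, I = 21.0),
                         sigma_ext = c(E = 1.0, I = 1.0),
                         U = 0.20, X = 1.00,
                         tau_u = 1500, tau_x = 200,
                         max_delay = 1) {
  stopifnot(N_E >= 1, N_I >= 0, p >= 1)
  if (c < 0 || c > 1) stop("connection probability `c` must lie in [0, 1]")
  if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]")
  n_sel <- f * N_E
  if (abs(n_sel - round(n_sel)) > 1e-9)
    stop("`f` * N_E = ", n_sel, " is not an integer; choose `f` so that ",
         "selective population sizes are exact")
  if (p * f > 1 + 1e-12)
    stop("`p` * `f` = ", p * f, " exceeds 1: selective populations would ",
         "overlap")
  two <- function(v, nm) {
    v <- rep_len(v, 2L)
    names(v) <- c("E", "I")
    if (any(!is.finite(v))) stop("non-finite value in `", nm, "`")
    v
  }
  theta <- two(theta, "theta"); V_r <- two(V_r, "V_r")
  tau_m <- two(tau_m, "tau_m")
  mu_ext <- two(mu_ext, "mu_ext"); sigma_ext <- two(sigma_ext, "sigma_ext")
  if (any(V_r >= theta)) stop("reset potential must be below threshold")
  if (any(c(tau_m, tau_arp, tau_u, tau_x) <= 0))
    stop("all time constants must be positive")
  if (U <= 0 || U > 1) stop("`U` must lie in (0, 1]")
  if (X <= 0) stop("`X` must be positive")
  if (any(c(J_b, J_p, J_EI, J_IE, J_II) < 0))
    stop("efficacies are magnitudes and must be >= 0")
  if (max_delay <= 0) stop("`max_delay` must be positive")

  structure(list(
    N_E = as.integer(N_E), N_I = as.integer(N_I), p = as.integer(p), f = f,
    c = c, gamma = gamma, J_b = J_b, J_p = J_p,
    J_EI = J_EI, J_IE = J_IE, J_II = J_II,
    theta = theta, V_r = V_r, tau_m = tau_m, tau_arp = tau_arp,
    mu_ext = mu_ext, sigma_ext = sigma_ext,
    U = U, X = X, tau_u = tau_u, tau_x = tau_x,
    max_delay = max_delay), class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>\n")
  cat(sprintf("  %d E + %d I neurons, %d items x %d neurons, Ens %d\n",
              x$N_E, x$N_I, x$p, as.integer(x$f * x$N_E),
              as.integer((1 - x$p * x$f) * x$N_E)))
  cat(sprintf("  c = %.3g, gamma = %.3g, J_b/J_p = %.3g/%.3g mV\n",
              x$c, x$gamma, x$J_b, x$J_p))
  cat(sprintf("  J_EI/J_IE/J_II = %.3g/%.3g/%.3g mV\n",
              x$J_EI, x$J_IE, x$J_II))
  cat(sprintf("  STP: U = %.2g, X = %.2g, tau_u = %g ms, tau_x = %g ms\n",
              x$U, x$X, x$tau_u, x$tau_x))
  invisible(x)
}

#' In-degree-preserving network reduction
#'
#' Divides both population sizes by `factor` and multiplies the connection
#' probability by the same factor, so that the expected number of inputs
#' per neuron (and hence the mean synaptic drive) is unchanged.  Useful for
#' desk-scale sweeps where the full network would be unnecessarily slow.
#'
#' @param spec a [network_spec()].
#' @param factor integer reduction factor; `c * factor` must stay `<= 1`
#'   and population sizes must stay integral.
#' @return A `network_spec` with reduced sizes.
#' @export
scale_network <- function(spec, factor) {
  stopifnot(inherits(spec, "network_spec"), factor >= 1)
  args <- unclass(spec)
  args$N_E <- spec$N_E / factor
  args$N_I <- spec$N_I / factor
  args$c <- min(1, spec$c * factor)
  if (abs(args$N_E - round(args$N_E)) > 1e-9 ||
      abs(args$N_I - round(args$N_I)) > 1e-9)
    stop("`factor` must divide both N_E and N_I")
  do.call(network_spec, args)
}

#' Partition neurons into selective, non-selective, and inhibitory populations
#'
#' Assigns contiguous index ranges: `Es1 ... Esp` (each `f * N_E` neurons),
#' `Ens` (the remaining excitatory neurons), then `I`.
#'
#' @param spec a [network_spec()].
#' @return An object of class `population_layout` with elements `n`
#'   (total neurons), `n_E`, `labels` (factor of per-neuron population
#'   labels), `pop` (0-based integer codes used by the engine:
#'   `0..p-1` = selective, `p` = Ens, `p+1` = I), and `table`, a data frame
#'   of per-population index ranges (1-based, inclusive).
#' @examples
#' lay <- build_layout(network_spec())
#' subset(lay$table, label == "Ens")$size  # 4000
#' @export
build_layout <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  n_sel <- as.integer(round(spec$f * spec$N_E))
  n_ens <- spec$N_E - spec$p * n_sel
  if (n_ens < 0) stop("selective populations exceed the excitatory pool")
  sizes <- c(rep(n_sel, spec$p), n_ens, spec$N_I)
  lab <- c(paste0("Es", seq_len(spec$p)), "Ens", "I")
  pop <- rep.int(seq_along(sizes) - 1L, sizes)
  start <- cumsum(c(1L, sizes))[seq_along(sizes)]
  tab <- data.frame(label = lab, pop = seq_along(sizes) - 1L,
                    start = start, end = start + sizes - 1L, size = sizes,
                    stringsAsFactors = FALSE)
  structure(list(n = spec$N_E + spec$N_I, n_E = spec$N_E, p = spec$p,
                 pop = pop,
                 labels = factor(lab[pop + 1L], levels = lab),
                 table = tab),
            class = "population_layout")
}

#' Neuron indices (1-based) of one population
#'
#' @param layout a [build_layout()] result.
#' @param label population label, e.g. `"Es1"`, `"Ens"`, `"I"`.
#' @return Integer vector of neuron indices.
#' @export
population_neurons <- function(layout, label) {
  stopifnot(inherits(layout, "population_layout"))
  row <- layout$table[layout$table$label == label, ]
  if (nrow(row) != 1) stop("unknown population label: ", label)
  if (row$size == 0) return(integer(0))
  seq.int(row$start, row$end)
}

#' Sample the random synaptic connectivity
#'
#' Every ordered pair (pre -> post, pre != post) is connected independently
#' with probability `c`.  Weight classes follow the population identities:
#' E-to-E within the same selective population is potentiated (`J_p`),
#' between different selective populations baseline (`J_b`), and any
#' E-to-E synapse touching the non-selective population is potentiated
#' with probability `gamma` (baseline otherwise); E-to-I, I-to-E, and
#' I-to-I take the fixed efficacies.  Delays are uniform on
#' `(0, max_delay]` ms, quantized up to the integration grid (at least one
#' step).  E-to-E synapses share the presynaptic neuron's dynamic
#' utilization/resource state, initialised at `(U, X)`.
#'
#' @param spec a [network_spec()].
#' @param layout the matching [build_layout()].
#' @param seed integer seed fixing the random structure (mandatory).
#' @param dt integration step (ms) used to quantize delays.
#' @return An object of class `synapse_table` (compressed by presynaptic
#'   neuron); convert with [as.data.frame.synapse_table()] for inspection
#'   or export.
#' @examples
#' spec <- network_spec(N_E = 80, N_I = 20, f = 0.1, c = 0.2)
#' syn <- sample_connectivity(spec, build_layout(spec), seed = 1)
#' syn$n_synapses
#' @export
sample_connectivity <- function(spec, layout, seed, dt = 0.1) {
  stopifnot(inherits(spec, "network_spec"),
            inherits(layout, "population_layout"))
  if (missing(seed) || length(seed) != 1 || !is.finite(seed) ||
      seed != round(seed))
    stop("`seed` must be a single integer (reproducibility contract)")
  net <- cpp_sample_connectivity(layout$pop, spec$p, spec$c, spec$gamma,
                                 spec$J_b, spec$J_p, spec$J_EI, spec$J_IE,
                                 spec$J_II, dt, spec$max_delay, seed)
  net$dt <- dt
  net$seed <- as.integer(seed)
  net$n_synapses <- length(net$post)
  class(net) <- "synapse_table"
  net
}

#' @export
print.synapse_table <- function(x, ...) {
  cat(sprintf("<synapse_table> %d synapses, %d presynaptic neurons, dt = %g ms (seed %d)\n",
              x$n_synapses, length(x$ptr) - 1L, x$dt, x$seed))
  invisible(x)
}

#' Flatten a synapse table to one row per connection
#'
#' @param x a `synapse_table`.
#' @param row.names,optional,... ignored (data-frame method signature).
#' @return Data frame with columns `pre`, `post` (1-based), `class`
#'   (`EE`, `EI`, `IE`, `II`), `J` (mV), `delay_ms`.
#' @export
as.data.frame.synapse_table <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  n <- length(x$ptr) - 1L
  pre <- rep.int(seq_len(n), diff(x$ptr))
  data.frame(pre = pre, post = x$post + 1L,
             class = c("EE", "EI", "IE", "II")[x$wclass + 1L],
             J = x$w, delay_ms = x$delay_steps * x$dt)
}

#' Write / read a synapse table as delimited text
#'
#' @param x a `synapse_table`.
#' @param path file path.
#' @return `write_synapses` returns `path` invisibly.
#' @export
write_synapses <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
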