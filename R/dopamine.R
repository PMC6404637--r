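#' Dopamine D1 modulation parameters
#'
#' A D1 activation level `D` scales the excitatory-to-excitatory and
#' excitatory-to-inhibitory synaptic efficacies through two sigmoids that
#' share steepness `K_c` but are shifted in opposite directions by `D_V`
#' around the optimal level `D_0`: glutamatergic drive onto excitatory
#' neurons strengthens (and saturates) earlier than drive onto inhibitory
#' neurons.  Each factor has the closed form
#' \deqn{A(D) = \frac{1 + D_L\,S(D)}{1 + D_L/2} - (1 - A_{min}),\qquad
#'       S(D) = \frac{1}{1+e^{(D^{(0)}-D)/K_c}},}
#' with centre \eqn{D^{(0)} = D_0 - D_V} for the EE factor and
#' \eqn{D_0 + D_V} for the EI factor, modulation depth
#' \eqn{D_L = A_{max} - A_{min}}, and the normaliser \eqn{1 + D_L/2}
#' obtained by evaluating the sigmoid term at `D = D_0` with `D_V = 0`.
#' Factors are handled as dimensionless multipliers (1.04 means "104 %").
#'
#' The two presets mirror the reference parameterisations:
#' `K_c = 0.150, D_V = 0.105` (profile 1, default) and
#' `K_c = 0.120, D_V = 0.185` (profile 2).
#'
#' The `[A_min, A_max]` range is a free calibration of the model: it fixes
#' where the dopamine trajectory sits in the EE-EI plane.  The default
#' range was chosen with [calibrate_da_range()] so that the resting state
#' at `D = D_0` lies just on the quiescent (phase1) side of the
#' phase-transition border - maximal loading sensitivity without
#' spontaneous "imaginary memory".
#'
#' @param D_0 optimal activation level (centre of the domain).
#' @param D_min,D_max domain bounds of the activation level.
#' @param K_c steepness of both sigmoids.
#' @param D_V horizontal shift: the EE sigmoid is centred at `D_0 - D_V`,
#'   the EI sigmoid at `D_0 + D_V`.
#' @param A_min,A_max scaling-factor range (dimensionless multipliers),
#'   `A_min < A_max`.
#' @return An object of class `da_params` with the derived constants
#'   `D_E0`, `D_I0`, `D_L`, `A_P1`, `C_EE`, `C_EI`.
#' @examples
#' pars <- da_params()
#' scaling_factors(1.0, pars)
#' @export
da_params <- function(D_0 = 1.0, D_min = 0, D_max = 2.0,
                      K_c = 0.150, D_V = 0.105,
                      A_min = 1.00, A_max = 2.53) {
  if (!(D_min <= D_0 && D_0 <= D_max)) stop("`D_0` must lie in [D_min, D_max]")
  if (K_c <= 0) stop("`K_c` must be positive")
  if (D_V < 0) stop("`D_V` must be >= 0")
  if (!(A_min < A_max)) stop("`A_min` must be smaller than `A_max`")
  D_L <- A_max - A_min
  # normalizers: sigmoid term at D = D_0 with D_V = 0 (exp(0) = 1)
  C <- 1 + D_L / 2
  structure(list(D_0 = D_0, D_min = D_min, D_max = D_max, K_c = K_c,
                 D_V = D_V, A_min = A_min, A_max = A_max,
                 D_E0 = D_0 - D_V, D_I0 = D_0 + D_V,
                 D_L = D_L, A_P1 = 1 - A_min, C_EE = C, C_EI = C),
            class = "da_params")
}

#' @export
print.da_params <- function(x, ...) {
  cat(sprintf("<da_params> D_0 = %g on [%g, %g], K_c = %g, D_V = %g, A in [%g, %g]\n",
              x$D_0, x$D_min, x$D_max, x$K_c, x$D_V, x$A_min, x$A_max))
  invisible(x)
}

#' Synaptic scaling factors at a given D1 activation level
#'
#' Evaluates the closed-form EE and EI scaling factors (see [da_params()]).
#' Both are monotonically non-decreasing in `D`, and for `D_V > 0` the EE
#' factor leads the EI factor everywhere, with the difference
#' `dA = A_EE - A_EI` maximal at `D_0`.
#'
#' @param D activation level(s) within `[D_min, D_max]` (vectorised).
#' @param params a [da_params()].
#' @return Data frame with columns `D`, `A_EE`, `A_EI`, `dA`
#'   (dimensionless multipliers).
#' @examples
#' sf <- scaling_factors(c(0.6, 1.0, 1.4), da_params())
#' sf$dA   # peaks at D = 1
#' @export
scaling_factors <- function(D, params) {
  stopifnot(inherits(params, "da_params"))
  if (any(D < params$D_min - 1e-12 | D > params$D_max + 1e-12))
    stop("`D` outside the activation-level domain [",
         params$D_min, ", ", params$D_max, "]")
  sig <- function(centre) 1 / (1 + exp((centre - D) / params$K_c))
  A_EE <- (1 + params$D_L * sig(params$D_E0)) / params$C_EE - params$A_P1
  A_EI <- (1 + params$D_L * sig(params$D_I0)) / params$C_EI - params$A_P1
  data.frame(D = D, A_EE = A_EE, A_EI = A_EI, dA = A_EE - A_EI)
}

#' Dopamine trajectory through the EE-EI plane
#'
#' Evaluates the scaling factors on a regular grid over the activation
#' domain, yielding the trajectory traced by the network state as
#' dopamine varies.
#'
#' @param params a [da_params()].
#' @param grid_step grid increment on the activation level (> 0).
#' @return A data frame of class `da_profile`: columns `D`, `A_EE`,
#'   `A_EI`, `dA`; endpoints included.
#' @export
build_trajectory <- function(params, grid_step = 0.01) {
  stopifnot(inherits(params, "da_params"))
  if (grid_step <= 0) stop("`grid_step` must be positive")
  D <- seq(params$D_min, params$D_max, by = grid_step)
  if (tail(D, 1) < params$D_max - 1e-9) D <- c(D, params$D_max)
  out <- scaling_factors(D, params)
  class(out) <- c("da_profile", "data.frame")
  out
}

#' Calibrate the scaling-factor range against the phase border
#'
#' Chooses the modulation depth `A_max` (at fixed `A_min`) so that the
#' resting network at the optimal activation level `D_0` sits just on the
#' quiescent (phase1) side of the transition to self-sustained activity.
#' The search increases the depth until a resting simulation at the
#' `D_0`-induced `(A_EE, A_EI)` point turns phase2, then bisects the
#' border and backs off by `margin`.
#'
#' This is a stochastic calibration (each probe is one resting
#' simulation); it is intended to be run once per network configuration
#' and its result frozen into [da_params()].
#'
#' @param spec a [network_spec()].
#' @param synapses a matching [sample_connectivity()] result.
#' @param A_min lower end of the factor range (held fixed).
#' @param depth_range search interval for `A_max - A_min`.
#' @param tol bisection resolution on the depth.
#' @param margin depth subtracted from the border estimate so the resting
#'   state stays inside phase1.
#' @param duration,seed resting-simulation length (ms) and base seed.
#' @param n_seeds resting simulations per probe depth; a depth counts as
#'   phase2 when the majority of its runs are.
#' @param rate_threshold phase2 rate criterion (Hz), see [classify_phase()].
#' @param ... further [da_params()] fields (`K_c`, `D_V`, ...).
#' @return A calibrated [da_params()].
#' @export
calibrate_da_range <- function(spec, synapses, A_min = 1.0,
                               depth_range = c(0.05, 2.0), tol = 0.01,
                               margin = 0.02, duration = 2000, seed = 1,
                               n_seeds = 3, rate_threshold = 10, ...) {
  probe <- function(depth) {
    pars <- da_params(A_min = A_min, A_max = A_min + depth, ...)
    A <- scaling_factors(pars$D_0, pars)
    ph2 <- vapply(seq_len(n_seeds), function(k) {
      res <- run_simulation(spec, synapses, A_EE = A$A_EE, A_EI = A$A_EI,
                            duration = duration,
                            seed = derive_seed(seed, k))
      classify_phase(res, rate_threshold = rate_threshold) == "phase2"
    }, NA)
    sum(ph2) > n_seeds / 2
  }
  lo <- depth_range[1]; hi <- depth_range[2]
  if (probe(lo))
    stop("resting state is already phase2 at the smallest depth; ",
         "lower `depth_range[1]` or `A_min`")
  if (!probe(hi))
    stop("phase2 never reached at the largest depth; raise `depth_range[2]`")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (probe(mid)) hi <- mid else lo <- mid
  }
  da_params(A_min = A_min, A_max = A_min + max(lo - margin, depth_range[1]),
            ...)
}
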