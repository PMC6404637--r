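# Synthetic ground-truth generators for validating the analysis layer.
# None of these share numerical code with the estimators they test.

#' Galton-Watson avalanche raster with known branching ratio
#'
#' Simulates independent branching avalanches (Poisson offspring with mean
#' `offspring_mean`, one initial unit) and lays them out as spike events,
#' one generation per `dt_bin` window, with at least two empty bins
#' between avalanches.  The estimated branching parameter of the emitted
#' raster converges to `offspring_mean`.
#'
#' @param offspring_mean true branching ratio (>= 0).
#' @param n_avalanches number of avalanches.
#' @param seed integer seed.
#' @param dt_bin bin width (ms) used for the layout.
#' @param max_generations safety cap on avalanche duration (relevant at or
#'   above criticality).
#' @param max_size safety cap on total avalanche size.
#' @return Data frame `time`, `neuron` (an avalanche-compatible raster).
#' @examples
#' r <- branching_raster(0.8, 200, seed = 1)
#' branching_parameter(detect_avalanches(r$time, 0.3))$sigma
#' @export
branching_raster <- function(offspring_mean, n_avalanches, seed,
                             dt_bin = 0.3, max_generations = 100,
                             max_size = 1e5) {
  stopifnot(offspring_mean >= 0, n_avalanches >= 1)
  set.seed(seed)
  times <- vector("list", n_avalanches)
  t0 <- dt_bin  # leave bin 0 empty
  for (a in seq_len(n_avalanches)) {
    counts <- 1L
    repeat {
      nxt <- sum(rpois(counts[length(counts)], offspring_mean))
      if (nxt == 0 || length(counts) >= max_generations ||
          sum(counts) + nxt > max_size) break
      counts <- c(counts, nxt)
    }
    # place spikes mid-bin, one generation per bin
    times[[a]] <- rep(t0 + (seq_along(counts) - 0.5) * dt_bin, counts)
    t0 <- t0 + (length(counts) + 2) * dt_bin  # >= 2 empty separator bins
  }
  tt <- unlist(times)
  data.frame(time = tt, neuron = rep_len(1L, length(tt)))
}

#' Discrete power-law avalanche-size sample
#'
#' Inverse-CDF sampler on the integer support `s_min..s_max` with
#' probabilities proportional to `s^alpha`.  Independent of the fitting
#' code path, so it can serve as its oracle.
#'
#' @param alpha exponent (< -1).
#' @param s_min,s_max integer support bounds.
#' @param n sample size.
#' @param seed integer seed.
#' @return Integer vector of sizes.
#' @export
powerlaw_sizes <- function(alpha, s_min = 1, s_max = 1e4, n, seed) {
  stopifnot(alpha < -1, s_min >= 1, s_max > s_min, n >= 1)
  set.seed(seed)
  s <- seq.int(s_min, s_max)
  p <- s^alpha
  cdf <- cumsum(p) / sum(p)
  u <- runif(n)
  s[findInterval(u, cdf) + 1L]
}

#' Pair of Gaussian series with known correlation
#'
#' @param rho target correlation in `[-1, 1]`.
#' @param n series length.
#' @param seed integer seed.
#' @return List with components `x` and `y`.
#' @export
correlated_pair <- function(rho, n, seed) {
  stopifnot(abs(rho) <= 1, n >= 2)
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  list(x = x, y = y)
}

#' Renewal spike train with known interval law
#'
#' @param law `"periodic"`, `"exponential"` (Poisson train, CV 1), or
#'   `"gamma"` (CV `1/sqrt(shape)`).
#' @param rate firing rate (Hz).
#' @param n number of spikes.
#' @param seed integer seed.
#' @param shape Gamma shape parameter (for `law = "gamma"`).
#' @return Numeric vector of spike times (ms).
#' @export
isi_train <- function(law = c("periodic", "exponential", "gamma"),
                      rate, n, seed, shape = 4) {
  law <- match.arg(law)
  stopifnot(rate > 0, n >= 2)
  set.seed(seed)
  mean_isi <- 1000 / rate
  isi <- switch(law,
    periodic = rep(mean_isi, n),
    exponential = rexp(n, rate = 1 / mean_isi),
    gamma = rgamma(n, shape = shape, rate = shape / mean_isi))
  cumsum(isi)
}
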