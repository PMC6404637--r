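# Single-neuron closed forms, noise statistics, STP dynamics, and the
# reproducibility contract of the integrator.

one_neuron_spec <- function(mu, sigma = 0) {
  network_spec(N_E = 1, N_I = 0, p = 1, f = 1, c = 0,
               mu_ext = c(E = mu, I = 21), sigma_ext = c(E = sigma, I = 1))
}

test_that("a deterministic suprathreshold neuron fires at the LIF period", {
  # tau_arp + tau * log((mu - V_r)/(mu - theta)), Table-style constants
  spec <- one_neuron_spec(23.8)
  net <- make_net(spec)
  res <- run_simulation(spec, net$syn, duration = 2000, seed = 1)
  period <- 2 + 15 * log((23.8 - 16) / (23.8 - 20))
  isi <- diff(res$spikes$time)
  expect_equal(mean(isi), period, tolerance = 0.02)
  expect_lt(diff(range(isi)), 1e-9)        # strictly periodic
  # refractory period respected
  expect_true(all(isi >= spec$tau_arp))
})

test_that("halving dt leaves the deterministic firing period within 5%", {
  spec <- one_neuron_spec(23.8)
  lay <- build_layout(spec)
  p <- sapply(c(0.1, 0.05), function(dt) {
    syn <- sample_connectivity(spec, lay, seed = 1, dt = dt)
    res <- run_simulation(spec, syn, duration = 1000, dt = dt, seed = 1)
    mean(diff(res$spikes$time))
  })
  expect_lt(abs(p[2] - p[1]) / p[1], 0.05)
})

test_that("free membranes reach mean mu_ext and SD sigma_ext/sqrt(2)", {
  # disconnected subthreshold ensemble: with the white-noise current
  # convention tau V' = -V + mu + sigma sqrt(tau) eta the cross-section of
  # final V samples the stationary law N(mu, sigma^2 / 2)
  spec <- network_spec(N_E = 2000, N_I = 0, p = 1, f = 1, c = 0,
                       mu_ext = c(E = 10, I = 21),
                       sigma_ext = c(E = 1, I = 1),
                       V_r = c(E = 0, I = 13))
  net <- make_net(spec)
  res <- run_simulation(spec, net$syn, duration = 200, seed = 3)
  expect_equal(nrow(res$spikes), 0)
  expect_equal(mean(res$V_final), 10, tolerance = 0.02)
  expect_equal(sd(res$V_final), 1 / sqrt(2), tolerance = 0.08)
})

# Exact event-driven facilitation/depression oracle: replays a spike
# train through the jump/relaxation rules with exponential decay and
# returns the per-interval time averages of u and x.
stp_oracle <- function(st, t_end, U = 0.2, X = 1, tau_u = 1500,
                       tau_x = 200) {
  u <- U; x <- X; t_prev <- 0
  tu_int <- tx_int <- 0  # time integrals
  seg <- function(v0, vinf, tau, dt) vinf * dt + (v0 - vinf) * tau *
    (1 - exp(-dt / tau))
  u_pre <- x_pre <- numeric(length(st))
  for (k in seq_along(st)) {
    dtk <- st[k] - t_prev
    tu_int <- tu_int + seg(u, U, tau_u, dtk)
    tx_int <- tx_int + seg(x, X, tau_x, dtk)
    u <- U + (u - U) * exp(-dtk / tau_u)
    x <- X + (x - X) * exp(-dtk / tau_x)
    u <- u + U * (1 - u)              # facilitation jump first
    u_pre[k] <- u; x_pre[k] <- x      # transmitted state (pre-jump x)
    x <- x - u * x
    t_prev <- st[k]
  }
  dtk <- t_end - t_prev
  tu_int <- tu_int + seg(u, U, tau_u, dtk)
  tx_int <- tx_int + seg(x, X, tau_x, dtk)
  list(u_mean = tu_int / t_end, x_mean = tx_int / t_end,
       u_pre = u_pre, x_pre = x_pre)
}

test_that("STP state follows the event-driven recursion of the spike train", {
  spec <- one_neuron_spec(19.9, sigma = 1)
  net <- make_net(spec)
  res <- run_simulation(spec, net$syn, duration = 30000, seed = 5,
                        record_currents = 1, sample_ms = 5)
  st <- sort(res$spikes$time)
  expect_gt(length(st), 100)
  orc <- stp_oracle(st, 30000)
  # engine's time-averaged traces match the exact recursion
  expect_equal(mean(res$stp_rec$u[, 1]), orc$u_mean, tolerance = 0.02)
  expect_equal(mean(res$stp_rec$x[, 1]), orc$x_mean, tolerance = 0.03)
  # bounds hold throughout
  expect_true(all(res$stp_rec$u[, 1] >= 0.2 - 1e-9))
  expect_true(all(res$stp_rec$u[, 1] <= 1 + 1e-9))
  expect_true(all(res$stp_rec$x[, 1] >= -1e-9 &
                    res$stp_rec$x[, 1] <= 1 + 1e-9))
})

test_that("a Poisson-like train recovers the mean-field STP fixed points", {
  # fluctuation-driven neuron near 10 Hz with ISI CV ~ 1; at that rate the
  # fixed points of the facilitation/depression map are
  # u* = U(1 + r tau_u)/(1 + U r tau_u) = 0.8 and
  # x* = X/(1 + tau_x u* r) ~ 0.385
  spec <- one_neuron_spec(16.5, sigma = 3.0)
  net <- make_net(spec)
  res <- run_simulation(spec, net$syn, duration = 60000, seed = 11,
                        record_currents = 1, sample_ms = 5)
  st <- sort(res$spikes$time)
  r <- length(st) / 60000               # spikes per ms
  expect_gt(r, 0.006); expect_lt(r, 0.016)
  cv <- isi_cv(st)$cv
  expect_gt(cv, 0.75); expect_lt(cv, 1.15)
  u_star <- 0.2 * (1 + r * 1500) / (1 + 0.2 * r * 1500)
  x_star <- 1 / (1 + 200 * u_star * r)
  orc <- stp_oracle(st, 60000)
  expect_equal(mean(orc$u_pre), u_star, tolerance = 0.10)
  expect_equal(mean(orc$x_pre), x_star, tolerance = 0.15)
  # engine trace agrees with the oracle's time averages
  expect_equal(mean(res$stp_rec$u[, 1]), orc$u_mean, tolerance = 0.02)
  expect_equal(mean(res$stp_rec$x[, 1]), orc$x_mean, tolerance = 0.03)
})

test_that("identical seeds give bit-identical rasters, different seeds differ", {
  net <- make_net(tiny_spec(), seed = 2)
  a <- run_simulation(tiny_spec(), net$syn, duration = 500, seed = 9)
  b <- run_simulation(tiny_spec(), net$syn, duration = 500, seed = 9)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$V_final, b$V_final)
  d <- run_simulation(tiny_spec(), net$syn, duration = 500, seed = 10)
  expect_false(identical(a$spikes, d$spikes))
})

test_that("stimuli scale the mean drive of the target population only", {
  spec <- network_spec(N_E = 200, N_I = 50, p = 2, f = 0.25, c = 0,
                       mu_ext = c(E = 18, I = 15), sigma_ext = c(E = 1, I = 1))
  net <- make_net(spec)
  stim <- stimulus_protocol("Es1", 100, 300, contrast = 1.15)
  res <- run_simulation(spec, net$syn, stimuli = stim, duration = 500,
                        seed = 4)
  during <- c(100, 400)
  expect_gt(population_rate(res, "Es1", during),
            5 * max(population_rate(res, "Es2", during), 0.2))
  # stimulus validation
  expect_error(stimulus_protocol("Es1", 0, -5), "duration")
  expect_error(stimulus_protocol("Es1", 0, 10, contrast = 0.5), "contrast")
})

test_that("simulation contract violations are caught", {
  net <- make_net(tiny_spec())
  expect_error(run_simulation(tiny_spec(), net$syn, duration = 100),
               "seed")
  expect_error(run_simulation(tiny_spec(), net$syn, duration = 100.05,
                              seed = 1), "multiple")
  expect_error(run_simulation(tiny_spec(), net$syn, duration = 100,
                              dt = 0.2, seed = 1), "rebuild")
})
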