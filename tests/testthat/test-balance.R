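test_that("correlation magnitude behaves as the product-moment |rho|", {
  e <- rnorm(100)
  expect_equal(ei_correlation(e, -2 * e), 1)
  expect_equal(ei_correlation(e, 3 * e + 5), 1)       # affine invariance
  # independent white noise: |rho| ~ O(1/sqrt(n))
  p <- correlated_pair(0, 1e5, seed = 1)
  expect_lt(ei_correlation(p$x, p$y), 0.02)
  # known mixing coefficient
  p7 <- correlated_pair(0.7, 1e4, seed = 2)
  r <- ei_correlation(p7$x, p7$y)
  expect_gt(r, 0.68); expect_lt(r, 0.72)
  # affine rescaling of either trace leaves |rho| untouched
  expect_equal(ei_correlation(10 * p7$x + 3, p7$y), r)
  expect_warning(out <- ei_correlation(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(out))
  expect_error(ei_correlation(1:5, 1:4), "equal length")
})

test_that("the printed variance-sum variant is kept for audit", {
  p <- correlated_pair(0.9, 1000, seed = 3)
  vs <- ei_correlation(p$x, p$y, method = "variance_sum")
  pe <- ei_correlation(p$x, p$y)
  expect_lt(vs, pe)      # cov/(var+var) <= cov/(2 sd sd) <= |rho|
})

test_that("ISI coefficient of variation matches renewal-process theory", {
  expect_equal(isi_cv(isi_train("periodic", 10, 100, seed = 1))$cv, 0)
  cv_exp <- isi_cv(isi_train("exponential", 10, 1e4, seed = 2))$cv
  expect_gt(cv_exp, 0.97); expect_lt(cv_exp, 1.03)
  cv_gam <- isi_cv(isi_train("gamma", 10, 1e4, seed = 3, shape = 4))$cv
  expect_equal(cv_gam, 0.5, tolerance = 0.03)
  # invariant under time-unit rescaling
  t <- isi_train("gamma", 10, 1000, seed = 4)
  expect_equal(isi_cv(t)$cv, isi_cv(t * 1000)$cv)
  expect_error(isi_cv(c(5)), "no inter-spike")
})

test_that("per-neuron averaging is available as a variant", {
  sp <- data.frame(time = c(isi_train("periodic", 10, 50, seed = 1),
                            isi_train("exponential", 10, 50, seed = 2)),
                   neuron = rep(1:2, each = 50))
  pooled <- isi_cv(sp)$cv
  per <- isi_cv(sp, per_neuron = TRUE)$cv
  expect_false(isTRUE(all.equal(pooled, per)))
  expect_lt(per, pooled)  # periodic neuron pulls the per-neuron mean down
})

test_that("population balance decomposes channels and flags silent inputs", {
  spec <- desk_spec()
  net <- make_net(spec, seed = 6)
  rec <- c(population_neurons(net$lay, "Es1")[1:25],
           population_neurons(net$lay, "I")[1:10])
  stim <- stimulus_protocol("Es1", 200, 300, 1.10)
  res <- run_simulation(spec, net$syn, stimuli = stim, duration = 600,
                        seed = 8, record_currents = rec)
  tot <- population_balance(res, "total", window = c(200, 500))
  recur <- population_balance(res, "recurrent_only", window = c(200, 500))
  expect_true(all(tot$per_neuron$rho >= 0 & tot$per_neuron$rho <= 1,
                  na.rm = TRUE))
  # recurrent-only correlation exceeds the total-current correlation
  m_tot <- tot$summary$mean[tot$summary$population == "Es1"]
  m_rec <- recur$summary$mean[recur$summary$population == "Es1"]
  expect_gt(m_rec, m_tot)

  # inhibition disabled: inhibitory traces are flat, correlation undefined
  spec0 <- network_spec(N_E = 100, N_I = 25, p = 2, f = 0.1, c = 0.2,
                        J_IE = 0, J_II = 0,
                        mu_ext = c(E = 23.8, I = 0),
                        sigma_ext = c(E = 1, I = 0))
  net0 <- make_net(spec0, seed = 2)
  res0 <- run_simulation(spec0, net0$syn, duration = 400, seed = 3,
                         record_currents = population_neurons(net0$lay,
                                                              "Es1"))
  bal0 <- population_balance(res0, "recurrent_only", window = c(100, 400))
  expect_true(all(is.na(bal0$per_neuron$rho)))
  expect_error(population_balance(run_simulation(spec0, net0$syn,
                                                 duration = 200, seed = 1),
                                  "total"), "record_currents")
})
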