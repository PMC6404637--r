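test_that("population layout partitions the network as specified", {
  lay <- build_layout(network_spec())
  tab <- lay$table
  expect_equal(tab$size[tab$label == "Es1"], 800)
  expect_equal(sum(tab$size[grepl("^Es", tab$label)]), 4000)
  expect_equal(tab$size[tab$label == "Ens"], 4000)
  expect_equal(tab$size[tab$label == "I"], 2000)
  expect_equal(length(lay$pop), 10000)
  # ranges partition the index space
  expect_equal(unname(unlist(Map(seq, tab$start, tab$end))), 1:10000)

  # boundary p * f = 1: empty Ens is a valid layout
  lay2 <- build_layout(network_spec(N_E = 10, N_I = 2, p = 10, f = 0.1))
  expect_equal(lay2$table$size[lay2$table$label == "Ens"], 0)

  lay3 <- build_layout(network_spec(N_E = 100, N_I = 10, p = 2, f = 0.25))
  expect_equal(lay3$table$size[1:3], c(25, 25, 50))
})

test_that("invalid specs are rejected with informative errors", {
  expect_error(network_spec(N_E = 100, p = 5, f = 0.25), "exceeds 1")
  expect_error(network_spec(N_E = 1000, f = 0.0333), "not an integer")
  expect_error(network_spec(c = 1.5), "\\[0, 1\\]")
  expect_error(network_spec(V_r = c(E = 25, I = 13)), "below threshold")
  expect_error(network_spec(tau_u = -1), "positive")
  expect_error(network_spec(U = 0), "U")
})

test_that("connectivity is Bernoulli(c) with correct weight classes", {
  net <- make_net(tiny_spec(), seed = 7)
  df <- as.data.frame(net$syn)
  n <- net$lay$n
  # no self-connections, no duplicated ordered pairs
  expect_false(any(df$pre == df$post))
  expect_false(any(duplicated(df[, c("pre", "post")])))
  # binomial count oracle: total count within 4 SD of n(n-1)c
  m <- n * (n - 1) * 0.2
  expect_lt(abs(nrow(df) - m), 4 * sqrt(m * 0.8))
  # weight classes by population pair
  pop <- net$lay$labels
  within_es <- df$pre <= 10 & df$post <= 10          # both in Es1
  between_es <- df$pre <= 10 & df$post > 10 & df$post <= 20
  expect_true(all(df$J[df$class == "EE" & within_es] == 0.45))
  expect_true(all(df$J[df$class == "EE" & between_es] == 0.10))
  expect_true(all(df$J[df$class == "EI"] == 0.135))
  expect_true(all(df$J[df$class == "IE"] == 0.25))
  expect_true(all(df$J[df$class == "II"] == 0.20))
  # delays quantized to dt grid within (0, 1] ms
  expect_true(all(df$delay_ms > 0 & df$delay_ms <= 1))
  expect_true(all(abs(df$delay_ms / 0.1 - round(df$delay_ms / 0.1)) < 1e-9))
})

test_that("gamma mixture governs synapses touching the non-selective pool", {
  spec <- network_spec(N_E = 400, N_I = 100, p = 2, f = 0.1, c = 0.5,
                       gamma = 0.1)
  net <- make_net(spec, seed = 3)
  df <- as.data.frame(net$syn)
  ens <- population_neurons(net$lay, "Ens")
  mix <- df$class == "EE" & (df$pre %in% ens | df$post %in% ens)
  frac <- mean(df$J[mix] == spec$J_p)
  n_mix <- sum(mix)
  expect_lt(abs(frac - 0.1), 4 * sqrt(0.1 * 0.9 / n_mix))
})

test_that("connectivity sampling is reproducible and degenerate cases work", {
  spec <- tiny_spec()
  lay <- build_layout(spec)
  a <- sample_connectivity(spec, lay, seed = 11)
  b <- sample_connectivity(spec, lay, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- sample_connectivity(spec, lay, seed = 12)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))

  none <- sample_connectivity(tiny_spec(c = 0), lay, seed = 1)
  expect_equal(none$n_synapses, 0)
  expect_error(sample_connectivity(spec, lay, seed = "x"), "seed")

  all_pairs <- sample_connectivity(tiny_spec(c = 1), lay, seed = 1)
  expect_equal(all_pairs$n_synapses, lay$n * (lay$n - 1))
})
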