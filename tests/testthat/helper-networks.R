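# Small shared network fixtures, built in code at test time.

tiny_spec <- function(c = 0.2, ...) {
  network_spec(N_E = 100, N_I = 25, p = 2, f = 0.1, c = c, ...)
}

# In-degree-preserving desk-scale version of the reference network.
desk_spec <- function(...) scale_network(network_spec(...), 4)

make_net <- function(spec, seed = 1, dt = 0.1) {
  lay <- build_layout(spec)
  list(spec = spec, lay = lay,
       syn = sample_connectivity(spec, lay, seed = seed, dt = dt))
}

# Synthetic sim_result wrapper around a bare raster, for analyses that
# only touch spikes/layout/duration.
fake_result <- function(spikes, spec, duration) {
  structure(list(spikes = spikes, layout = build_layout(spec),
                 duration = duration, dt = 0.1, seed = 0L,
                 A_EE = 1, A_EI = 1),
            class = "sim_result")
}
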