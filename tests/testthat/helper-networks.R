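# Miniature network (200 neurons, same architecture) for fast mechanics
# tests; conductances are the full-scale ones, so its dynamics is not the
# full model's, which protocol-mechanics tests do not need.
mini_config <- function(...) {
  network_config(n_excitatory = 160, n_inhibitory = 40, n_selective = 5,
                 selective_size = 16, ...)
}

# Near-bifurcation operating point used by the end-to-end checks: the last
# monostable cell of the mean-field census at intermediate inhibition
# (see choose_working_point()), with the calibrated background noise.
op_config <- function(...) network_config(w_plus = 2.025, w_inh = 1.0, ...)

# burn-in that brings excursion occupancy to stationarity there (dwell
# times are a few hundred ms, so 3 s is ample)
op_warmup_ms <- function() 3000

# per-population mean firing rate (Hz) of a single-trial spike_data
pop_rates_hz <- function(spikes, net, t_min = 0) {
  dur <- attr(spikes, "duration_ms")
  keep <- spikes$time_ms >= t_min
  counts <- tabulate(spikes$neuron[keep], nbins = n_total <- sum(net$populations$size))
  agg <- tapply(counts, net$membership, sum)
  as.numeric(agg / net$populations$size / ((dur - t_min) / 1000))
}
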