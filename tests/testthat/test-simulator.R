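test_that("magnesium block has the right value, limits and monotonicity", {
  expect_equal(mg_block(0), 1 / 1.2801, tolerance = 1e-12)
  expect_lt(mg_block(-200), 1e-4) # hyperpolarised limit: full block
  v <- seq(-90, 20, by = 1)
  expect_true(all(diff(mg_block(v)) > 0))
  expect_true(all(mg_block(v) > 0 & mg_block(v) < 1))
  expect_error(mg_block(NA), "nonfinite")
})

test_that("gating decays exponentially and NMDA saturates below 1", {
  syn <- synapse_params()
  st <- list(s_ampa = 1, s_gaba = 1, s_nmda = 0, x_nmda = 0)
  dt <- 0.05
  for (i in 1:400) st <- update_gating(st, spikes = 0, dt_ms = dt) # 20 ms
  expect_equal(st$s_ampa, exp(-20 / 2), tolerance = 1e-10)
  expect_equal(st$s_gaba, exp(-20 / 10), tolerance = 1e-10)

  # sustained 100 Hz drive: s_nmda plateaus strictly below 1
  st <- list(s_ampa = 0, s_gaba = 0, s_nmda = 0, x_nmda = 0)
  steps_per_spike <- round(10 / dt) # one spike every 10 ms
  for (i in 1:20000) {
    st <- update_gating(st, spikes = as.integer(i %% steps_per_spike == 0),
                        dt_ms = dt)
  }
  expect_gt(st$s_nmda, 0.3)
  expect_lt(st$s_nmda, 1)

  expect_error(update_gating(st, dt_ms = -0.01), "positive")
  expect_error(update_gating(st, dt_ms = 0.5), "0.1")
})

test_that("NMDA gating after one spike matches a 10x finer integration", {
  dt <- 0.05
  run <- function(step) {
    st <- list(s_ampa = 0, s_gaba = 0, s_nmda = 0, x_nmda = 0)
    st <- update_gating(st, spikes = 1, dt_ms = step)
    for (i in seq_len(round(40 / step) - 1))
      st <- update_gating(st, spikes = 0, dt_ms = step)
    st$s_nmda
  }
  # forward Euler on the saturating term is first order in dt
  expect_equal(run(dt), run(dt / 10), tolerance = 0.02)
})

test_that("membrane dynamics: equilibrium, leak relaxation, refractoriness", {
  zero_in <- list(s_ext = 0, s_ampa = 0, s_nmda = 0, s_gaba = 0)
  st <- list(v = -70, r = 0)
  for (i in 1:1000) {
    out <- membrane_step(st$v, st$r, zero_in, dt_ms = 0.05)
    st <- list(v = out$v_mv, r = out$refractory_ms)
  }
  expect_equal(st$v, -70)

  # leak-only relaxation from reset: V(t) = VL + (V0 - VL) exp(-t/tau_m)
  v <- -55
  for (i in 1:400) v <- membrane_step(v, 0, zero_in, dt_ms = 0.05)$v_mv # 20 ms
  expect_equal(v, -70 + 15 * exp(-1), tolerance = 0.01)

  # during the refractory period no spike can be emitted
  strong <- list(s_ext = 50, s_ampa = 0, s_nmda = 0, s_gaba = 0)
  out <- membrane_step(-50, 0, strong, dt_ms = 0.05) # at threshold: spike
  expect_true(out$spike)
  expect_equal(out$v_mv, -55)
  t_ref <- out$refractory_ms
  while (t_ref > 0) {
    out <- membrane_step(out$v_mv, t_ref, strong, dt_ms = 0.05)
    expect_false(out$spike)
    expect_equal(out$v_mv, -55)
    t_ref <- out$refractory_ms
  }
})

test_that("background OU rate has the right fixed point and moments", {
  # sigma = 0: the baseline is a fixed point
  st <- background_rate_step(rep(2.4, 5), 2.4, 0, 10, 0.05)
  expect_equal(st$nu_khz, rep(2.4, 5))

  # stationary std matches sigma within 5% (many parallel chains)
  set.seed(1)
  nu <- rep(2.4, 2000)
  for (i in 1:400) nu <- background_rate_step(nu, 2.4, 0.3, 10, 0.5)$nu_khz
  samples <- numeric(0)
  for (i in 1:50) {
    nu <- background_rate_step(nu, 2.4, 0.3, 10, 0.5)$nu_khz
    samples <- c(samples, nu)
  }
  expect_equal(sd(samples), 0.3, tolerance = 0.05)

  # rectification: emitted rate is never negative
  st <- background_rate_step(c(-1, 0.1), 0, 0, 10, 0.05)
  expect_true(all(st$rate_khz >= 0))
})

test_that("simulation is deterministic, silent without drive, respects tau_ref", {
  net <- build_network(mini_config())
  a <- run_trial(net, NULL, 500, seed = 42)
  b <- run_trial(net, NULL, 500, seed = 42)
  expect_identical(a$time_ms, b$time_ms)
  expect_identical(a$neuron, b$neuron)

  # zero background and no stimulus: no spikes at all
  quiet <- build_network(mini_config(nu0_khz = 0, sigma_nu_khz = 0))
  expect_equal(nrow(run_trial(quiet, NULL, 500, seed = 1)), 0)

  # no ISI shorter than the refractory period, ever
  isis <- unlist(tapply(a$time_ms, a$neuron, function(t) diff(sort(t))))
  if (length(isis)) expect_gte(min(isis), 1)

  expect_error(run_trial(net, NULL, 100, dt_ms = 0.5, seed = 1), "dt")
})

test_that("with all reversal potentials at rest the network is silent", {
  cfg <- mini_config(synapses = synapse_params(v_e_mv = -70, v_i_mv = -70))
  net <- build_network(cfg)
  sp <- run_trial(net, stimulus_schedule("S1", 0, 500, 500), 500, seed = 3)
  expect_equal(nrow(sp), 0) # all driving forces vanish at V = VL = -70
})

test_that("blocked and naive recurrent paths agree on a miniature network", {
  cfg <- network_config(n_excitatory = 16, n_inhibitory = 4, n_selective = 5,
                        selective_size = 2, w_plus = 1.5)
  net <- build_network(cfg)
  a <- run_trial(net, NULL, 500, seed = 11, method = "blocked")
  b <- run_trial(net, NULL, 500, seed = 11, method = "naive")
  # identical seeds and update order: same realisation up to float rounding
  expect_equal(nrow(a), nrow(b), tolerance = 0.02)
  ra <- tabulate(a$neuron, 20); rb <- tabulate(b$neuron, 20)
  expect_equal(ra, rb, tolerance = 0.1)
})

test_that("stimulated-population rate grows monotonically with drive", {
  net <- build_network(network_config())
  rates <- vapply(c(0, 200, 400), function(lam) {
    sched <- if (lam > 0) stimulus_schedule("S1", 0, 1000, lam)
    sp <- run_trial(net, sched, 1000, seed = 5)
    sum(attr(sp, "populations")[sp$neuron] == "S1") / 80
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("baseline spontaneous activity is stationary and exchangeable", {
  net <- build_network(network_config(w_plus = 1))
  sp <- run_trial(net, NULL, 10000, seed = 8, warmup_ms = 1000)
  pops <- attr(sp, "populations")
  sel <- paste0("S", 1:5)

  # the five selective populations fire at statistically equal rates
  # (spikes are correlated through the shared background, so the check is
  # on the relative spread of population counts, not a Poisson test)
  counts <- vapply(sel, function(l) sum(pops[sp$neuron] == l), numeric(1))
  expect_lt(stats::sd(counts) / mean(counts), 0.2)

  # first vs second half of the run: pooled selective rate is stationary
  sel_spikes <- sp$time_ms[pops[sp$neuron] %in% sel]
  n1 <- sum(sel_spikes < 5000); n2 <- sum(sel_spikes >= 5000)
  expect_lt(abs(n1 - n2) / ((n1 + n2) / 2), 0.25)
})
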