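#' NMDA magnesium-block factor
#'
#' The voltage-dependent factor multiplying the NMDA conductance,
#' `1 / (1 + mg_prefactor * exp(-mg_slope * V))`: magnesium blocks the
#' channel at hyperpolarised potentials, so the factor increases
#' monotonically from 0 to 1 with depolarisation.
#'
#' @param v_mv membrane potential, mV (vectorised).
#' @param synapses a [synapse_params()] object.
#' @return The block factor in (0, 1).
#' @export
#' @examples
#' mg_block(0)   # 1 / 1.2801
mg_block <- function(v_mv, synapses = synapse_params()) {
  if (!all(is.finite(v_mv))) stop("nonfinite membrane potential")
  1 / (1 + synapses$mg_prefactor * exp(-synapses$mg_slope_per_mv * v_mv))
}

#' One gating update step (reference implementation)
#'
#' Advances the presynaptic gating variables of one neuron by `dt`: AMPA and
#' GABA gating decays exponentially (2 ms, 10 ms) and jumps by +1 per spike;
#' the NMDA auxiliary variable `x` does the same with the 2 ms rise
#' constant, while the NMDA gating integrates
#' `ds/dt = -s/tau_decay + alpha * x * (1 - s)` (forward Euler), which keeps
#' `s` in `[0, 1]`. This mirrors, step for step, the compiled network core;
#' it exists for unit testing and for single-synapse exploration.
#'
#' @param state list with `s_ampa`, `s_gaba`, `s_nmda`, `x_nmda` (and
#'   optionally `s_ampa_ext`).
#' @param spikes number of presynaptic spikes in the previous step.
#' @param dt_ms time step, ms (must be positive and at most 0.1).
#' @param synapses a [synapse_params()] object.
#' @param ext_spikes external spikes applied to `s_ampa_ext`.
#' @return The updated state list.
#' @export
update_gating <- function(state, spikes = 0, dt_ms = 0.05,
                          synapses = synapse_params(), ext_spikes = 0) {
  if (dt_ms <= 0) stop("dt must be positive")
  if (dt_ms > 0.1) stop("dt must be at most 0.1 ms")
  s <- state$s_nmda
  s <- s + dt_ms * (-s / synapses$tau_nmda_decay_ms +
                      synapses$alpha_per_ms * state$x_nmda * (1 - s))
  state$s_nmda <- min(1, max(0, s))
  state$x_nmda <- state$x_nmda * exp(-dt_ms / synapses$tau_nmda_rise_ms) + spikes
  state$s_ampa <- state$s_ampa * exp(-dt_ms / synapses$tau_ampa_ms) + spikes
  state$s_gaba <- state$s_gaba * exp(-dt_ms / synapses$tau_gaba_ms) + spikes
  if (!is.null(state$s_ampa_ext))
    state$s_ampa_ext <- state$s_ampa_ext * exp(-dt_ms / synapses$tau_ampa_ms) +
      ext_spikes
  state
}

#' One membrane update step (reference implementation)
#'
#' Forward-Euler update of the subthreshold dynamics
#' `Cm dV/dt = -gL (V - VL) - Isyn`, where `Isyn` sums the external AMPA,
#' recurrent AMPA, magnesium-blocked NMDA and GABA currents, each of the
#' form conductance x gating x driving force. On reaching threshold the
#' neuron spikes, the potential resets and stays clamped for the refractory
#' period.
#'
#' @param v_mv membrane potential, mV.
#' @param refractory_ms remaining refractory time, ms.
#' @param inputs list of gated conductance sums: `s_ext`, `s_ampa`,
#'   `s_nmda`, `s_gaba` (weighted presynaptic gating sums).
#' @param dt_ms time step, ms.
#' @param neuron a [neuron_params()] object.
#' @param synapses a [synapse_params()] object.
#' @return A list `v_mv`, `refractory_ms`, `spike` (logical).
#' @export
membrane_step <- function(v_mv, refractory_ms = 0, inputs, dt_ms = 0.05,
                          neuron = neuron_params("excitatory"),
                          synapses = synapse_params()) {
  if (!is.finite(v_mv)) stop("nonfinite membrane potential")
  if (refractory_ms > 0) {
    return(list(v_mv = neuron$v_reset_mv,
                refractory_ms = max(0, refractory_ms - dt_ms), spike = FALSE))
  }
  cls <- neuron$class
  gs <- function(g) unname(g[cls])
  cm_pf <- neuron$capacitance_nf * 1000
  isyn <- gs(synapses$g_ampa_ext_ns) * inputs$s_ext * (v_mv - synapses$v_e_mv) +
    gs(synapses$g_ampa_rec_ns) * inputs$s_ampa * (v_mv - synapses$v_e_mv) +
    gs(synapses$g_nmda_ns) * mg_block(v_mv, synapses) * inputs$s_nmda *
      (v_mv - synapses$v_e_mv) +
    gs(synapses$g_gaba_ns) * inputs$s_gaba * (v_mv - synapses$v_i_mv)
  v <- v_mv + dt_ms * (-neuron$leak_ns * (v_mv - neuron$v_leak_mv) - isyn) / cm_pf
  if (!is.finite(v)) stop("membrane potential diverged; reduce dt")
  if (v >= neuron$v_thr_mv) {
    list(v_mv = neuron$v_reset_mv, refractory_ms = neuron$tau_ref_ms,
         spike = TRUE)
  } else {
    list(v_mv = v, refractory_ms = 0, spike = FALSE)
  }
}

#' One background-rate (Ornstein-Uhlenbeck) step
#'
#' The aggregated external Poisson input to each population has a slowly
#' fluctuating rate following an OU process with mean `nu0`, relaxation time
#' `tau` and stationary standard deviation `sigma`:
#' `dnu = (nu0 - nu) dt / tau + sigma * sqrt(2 dt / tau) * N(0, 1)`.
#' Negative excursions are rectified to zero on emission (the internal state
#' is left untouched, so the pre-rectification process keeps its OU
#' moments).
#'
#' @param nu_khz current rate state, kHz (vectorised over populations).
#' @param nu0_khz,sigma_khz,tau_ms OU parameters.
#' @param dt_ms time step, ms.
#' @return A list `nu_khz` (new state) and `rate_khz` (rectified emission).
#' @export
background_rate_step <- function(nu_khz, nu0_khz, sigma_khz, tau_ms, dt_ms) {
  stopifnot(tau_ms > 0, dt_ms > 0, sigma_khz >= 0)
  nu <- nu_khz + (nu0_khz - nu_khz) * dt_ms / tau_ms +
    sigma_khz * sqrt(2 * dt_ms / tau_ms) * stats::rnorm(length(nu_khz))
  list(nu_khz = nu, rate_khz = pmax(nu, 0))
}

#' Stimulus / attention schedule
#'
#' External stimulation and attentional bias are both modelled as extra
#' Poisson rate added to the background input of one selective population
#' during an interval. Schedules from several calls can be combined with
#' `rbind()`.
#'
#' @param population population label (e.g. `"S1"`).
#' @param onset_ms,offset_ms interval bounds (onset < offset).
#' @param rate_hz extra input rate, Hz (`>= 0`).
#' @return A data frame of class `"stimulus_schedule"`.
#' @export
stimulus_schedule <- function(population, onset_ms, offset_ms, rate_hz) {
  stopifnot(length(population) == length(onset_ms),
            all(onset_ms < offset_ms), all(rate_hz >= 0))
  structure(data.frame(population = as.character(population),
                       onset_ms = onset_ms, offset_ms = offset_ms,
                       rate_hz = rate_hz, stringsAsFactors = FALSE),
            class = c("stimulus_schedule", "data.frame"))
}

# schedule -> matrix for the C++ core (0-based population, rates in kHz)
schedule_matrix <- function(schedule, net) {
  if (is.null(schedule) || nrow(schedule) == 0)
    return(matrix(0, 0, 4))
  p <- match(schedule$population, levels(net$membership))
  if (anyNA(p)) stop("schedule names an unknown population")
  cbind(p - 1, schedule$onset_ms, schedule$offset_ms, schedule$rate_hz / 1000)
}

#' Simulate one network trial
#'
#' Integrates the full conductance-based network for `duration_ms` at step
#' `dt_ms` (forward Euler; spikes are recorded at the step boundary where
#' the threshold is crossed). Every neuron receives an independent external
#' Poisson train whose rate is the population's OU-modulated background rate
#' plus any scheduled stimulus/attention rate. Given the same seed the
#' output is bit-identical.
#'
#' @param net a [build_network()] spec.
#' @param schedule a [stimulus_schedule()] or `NULL`.
#' @param duration_ms trial length, ms.
#' @param dt_ms integration step, ms (at most 0.1; default 0.05).
#' @param seed integer seed.
#' @param warmup_ms discarded burn-in simulated before `t = 0` so that the
#'   trial starts from (approximately) stationary network activity rather
#'   than from the arbitrary cold initial condition; spikes during the
#'   warm-up are dropped and times are reported relative to its end.
#' @param record_rates if `TRUE`, attach the realised background-rate
#'   trajectories (1 ms resolution) as attribute `background_rates`.
#' @param method `"blocked"` (population-aggregated recurrent input, the
#'   default) or `"naive"` (per-synapse sums; only sensible for miniature
#'   networks).
#' @return A single-trial [spike_data()] object with the population map in
#'   attribute `populations`.
#' @export
run_trial <- function(net, schedule = NULL, duration_ms, dt_ms = 0.05,
                      seed = NULL, warmup_ms = 0, record_rates = FALSE,
                      method = c("blocked", "naive")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "network_spec"), duration_ms > 0, warmup_ms >= 0)
  if (!is.null(schedule)) {
    sm <- schedule_matrix(schedule, net)
    sm[, 2] <- sm[, 2] + warmup_ms
    sm[, 3] <- sm[, 3] + warmup_ms
    # overlapping entries for one population add their rates (bias on top of
    # stimulus); identical (pop, onset, offset) rows are almost surely a
    # mistake and conflict
    if (nrow(sm) > 1 && anyDuplicated(sm))
      stop("conflicting duplicate schedule entries")
  } else sm <- matrix(0, 0, 4)
  if (!is.null(seed)) set.seed(seed)
  cfg <- net$config
  ne <- cfg$neurons$excitatory
  ni <- cfg$neurons$inhibitory
  syn <- cfg$synapses
  par_vec <- function(p) c(p$capacitance_nf * 1000, p$leak_ns, p$v_leak_mv,
                           p$v_thr_mv, p$v_reset_mv, p$tau_ref_ms)
  gvec <- function(cls) c(syn$g_ampa_ext_ns[cls], syn$g_ampa_rec_ns[cls],
                          syn$g_nmda_ns[cls], syn$g_gaba_ns[cls])
  res <- sim_network_cpp(
    pop_of = pop_index(net) - 1L,
    pop_size = net$populations$size,
    pop_is_exc = as.integer(net$populations$class == "excitatory"),
    W = net$W,
    exc_par = par_vec(ne), inh_par = par_vec(ni),
    g_exc = gvec("excitatory"), g_inh = gvec("inhibitory"),
    syn = c(syn$v_e_mv, syn$v_i_mv, syn$tau_ampa_ms, syn$tau_nmda_rise_ms,
            syn$tau_nmda_decay_ms, syn$tau_gaba_ms, syn$alpha_per_ms,
            syn$mg_prefactor, syn$mg_slope_per_mv),
    bg = c(cfg$nu0_khz, cfg$sigma_nu_khz, cfg$tau_nu_ms),
    stim = sm,
    duration = duration_ms + warmup_ms, dt = dt_ms,
    include_self = cfg$include_self, naive = (method == "naive"),
    rate_sample_every = if (record_rates) max(1L, round(1 / dt_ms)) else 0L)
  keep <- res$time_ms > warmup_ms
  out <- spike_data(rep(1L, sum(keep)), res$neuron[keep],
                    pmin(res$time_ms[keep] - warmup_ms, duration_ms),
                    n_neurons = n_neurons(net), n_trials = 1L,
                    duration_ms = duration_ms,
                    populations = as.character(net$membership),
                    dt_ms = dt_ms, seed = if (is.null(seed)) NA_integer_ else seed)
  if (record_rates) {
    br <- as.data.frame(res$rates_khz)
    names(br) <- levels(net$membership)
    br <- cbind(time_ms = res$rate_times_ms - warmup_ms, br)
    attr(out, "background_rates") <- br[br$time_ms >= 0, , drop = FALSE]
  }
  out
}

#' Simulate an ensemble of independent trials
#'
#' Runs [run_trial()] `n_trials` times with per-trial seeds
#' `seed, seed + 1, ...` (the replay contract: any trial can be reproduced
#' alone from its recorded seed) and binds the results.
#'
#' @inheritParams run_trial
#' @param n_trials number of trials.
#' @param seed base seed; trial `i` uses `seed + i - 1`.
#' @return A [spike_data()] ensemble with attribute `trial_seeds`.
#' @export
run_trials <- function(net, schedule = NULL, duration_ms, n_trials,
                       dt_ms = 0.05, seed = 1L, warmup_ms = 0) {
  seeds <- seed + seq_len(n_trials) - 1L
  trials <- lapply(seeds, function(s)
    run_trial(net, schedule, duration_ms, dt_ms = dt_ms, seed = s,
              warmup_ms = warmup_ms))
  out <- bind_trials(trials)
  attr(out, "trial_seeds") <- seeds
  out
}
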