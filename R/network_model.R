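#' Integrate-and-fire neuron parameters
#'
#' Membrane parameters of the leaky integrate-and-fire point neuron used for
#' both cell classes of the network. Defaults are the standard cortical
#' values: excitatory (pyramidal) cells have `Cm = 0.5` nF and `gL = 25` nS
#' (membrane time constant 20 ms), inhibitory interneurons `Cm = 0.2` nF and
#' `gL = 20` nS (10 ms). Both classes share the resting potential (-70 mV),
#' spike threshold (-50 mV), reset potential (-55 mV) and an absolute
#' refractory period of 1 ms.
#'
#' @param class `"excitatory"` or `"inhibitory"`; selects the default
#'   capacitance and leak conductance.
#' @param capacitance_nf membrane capacitance, nF.
#' @param leak_ns leak conductance, nS.
#' @param v_leak_mv resting (leak reversal) potential, mV.
#' @param v_thr_mv spike threshold, mV.
#' @param v_reset_mv post-spike reset potential, mV.
#' @param tau_ref_ms absolute refractory period, ms.
#' @return A list of class `"neuron_params"`.
#' @export
#' @examples
#' neuron_params("excitatory")$capacitance_nf / neuron_params("excitatory")$leak_ns * 1000
neuron_params <- function(class = c("excitatory", "inhibitory"),
                          capacitance_nf = NULL, leak_ns = NULL,
                          v_leak_mv = -70, v_thr_mv = -50,
                          v_reset_mv = -55, tau_ref_ms = 1) {
  class <- match.arg(class)
  if (is.null(capacitance_nf))
    capacitance_nf <- if (class == "excitatory") 0.5 else 0.2
  if (is.null(leak_ns))
    leak_ns <- if (class == "excitatory") 25 else 20
  p <- list(class = class, capacitance_nf = capacitance_nf, leak_ns = leak_ns,
            v_leak_mv = v_leak_mv, v_thr_mv = v_thr_mv,
            v_reset_mv = v_reset_mv, tau_ref_ms = tau_ref_ms)
  stopifnot(is.finite(unlist(p[-1])))
  if (!(p$v_reset_mv < p$v_thr_mv))
    stop("reset potential must lie below threshold")
  if (p$tau_ref_ms <= 0) stop("refractory period must be positive")
  if (p$capacitance_nf <= 0 || p$leak_ns <= 0)
    stop("capacitance and leak conductance must be positive")
  structure(p, class = "neuron_params")
}

#' Synaptic parameters (AMPA, NMDA, GABA-A)
#'
#' Kinetic constants and maximal conductances of the three receptor types.
#' AMPA and GABA-A gating decays exponentially (2 ms and 10 ms; rise times
#' are neglected as they are below 1 ms); NMDA gating has a 2 ms rise, a
#' 100 ms decay, saturation rate `alpha = 0.5` / ms, and a voltage-dependent
#' magnesium-block factor `1 / (1 + mg_prefactor * exp(-mg_slope * V))`.
#' Conductances are given per postsynaptic cell class (excitatory,
#' inhibitory), in nS.
#'
#' @param v_e_mv,v_i_mv excitatory / inhibitory reversal potentials, mV.
#' @param tau_ampa_ms,tau_gaba_ms AMPA and GABA decay time constants, ms.
#' @param tau_nmda_rise_ms,tau_nmda_decay_ms NMDA rise / decay constants, ms.
#' @param alpha_per_ms NMDA saturation rate, 1/ms.
#' @param mg_slope_per_mv,mg_prefactor magnesium-block parameters.
#' @param g_ampa_ext_ns,g_ampa_rec_ns,g_nmda_ns,g_gaba_ns length-2 named
#'   vectors `c(excitatory = ..., inhibitory = ...)`, nS.
#' @return A list of class `"synapse_params"`.
#' @export
synapse_params <- function(v_e_mv = 0, v_i_mv = -70,
                           tau_ampa_ms = 2, tau_nmda_rise_ms = 2,
                           tau_nmda_decay_ms = 100, tau_gaba_ms = 10,
                           alpha_per_ms = 0.5,
                           mg_slope_per_mv = 0.062, mg_prefactor = 0.2801,
                           g_ampa_ext_ns = c(excitatory = 2.08, inhibitory = 1.62),
                           g_ampa_rec_ns = c(excitatory = 0.104, inhibitory = 0.081),
                           g_nmda_ns = c(excitatory = 0.327, inhibitory = 0.258),
                           g_gaba_ns = c(excitatory = 1.25, inhibitory = 0.973)) {
  p <- list(v_e_mv = v_e_mv, v_i_mv = v_i_mv,
            tau_ampa_ms = tau_ampa_ms, tau_nmda_rise_ms = tau_nmda_rise_ms,
            tau_nmda_decay_ms = tau_nmda_decay_ms, tau_gaba_ms = tau_gaba_ms,
            alpha_per_ms = alpha_per_ms,
            mg_slope_per_mv = mg_slope_per_mv, mg_prefactor = mg_prefactor,
            g_ampa_ext_ns = g_ampa_ext_ns, g_ampa_rec_ns = g_ampa_rec_ns,
            g_nmda_ns = g_nmda_ns, g_gaba_ns = g_gaba_ns)
  stopifnot(is.finite(unlist(p)))
  taus <- c(tau_ampa_ms, tau_nmda_rise_ms, tau_nmda_decay_ms, tau_gaba_ms)
  if (any(taus <= 0)) stop("synaptic time constants must be positive")
  if (mg_prefactor <= 0) stop("mg_prefactor must be positive")
  if (any(c(g_ampa_ext_ns, g_ampa_rec_ns, g_nmda_ns, g_gaba_ns) <= 0))
    stop("conductances must be positive")
  structure(p, class = "synapse_params")
}

#' Depressed inter-population weight from the cohesion level
#'
#' When the within-population (cohesion) weight `w_plus` is potentiated, the
#' weight between different selective populations is depressed to `w_minus`
#' so that the mean excitatory synaptic efficacy seen by any excitatory
#' neuron stays constant (equal to the baseline 1) as `w_plus` varies:
#' `f * w_plus + (1 - f) * w_minus = 1`, where `f` is the coding fraction
#' (selective population size over total excitatory count, 80/800 = 0.1 by
#' default). The result is clamped at 0, the smallest admissible weight.
#'
#' @param w_plus cohesion level, dimensionless, `>= 1`.
#' @param f coding fraction, in (0, 1).
#' @return `w_minus = max(0, 1 - f * (w_plus - 1) / (1 - f))`.
#' @export
#' @examples
#' wminus_from_wplus(2, 0.1)   # 1 - 0.1/0.9
wminus_from_wplus <- function(w_plus, f = 0.1) {
  if (!all(is.finite(w_plus)) || !all(is.finite(f)))
    stop("nonfinite inputs to wminus_from_wplus")
  if (any(w_plus < 1)) stop("w_plus must be >= 1")
  if (any(f <= 0) || any(f >= 1)) stop("coding fraction f must be in (0, 1)")
  pmax(0, 1 - f * (w_plus - 1) / (1 - f))
}

#' Network configuration
#'
#' Assembles the full parameter set of the clustered attractor network:
#' population sizes (800 excitatory of which 5 selective populations of 80
#' plus 400 non-selective; 200 inhibitory), the structural weights (cohesion
#' `w_plus`, inhibition `w_inh`, the derived depression `w_minus`), and the
#' Ornstein-Uhlenbeck-modulated external Poisson background (baseline
#' `nu0_khz` = 2.4 kHz, i.e. 800 external afferents at 3 Hz per neuron).
#' The default fluctuation parameters (`sigma_nu_khz` 0.75% of the
#' baseline, `tau_nu_ms` = 100 ms) are deliberately small and slow: the
#' rate modulation is shared by a whole population, so it acts coherently
#' on 80 neurons at once, and slow coherent fluctuations of this size seed
#' frequent but transient attractor excursions near the bifurcation while
#' keeping the spontaneous mean rate at the low-activity level (see the
#' package vignette for the calibration).
#'
#' Several constants are not fixed by the core model and carry the
#' conventions of the underlying attractor framework; they are listed in
#' `$reconstructed` and are all overridable here or in a YAML/JSON file read
#' by [read_network_config()]: the `w_minus(w_plus)` normalisation and the
#' non-selective couplings, the inhibitory self-coupling `w_ii`, and the
#' background-noise parameters (`sigma_nu_khz`, `tau_nu_ms`).
#'
#' @param w_plus cohesion level (within-selective-population weight), `>= 1`.
#' @param w_inh inhibition level (I -> E weight), `> 0`.
#' @param w_ii inhibitory self-coupling weight.
#' @param n_excitatory,n_inhibitory cell counts.
#' @param n_selective number of stimulus-selective excitatory populations.
#' @param selective_size neurons per selective population.
#' @param nu0_khz baseline aggregated external Poisson rate per neuron, kHz.
#' @param sigma_nu_khz stationary std of the background-rate fluctuations, kHz.
#' @param tau_nu_ms relaxation time of the background-rate process, ms.
#' @param include_self include autapses (the network is fully connected).
#' @param neurons list with `excitatory` and `inhibitory` [neuron_params()].
#' @param synapses a [synapse_params()] object.
#' @return A list of class `"network_config"`.
#' @seealso [build_network()], [read_network_config()]
#' @export
network_config <- function(w_plus = 1, w_inh = 1, w_ii = 1,
                           n_excitatory = 800, n_inhibitory = 200,
                           n_selective = 5, selective_size = 80,
                           nu0_khz = 2.4, sigma_nu_khz = 0.018,
                           tau_nu_ms = 100,
                           include_self = TRUE,
                           neurons = list(excitatory = neuron_params("excitatory"),
                                          inhibitory = neuron_params("inhibitory")),
                           synapses = synapse_params()) {
  cfg <- list(w_plus = w_plus, w_inh = w_inh, w_ii = w_ii,
              n_excitatory = n_excitatory, n_inhibitory = n_inhibitory,
              n_selective = n_selective, selective_size = selective_size,
              nu0_khz = nu0_khz, sigma_nu_khz = sigma_nu_khz,
              tau_nu_ms = tau_nu_ms, include_self = include_self,
              neurons = neurons, synapses = synapses,
              reconstructed = c("w_minus_normalisation", "ns_couplings",
                                "w_ii", "nu0_khz", "sigma_nu_khz", "tau_nu_ms"))
  structure(cfg, class = "network_config")
}

#' Read a network configuration file
#'
#' Reads a hierarchical YAML or JSON file (by extension) with optional
#' sections `neurons.excitatory`, `neurons.inhibitory`, `synapses` and
#' `network`; every value defaults to the ones in [network_config()] and any
#' subset may be overridden.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"network_config"` object.
#' @export
read_network_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                "yaml" = , "yml" = yaml::read_yaml(path),
                "json" = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop("unsupported config format: ", ext))
  np <- function(class) {
    args <- raw$neurons[[class]]
    do.call(neuron_params, c(list(class = class), args))
  }
  neurons <- list(excitatory = np("excitatory"), inhibitory = np("inhibitory"))
  syn <- do.call(synapse_params, as.list(raw$synapses))
  do.call(network_config,
          c(raw$network, list(neurons = neurons, synapses = syn)))
}

#' Build the clustered network
#'
#' Lays out the neuron-to-population map and the block-structured synaptic
#' weight matrix. Neurons are ordered S1..S5 (selective populations),
#' NS (non-selective excitatory), I (inhibitory). Weight blocks, indexed
#' (presynaptic population, postsynaptic population):
#' within-selective `w_plus`; between selective populations and from NS onto
#' selective populations `w_minus` (keeping the mean excitatory efficacy onto
#' any excitatory target at the baseline 1); selective -> NS, NS -> NS and
#' all E -> I at the baseline 1; I -> E at the inhibition level `w_inh`;
#' I -> I at `w_ii`.
#'
#' @param config a [network_config()] object (or arguments passed to it).
#' @return A list of class `"network_spec"` with elements `populations`
#'   (data frame: label, size, class), `membership` (factor, one entry per
#'   neuron), `W` (P x P weight matrix, rows = presynaptic population),
#'   `w_minus`, `coding_fraction` and the embedded `config`.
#' @export
#' @examples
#' net <- build_network(network_config(w_plus = 2.1, w_inh = 1.015))
#' table(net$populations$class, net$populations$size)
build_network <- function(config = network_config()) {
  if (!inherits(config, "network_config")) stop("config must be a network_config")
  ns_size <- config$n_excitatory - config$n_selective * config$selective_size
  if (ns_size < 0)
    stop("selective populations do not fit into the excitatory pool")
  f <- config$selective_size / config$n_excitatory
  w_minus <- wminus_from_wplus(config$w_plus, f)
  sel <- paste0("S", seq_len(config$n_selective))
  labels <- c(sel, "NS", "I")
  sizes <- c(rep(config$selective_size, config$n_selective), ns_size,
             config$n_inhibitory)
  classes <- c(rep("excitatory", config$n_selective + 1L), "inhibitory")
  P <- length(labels)
  W <- matrix(1, P, P, dimnames = list(pre = labels, post = labels))
  for (i in seq_along(sel)) for (j in seq_along(sel))
    W[i, j] <- if (i == j) config$w_plus else w_minus
  W["NS", sel] <- w_minus
  W["I", c(sel, "NS")] <- config$w_inh
  W["I", "I"] <- config$w_ii
  membership <- factor(rep(labels, times = sizes), levels = labels)
  structure(list(populations = data.frame(label = labels, size = sizes,
                                          class = classes,
                                          stringsAsFactors = FALSE),
                 membership = membership,
                 W = W, w_minus = w_minus, coding_fraction = f,
                 config = config),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cfg <- x$config
  cat("Clustered attractor network:",
      sum(x$populations$size[x$populations$class == "excitatory"]), "E /",
      sum(x$populations$size[x$populations$class == "inhibitory"]), "I neurons\n")
  cat(sprintf("  w_plus = %.3f, w_minus = %.3f, w_inh = %.3f, w_ii = %.3f\n",
              cfg$w_plus, x$w_minus, cfg$w_inh, cfg$w_ii))
  cat(sprintf("  background: nu0 = %.2f kHz, sigma_nu = %.2f kHz, tau = %g ms\n",
              cfg$nu0_khz, cfg$sigma_nu_khz, cfg$tau_nu_ms))
  invisible(x)
}

# number of neurons in a network_spec
n_neurons <- function(net) sum(net$populations$size)

# integer (1-based) population index per neuron
pop_index <- function(net) as.integer(net$membership)

# neuron indices belonging to one or more population labels
neurons_of <- function(net, labels) which(net$membership %in% labels)
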