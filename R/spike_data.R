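#' Spike-train container
#'
#' A `spike_data` object is a data frame with columns `trial` (integer),
#' `neuron` (integer, 1-based) and `time_ms` (double), carrying as
#' attributes the ensemble geometry needed by the statistics layer:
#' `n_neurons`, `n_trials`, `duration_ms`, optionally the per-neuron
#' population labels, the integration step and the seed used.
#'
#' @param trial,neuron,time_ms per-spike vectors (recycled to equal length).
#' @param n_neurons,n_trials,duration_ms ensemble geometry.
#' @param populations optional character/factor vector, one per neuron.
#' @param dt_ms,seed optional provenance metadata.
#' @return A data frame of class `"spike_data"`.
#' @export
spike_data <- function(trial, neuron, time_ms, n_neurons, n_trials,
                       duration_ms, populations = NULL, dt_ms = NA_real_,
                       seed = NA_integer_) {
  df <- data.frame(trial = as.integer(trial), neuron = as.integer(neuron),
                   time_ms = as.numeric(time_ms))
  if (nrow(df) > 0) {
    if (any(df$time_ms < 0) || any(df$time_ms > duration_ms))
      stop("spike times outside [0, duration]")
    if (any(df$neuron < 1L) || any(df$neuron > n_neurons))
      stop("neuron index out of range")
    if (any(df$trial < 1L) || any(df$trial > n_trials))
      stop("trial index out of range")
  }
  structure(df, n_neurons = as.integer(n_neurons),
            n_trials = as.integer(n_trials),
            duration_ms = as.numeric(duration_ms),
            populations = populations, dt_ms = dt_ms, seed = seed,
            class = c("spike_data", "data.frame"))
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("spike_data: %d spikes, %d neurons, %d trials, %.1f ms\n",
              nrow(x), attr(x, "n_neurons"), attr(x, "n_trials"),
              attr(x, "duration_ms")))
  invisible(x)
}

#' Bind per-trial spike data into one ensemble
#'
#' @param trials a list of single-trial `spike_data` objects with identical
#'   geometry.
#' @return A `spike_data` ensemble whose `trial` column numbers the elements
#'   of `trials` in order.
#' @export
bind_trials <- function(trials) {
  stopifnot(length(trials) > 0)
  g <- trials[[1]]
  dfs <- lapply(seq_along(trials), function(i) {
    ti <- trials[[i]]
    data.frame(trial = rep(i, nrow(ti)), neuron = ti$neuron,
               time_ms = ti$time_ms)
  })
  all <- do.call(rbind, dfs)
  spike_data(all$trial, all$neuron, all$time_ms,
             n_neurons = attr(g, "n_neurons"), n_trials = length(trials),
             duration_ms = attr(g, "duration_ms"),
             populations = attr(g, "populations"),
             dt_ms = attr(g, "dt_ms"))
}

#' Restrict a spike ensemble to a subset of neurons
#'
#' Keeps only the spikes of `neurons` and renumbers them 1..k (preserving
#' order), so that downstream counting allocates rows only for the kept
#' neurons.
#'
#' @param spikes a `spike_data` object.
#' @param neurons integer vector of original neuron indices to keep.
#' @return A `spike_data` object over `length(neurons)` neurons.
#' @export
subset_neurons <- function(spikes, neurons) {
  neurons <- sort(unique(as.integer(neurons)))
  keep <- spikes$neuron %in% neurons
  remap <- match(spikes$neuron[keep], neurons)
  pops <- attr(spikes, "populations")
  spike_data(spikes$trial[keep], remap, spikes$time_ms[keep],
             n_neurons = length(neurons), n_trials = attr(spikes, "n_trials"),
             duration_ms = attr(spikes, "duration_ms"),
             populations = if (!is.null(pops)) pops[neurons],
             dt_ms = attr(spikes, "dt_ms"), seed = attr(spikes, "seed"))
}
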