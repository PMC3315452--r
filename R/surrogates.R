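#' Homogeneous Poisson spike trains
#'
#' Generates independent homogeneous Poisson trains: the count in any window
#' is Poisson, ISIs are exponential (CV = 1) and the count Fano factor is 1
#' at every window length — the null surrogate for the statistics layer.
#'
#' @param rate_hz firing rate, Hz (`>= 0`).
#' @param duration_ms train length, ms.
#' @param n_trials,n_neurons ensemble geometry.
#' @param seed optional integer seed (set for reproducibility).
#' @return A [spike_data()] ensemble.
#' @export
poisson_train <- function(rate_hz, duration_ms, n_trials = 1, n_neurons = 1,
                          seed = NULL) {
  stopifnot(rate_hz >= 0, duration_ms > 0)
  if (!is.null(seed)) set.seed(seed)
  k <- n_trials * n_neurons
  counts <- stats::rpois(k, rate_hz * duration_ms / 1000)
  total <- sum(counts)
  trial <- rep(rep(seq_len(n_trials), each = n_neurons), times = counts)
  neuron <- rep(rep(seq_len(n_neurons), times = n_trials), times = counts)
  tm <- stats::runif(total, 0, duration_ms)
  o <- order(trial, neuron, tm)
  spike_data(trial[o], neuron[o], tm[o], n_neurons = n_neurons,
             n_trials = n_trials, duration_ms = duration_ms, seed = seed)
}

#' Gamma-renewal spike trains
#'
#' Renewal processes with gamma-distributed ISIs of shape `k` and mean
#' `1/rate`: ISI CV is `1/sqrt(k)`, so `k` dials regularity (`k = 1` is
#' Poisson, large `k` approaches a clock). Used to test CV estimators and
#' the CV-Fano co-variation.
#'
#' @param shape gamma shape parameter `k > 0`.
#' @param rate_hz mean firing rate, Hz.
#' @param duration_ms,n_trials,n_neurons,seed as in [poisson_train()].
#' @return A [spike_data()] ensemble.
#' @export
gamma_renewal_train <- function(shape, rate_hz, duration_ms, n_trials = 1,
                                n_neurons = 1, seed = NULL) {
  stopifnot(shape > 0, rate_hz > 0, duration_ms > 0)
  if (!is.null(seed)) set.seed(seed)
  isi_rate <- shape * rate_hz / 1000 # gamma rate parameter, per ms
  one_train <- function() {
    n_guess <- ceiling(rate_hz * duration_ms / 1000 + 4 * sqrt(rate_hz * duration_ms / 1000) + 20)
    t <- cumsum(stats::rgamma(n_guess, shape = shape, rate = isi_rate))
    while (length(t) && t[length(t)] < duration_ms) {
      t <- c(t, t[length(t)] +
               cumsum(stats::rgamma(n_guess, shape = shape, rate = isi_rate)))
    }
    t[t < duration_ms]
  }
  trains <- vector("list", n_trials * n_neurons)
  trial <- integer(0); neuron <- integer(0); tm <- numeric(0)
  idx <- 1L
  for (tr in seq_len(n_trials)) for (nn in seq_len(n_neurons)) {
    t <- one_train()
    trial <- c(trial, rep(tr, length(t)))
    neuron <- c(neuron, rep(nn, length(t)))
    tm <- c(tm, t)
    idx <- idx + 1L
  }
  spike_data(trial, neuron, tm, n_neurons = n_neurons, n_trials = n_trials,
             duration_ms = duration_ms, seed = seed)
}

#' Closed-form count Fano factor of a two-state MMPP
#'
#' For a Markov-modulated Poisson process switching between rates
#' `rate_low` and `rate_high` with transition rates `up` (low to high) and
#' `down` (high to low), the spike count in a window of length `T` has
#' variance `lbar*T + 2*Delta^2*p1*p2*(theta*T - 1 + exp(-theta*T))/theta^2`
#' where `theta = up + down`, `p1, p2` are the stationary state
#' probabilities, `lbar` the stationary rate and `Delta` the rate
#' difference. The Fano factor follows by dividing by the mean `lbar*T`:
#' it tends to 1 for fast switching (dwell times much shorter than the
#' window, rate averaging) and grows as `1 + Delta^2*p1*p2*T/lbar` for slow
#' switching — the hallmark of attractor hopping observed at 100 ms windows.
#'
#' @param window_ms counting window, ms.
#' @param rate_low_hz,rate_high_hz the two Poisson rates, Hz.
#' @param up_per_s,down_per_s transition rates low->high and high->low, 1/s.
#' @return The analytic Fano factor (dimensionless), vectorised over
#'   `window_ms`.
#' @export
mmpp_fano <- function(window_ms, rate_low_hz, rate_high_hz, up_per_s,
                      down_per_s) {
  stopifnot(up_per_s > 0, down_per_s > 0, rate_low_hz >= 0, rate_high_hz >= 0)
  theta <- (up_per_s + down_per_s) / 1000   # per ms
  p_low <- down_per_s / (up_per_s + down_per_s)
  p_high <- up_per_s / (up_per_s + down_per_s)
  lbar <- (p_low * rate_low_hz + p_high * rate_high_hz) / 1000 # per ms
  delta <- (rate_high_hz - rate_low_hz) / 1000
  if (lbar == 0) return(rep(1, length(window_ms)))
  tt <- theta * window_ms
  1 + 2 * delta^2 * p_low * p_high * (tt - 1 + exp(-tt)) /
    (lbar * theta^2 * window_ms)
}

#' Markov-switching (two-state MMPP) spike trains
#'
#' The attractor-hopping surrogate: a Poisson process whose rate switches
#' between a low and a high level according to a two-state Markov chain.
#' Each trial draws its initial state from the stationary distribution, so
#' the ensemble is across-trial stationary as the Fano analysis assumes.
#' Slow switching (dwell times beyond the counting window) produces
#' super-Poisson counts; `freeze` disables switching and pins the rate to
#' one state — the surrogate analogue of stimulus-driven attractor
#' stabilisation, which returns the Fano factor to 1.
#'
#' @param rate_low_hz,rate_high_hz the two Poisson rates, Hz.
#' @param up_per_s,down_per_s transition rates low->high and high->low, 1/s.
#' @param duration_ms,n_trials,seed ensemble geometry and seed.
#' @param freeze `"none"` (default), `"high"` or `"low"`: clamp the
#'   modulating chain to one state.
#' @return A [spike_data()] ensemble (one neuron per trial) with attribute
#'   `analytic_fano`, a function of the window length in ms returning the
#'   closed-form [mmpp_fano()] for these parameters (1 when frozen).
#' @export
markov_switching_train <- function(rate_low_hz, rate_high_hz, up_per_s,
                                   down_per_s, duration_ms, n_trials = 1,
                                   seed = NULL, freeze = c("none", "high", "low")) {
  stopifnot(rate_low_hz >= 0, rate_high_hz >= 0, up_per_s > 0, down_per_s > 0,
            duration_ms > 0)
  freeze <- match.arg(freeze)
  if (!is.null(seed)) set.seed(seed)
  p_high <- up_per_s / (up_per_s + down_per_s)
  rates <- c(rate_low_hz, rate_high_hz) / 1000     # per ms
  leave <- c(up_per_s, down_per_s) / 1000          # per ms
  trial <- integer(0); tm <- numeric(0)
  for (tr in seq_len(n_trials)) {
    state <- switch(freeze,
                    none = if (stats::runif(1) < p_high) 2L else 1L,
                    high = 2L, low = 1L)
    t0 <- 0
    times <- numeric(0)
    while (t0 < duration_ms) {
      dwell <- if (freeze == "none") stats::rexp(1, rate = leave[state]) else Inf
      t1 <- min(t0 + dwell, duration_ms)
      k <- stats::rpois(1, rates[state] * (t1 - t0))
      if (k > 0) times <- c(times, stats::runif(k, t0, t1))
      t0 <- t1
      state <- 3L - state
    }
    times <- sort(times)
    trial <- c(trial, rep(tr, length(times)))
    tm <- c(tm, times)
  }
  out <- spike_data(trial, rep(1L, length(tm)), tm, n_neurons = 1,
                    n_trials = n_trials, duration_ms = duration_ms,
                    seed = seed)
  attr(out, "analytic_fano") <- if (freeze == "none") {
    function(window_ms) mmpp_fano(window_ms, rate_low_hz, rate_high_hz,
                                  up_per_s, down_per_s)
  } else {
    function(window_ms) rep(1, length(window_ms))
  }
  out
}
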