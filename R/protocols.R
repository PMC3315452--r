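# points (mean, var) of a neuron subset, for one window
group_points <- function(table, window, neurons) {
  pts <- variance_mean_per_neuron(table, window)
  pts[pts$neuron %in% neurons, , drop = FALSE]
}

#' Stimulation experiment: spontaneous vs stimulated Fano factor
#'
#' The core protocol: each trial runs `pre_ms` of spontaneous activity
#' followed by `stim_ms` of extra Poisson drive at `lambda_hz` onto one
#' selective population. Spike counts are taken in `window_ms` windows; the
#' comparison is between the last spontaneous window and the stimulation
#' window. Neurons of the stimulated population form the non-matched group
#' (the stimulus moves their rates); neurons of the other selective
#' populations form the matched group, compared through the mean-matching
#' procedure so that rate changes cannot masquerade as variability changes.
#'
#' @param config a [network_config()]; `w_plus` / `w_inh` may be overridden.
#' @param w_plus,w_inh optional overrides of the cohesion / inhibition level.
#' @param lambda_hz stimulus rate, Hz.
#' @param n_trials trials averaged (1000 in full runs; 200 in fast runs).
#' @param pre_ms,stim_ms protocol durations, ms.
#' @param window_ms counting window, ms.
#' @param stim_pop stimulated population label.
#' @param dt_ms integration step, ms.
#' @param seed base seed; trial `i` uses `seed + i - 1`.
#' @param warmup_ms discarded per-trial burn-in (see [run_trial()]) so the
#'   spontaneous period reflects stationary activity.
#' @param match_draws random matchings averaged in [mean_match()].
#' @return A list of class `"stimulation_result"` with elements
#'   `non_matched` and `matched` (each: `spontaneous`, `stimulated`,
#'   `difference` = spontaneous - stimulated), `selective_unmatched` (all
#'   selective neurons, no matching — the headline Fano values), and
#'   metadata (`w_plus`, `w_inh`, `lambda_hz`, `n_trials`, `seeds`).
#' @export
run_stimulation_experiment <- function(config = network_config(),
                                       w_plus = NULL, w_inh = NULL,
                                       lambda_hz = 200, n_trials = 1000,
                                       pre_ms = 500, stim_ms = 100,
                                       window_ms = 100, stim_pop = "S1",
                                       dt_ms = 0.05, seed = 1L,
                                       warmup_ms = 3000, match_draws = 50) {
  if (!is.null(w_plus)) config$w_plus <- w_plus
  if (!is.null(w_inh)) config$w_inh <- w_inh
  net <- build_network(config)
  sched <- if (lambda_hz > 0)
    stimulus_schedule(stim_pop, pre_ms, pre_ms + stim_ms, lambda_hz)
  spikes <- run_trials(net, if (lambda_hz > 0) sched else NULL,
                       duration_ms = pre_ms + stim_ms, n_trials = n_trials,
                       dt_ms = dt_ms, seed = seed, warmup_ms = warmup_ms)
  ct <- count_spikes(spikes, window_ms)
  w_spont <- round(pre_ms / window_ms)
  w_stim <- w_spont + 1L
  sel_labels <- grep("^S[0-9]+$", levels(net$membership), value = TRUE)
  stim_neurons <- neurons_of(net, stim_pop)
  other_neurons <- neurons_of(net, setdiff(sel_labels, stim_pop))
  nm_sp <- fano_regression(group_points(ct, w_spont, stim_neurons))
  nm_st <- fano_regression(group_points(ct, w_stim, stim_neurons))
  mm <- mean_match(group_points(ct, w_spont, other_neurons),
                   group_points(ct, w_stim, other_neurons),
                   n_draws = match_draws)
  all_sp <- fano_regression(group_points(ct, w_spont, c(stim_neurons, other_neurons)))
  all_st <- fano_regression(group_points(ct, w_stim, c(stim_neurons, other_neurons)))
  structure(list(
    non_matched = list(spontaneous = nm_sp$slope, stimulated = nm_st$slope,
                       difference = nm_sp$slope - nm_st$slope),
    matched = list(spontaneous = mm$a$slope, stimulated = mm$b$slope,
                   difference = mm$a$slope - mm$b$slope,
                   slope_sd = c(spontaneous = mm$a$slope_sd,
                                stimulated = mm$b$slope_sd)),
    selective_unmatched = list(spontaneous = all_sp$slope,
                               stimulated = all_st$slope,
                               difference = all_sp$slope - all_st$slope),
    w_plus = config$w_plus, w_inh = config$w_inh, lambda_hz = lambda_hz,
    n_trials = n_trials, window_ms = window_ms,
    seeds = attr(spikes, "trial_seeds")),
    class = "stimulation_result")
}

#' @export
print.stimulation_result <- function(x, ...) {
  cat(sprintf("stimulation experiment (w+ = %.2f, winh = %.3f, lambda = %g Hz, %d trials)\n",
              x$w_plus, x$w_inh, x$lambda_hz, x$n_trials))
  cat(sprintf("  non-matched: spont %.3f -> stim %.3f (reduction %.3f)\n",
              x$non_matched$spontaneous, x$non_matched$stimulated,
              x$non_matched$difference))
  cat(sprintf("  matched:     spont %.3f -> stim %.3f (reduction %.3f)\n",
              x$matched$spontaneous, x$matched$stimulated,
              x$matched$difference))
  invisible(x)
}

# Fano trajectory over consecutive windows for a neuron group
fano_trajectory <- function(ct, neurons) {
  vapply(seq_along(ct$starts_ms), function(w) {
    pts <- group_points(ct, w, neurons)
    if (all(pts$mean == 0)) NA_real_ else fano_regression(pts)$slope
  }, numeric(1))
}

#' Attention experiment: Fano time course with and without bias
#'
#' One stimulus is presented to a selective population; after
#' `att_onset_ms` an attentional bias (`lambda_att_hz` of extra exogenous
#' drive, a baseline-shift / contrast-increase mechanism) is added in the
#' attended condition. Both conditions share trial seeds, so the comparison
#' is paired. Returns the windowed Fano trajectory of the stimulated
#' population's neurons in both conditions.
#'
#' @param config a [network_config()].
#' @param lambda_hz stimulus rate, Hz.
#' @param lambda_att_hz attentional bias rate, Hz.
#' @param n_trials trials per condition.
#' @param pre_ms spontaneous period before stimulus onset, ms.
#' @param stim_ms stimulus duration, ms.
#' @param att_onset_ms attention onset, ms from trial start (default: 500 ms
#'   after stimulus onset).
#' @param window_ms,dt_ms,seed as in [run_stimulation_experiment()].
#' @param target population receiving stimulus and bias.
#' @return A data frame: `window_start_ms`, `fano_unattended`,
#'   `fano_attended`, with protocol metadata in attributes.
#' @export
run_attention_experiment <- function(config = network_config(),
                                     lambda_hz = 200, lambda_att_hz = 50,
                                     n_trials = 200, pre_ms = 500,
                                     stim_ms = 1000,
                                     att_onset_ms = pre_ms + 500,
                                     window_ms = 100, dt_ms = 0.05,
                                     seed = 1L, warmup_ms = 3000,
                                     target = "S1") {
  stopifnot(lambda_att_hz >= 0)
  net <- build_network(config)
  dur <- pre_ms + stim_ms
  base <- stimulus_schedule(target, pre_ms, dur, lambda_hz)
  att <- rbind(base, stimulus_schedule(target, att_onset_ms, dur, lambda_att_hz))
  sp_un <- run_trials(net, base, dur, n_trials, dt_ms = dt_ms, seed = seed,
                      warmup_ms = warmup_ms)
  sp_at <- run_trials(net, att, dur, n_trials, dt_ms = dt_ms, seed = seed,
                      warmup_ms = warmup_ms)
  neurons <- neurons_of(net, target)
  ct_un <- count_spikes(sp_un, window_ms)
  ct_at <- count_spikes(sp_at, window_ms)
  out <- data.frame(window_start_ms = ct_un$starts_ms,
                    fano_unattended = fano_trajectory(ct_un, neurons),
                    fano_attended = fano_trajectory(ct_at, neurons))
  attr(out, "protocol") <- list(lambda_hz = lambda_hz,
                                lambda_att_hz = lambda_att_hz,
                                att_onset_ms = att_onset_ms,
                                n_trials = n_trials, target = target,
                                w_plus = config$w_plus, w_inh = config$w_inh)
  out
}

#' Biased competition: attentional variability reduction vs inhibition
#'
#' Two selective populations receive an identical stimulus (target and
#' distractor competing in a receptive field); in the attended condition the
#' target additionally receives the attentional bias. For each inhibition
#' level the Fano factor of each stimulated population (regression over its
#' 80 neurons, averaged over the stimulation-period windows) is compared
#' between conditions; the reduction is unattended minus attended.
#'
#' @param config a [network_config()] (its `w_plus` sets the cohesion).
#' @param w_inh_values inhibition levels to scan.
#' @param lambda_hz identical stimulus rate to both populations, Hz.
#' @param lambda_att_hz attentional bias to the target, Hz.
#' @param n_trials trials per condition (2000 in full runs).
#' @param pre_ms,stim_ms protocol durations, ms.
#' @param window_ms,dt_ms,seed as elsewhere.
#' @param target,distractor stimulated population labels.
#' @return A data frame: `w_inh`, `fano_target_unatt`, `fano_target_att`,
#'   `reduction_target`, and the same three for the distractor.
#' @export
run_biased_competition <- function(config = network_config(),
                                   w_inh_values = config$w_inh,
                                   lambda_hz = 200, lambda_att_hz = 50,
                                   n_trials = 2000, pre_ms = 500,
                                   stim_ms = 1000, window_ms = 100,
                                   dt_ms = 0.05, seed = 1L, warmup_ms = 3000,
                                   target = "S1", distractor = "S2") {
  rows <- lapply(seq_along(w_inh_values), function(k) {
    cfg <- config
    cfg$w_inh <- w_inh_values[k]
    net <- build_network(cfg)
    dur <- pre_ms + stim_ms
    both <- stimulus_schedule(c(target, distractor), c(pre_ms, pre_ms),
                              c(dur, dur), c(lambda_hz, lambda_hz))
    att <- rbind(both, stimulus_schedule(target, pre_ms, dur, lambda_att_hz))
    s0 <- seed + (k - 1L) * 2L * n_trials
    sp_un <- run_trials(net, both, dur, n_trials, dt_ms = dt_ms, seed = s0,
                        warmup_ms = warmup_ms)
    sp_at <- run_trials(net, att, dur, n_trials, dt_ms = dt_ms,
                        seed = s0 + n_trials, warmup_ms = warmup_ms)
    stim_w <- which(count_spikes(sp_un, window_ms)$starts_ms >= pre_ms)
    mean_fano <- function(sp, pop) {
      ct <- count_spikes(sp, window_ms)
      mean(fano_trajectory(ct, neurons_of(net, pop))[stim_w], na.rm = TRUE)
    }
    data.frame(w_inh = cfg$w_inh,
               fano_target_unatt = mean_fano(sp_un, target),
               fano_target_att = mean_fano(sp_at, target),
               fano_distractor_unatt = mean_fano(sp_un, distractor),
               fano_distractor_att = mean_fano(sp_at, distractor))
  })
  out <- do.call(rbind, rows)
  out$reduction_target <- out$fano_target_unatt - out$fano_target_att
  out$reduction_distractor <- out$fano_distractor_unatt - out$fano_distractor_att
  out
}

#' Fano-factor map over a parameter grid
#'
#' Runs the stimulation experiment on every cell of a (cohesion,
#' inhibition) — or, with a scalar `w_plus`, (inhibition, stimulus) — grid
#' and collects the spontaneous, stimulated and difference Fano factors for
#' the matched and non-matched groups. Cells are independent; a failing cell
#' is recorded and the scan continues. Each cell's base seed is recorded so
#' any cell can be replayed bit-identically.
#'
#' @param w_plus,w_inh grids of cohesion / inhibition levels.
#' @param lambda_hz stimulus rate(s), Hz; scalar or a grid (crossed with the
#'   other axes).
#' @param config base [network_config()].
#' @param n_trials trials per cell (1000 in full runs, 200 in fast mode).
#' @param seed base seed; cell `i` uses `seed + (i-1) * n_trials`.
#' @param ... passed to [run_stimulation_experiment()].
#' @return A data frame of class `"fano_map"`: the axes, the six Fano
#'   layers, `seed`, `ok` (and `message` for failed cells).
#' @export
scan_fano_map <- function(w_plus, w_inh, lambda_hz = 200,
                          config = network_config(), n_trials = 200,
                          seed = 1L, ...) {
  grid <- expand.grid(w_plus = w_plus, w_inh = w_inh, lambda_hz = lambda_hz)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell_seed <- seed + (i - 1L) * n_trials
    base <- data.frame(grid[i, , drop = FALSE], seed = cell_seed,
                       row.names = NULL)
    res <- tryCatch(
      run_stimulation_experiment(config, w_plus = grid$w_plus[i],
                                 w_inh = grid$w_inh[i],
                                 lambda_hz = grid$lambda_hz[i],
                                 n_trials = n_trials, seed = cell_seed, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      cbind(base, fano_spont_matched = NA, fano_stim_matched = NA,
            diff_matched = NA, fano_spont_nonmatched = NA,
            fano_stim_nonmatched = NA, diff_nonmatched = NA,
            ok = FALSE, message = conditionMessage(res))
    } else {
      cbind(base,
            fano_spont_matched = res$matched$spontaneous,
            fano_stim_matched = res$matched$stimulated,
            diff_matched = res$matched$difference,
            fano_spont_nonmatched = res$non_matched$spontaneous,
            fano_stim_nonmatched = res$non_matched$stimulated,
            diff_nonmatched = res$non_matched$difference,
            ok = TRUE, message = "")
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fano_map", "data.frame")
  out
}
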