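# Protocol mechanics are exercised on a 200-neuron miniature network: the
# orchestration (schedules, windows, groups, seeds) is size-independent.

test_that("stimulation experiment is replayable and null under zero drive", {
  cfg <- mini_config(w_plus = 1.5)
  r1 <- run_stimulation_experiment(cfg, lambda_hz = 0, n_trials = 60,
                                   seed = 2, match_draws = 10)
  r2 <- run_stimulation_experiment(cfg, lambda_hz = 0, n_trials = 60,
                                   seed = 2, match_draws = 10)
  expect_equal(r1$non_matched$spontaneous, r2$non_matched$spontaneous)
  expect_equal(r1$matched$difference, r2$matched$difference)

  # without a stimulus the two windows are exchangeable: no systematic
  # Fano change in either group
  expect_lt(abs(r1$non_matched$difference), 0.5)
  expect_lt(abs(r1$matched$difference), 0.5)
  expect_equal(r1$seeds, 2:61)
})

test_that("a 1x1 scan reduces to the single experiment and its difference layer", {
  cfg <- mini_config(w_plus = 1.5)
  map <- scan_fano_map(1.5, 1.0, lambda_hz = 150, config = cfg,
                       n_trials = 40, seed = 7, match_draws = 5)
  one <- run_stimulation_experiment(cfg, w_plus = 1.5, w_inh = 1.0,
                                    lambda_hz = 150, n_trials = 40, seed = 7,
                                    match_draws = 5)
  expect_equal(nrow(map), 1)
  expect_true(map$ok)
  expect_equal(map$fano_spont_nonmatched, one$non_matched$spontaneous)
  expect_equal(map$diff_nonmatched,
               map$fano_spont_nonmatched - map$fano_stim_nonmatched)
  expect_equal(map$diff_matched, map$fano_spont_matched - map$fano_stim_matched)
})

test_that("scans record failures per cell and continue", {
  cfg <- mini_config(w_plus = 1.5, nu0_khz = 0, sigma_nu_khz = 0)
  # a silent network makes the Fano regression fail ("no active neurons");
  # the scan must keep going and mark the cell
  map <- scan_fano_map(c(1.0, 1.5), 1.0, lambda_hz = 0, config = cfg,
                       n_trials = 5, seed = 1, match_draws = 2)
  expect_equal(nrow(map), 2)
  expect_true(all(!map$ok))
  expect_match(map$message[1], "active")
})

test_that("attention with zero bias reproduces the unattended time course", {
  cfg <- mini_config(w_plus = 1.5)
  tc <- run_attention_experiment(cfg, lambda_hz = 150, lambda_att_hz = 0,
                                 n_trials = 30, pre_ms = 200, stim_ms = 400,
                                 att_onset_ms = 400, seed = 5)
  # a zero-rate bias adds no input and no extra randomness: identical trials
  expect_equal(tc$fano_attended, tc$fano_unattended)
  expect_equal(nrow(tc), 6)
})

test_that("biased competition is symmetric without an attentional bias", {
  cfg <- mini_config(w_plus = 1.5)
  bc <- run_biased_competition(cfg, w_inh_values = 1.0, lambda_hz = 150,
                               lambda_att_hz = 0, n_trials = 40,
                               pre_ms = 200, stim_ms = 300, seed = 3)
  # the two stimulated populations are exchangeable: their (noisy) Fano
  # factors agree within Monte-Carlo error, and the "reduction" columns
  # carry no systematic sign
  expect_lt(abs(bc$fano_target_unatt - bc$fano_distractor_unatt), 0.6)
  expect_true(all(is.finite(unlist(bc[1, ]))))
})

test_that("schedules validate their intervals and populations", {
  expect_error(stimulus_schedule("S1", 100, 50, 10))
  expect_error(stimulus_schedule("S1", 0, 100, -5))
  net <- build_network(mini_config())
  bad <- stimulus_schedule("S9", 0, 100, 10)
  expect_error(run_trial(net, bad, 200, seed = 1), "unknown population")
  dup <- rbind(stimulus_schedule("S1", 0, 100, 10),
               stimulus_schedule("S1", 0, 100, 10))
  expect_error(run_trial(net, dup, 200, seed = 1), "duplicate")
})
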