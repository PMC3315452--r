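test_that("Poisson surrogate has unit CV and unit Fano factor", {
  expect_equal(nrow(poisson_train(0, 1000, seed = 1)), 0)

  sp <- poisson_train(10, 1e6, seed = 2) # ~1e4 intervals
  expect_equal(cv_isi(sp)$cv, 1, tolerance = 0.02)

  counts <- as.numeric(count_spikes(poisson_train(30, 100, n_trials = 1e4,
                                                  seed = 3), 100)$counts)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.05)
})

test_that("gamma renewal surrogate controls ISI regularity", {
  # shape 1 is Poisson: ISI distributions indistinguishable by KS
  g1 <- gamma_renewal_train(1, 20, 5e5, seed = 4)
  isi <- diff(g1$time_ms)
  ks <- suppressWarnings(stats::ks.test(isi, "pexp", rate = 20 / 1000))
  expect_gt(ks$p.value, 0.01)

  g4 <- gamma_renewal_train(4, 20, 5e5, seed = 5)
  expect_equal(cv_isi(g4)$cv, 0.5, tolerance = 0.03)

  # renewal theorem: realised rate matches the requested one
  expect_equal(nrow(g4) / 5e5 * 1000, 20, tolerance = 0.02)
})

test_that("MMPP closed-form Fano is validated by Monte-Carlo", {
  # degenerate switching reduces to Poisson
  expect_equal(mmpp_fano(100, 20, 20, 2, 2), 1)

  # limits: slow switching inflates, fast switching averages out
  expect_gt(mmpp_fano(100, 5, 50, 1, 1), 1.4)
  expect_equal(mmpp_fano(100, 5, 50, 500, 500), 1, tolerance = 0.05)
  expect_gt(mmpp_fano(100, 5, 50, 500, 500), 1)

  # measured vs analytic at 1e4 trials, two parameter sets
  for (par in list(c(5, 50, 1, 1), c(10, 40, 2, 4))) {
    sp <- markov_switching_train(par[1], par[2], par[3], par[4],
                                 duration_ms = 100, n_trials = 1e4, seed = 6)
    counts <- as.numeric(count_spikes(sp, 100)$counts)
    measured <- var(counts) / mean(counts)
    analytic <- attr(sp, "analytic_fano")(100)
    expect_equal(measured, analytic, tolerance = 0.05)
  }
})

test_that("switching surrogate is stationary and seed-reproducible", {
  sp1 <- markov_switching_train(5, 50, 1, 3, 5e4, n_trials = 20, seed = 9)
  sp2 <- markov_switching_train(5, 50, 1, 3, 5e4, n_trials = 20, seed = 9)
  expect_identical(sp1$time_ms, sp2$time_ms)

  # stationary rate equals the dwell-weighted mean of the two rates
  p_high <- 1 / (1 + 3)
  expect_equal(nrow(sp1) / (20 * 50), (1 - p_high) * 5 + p_high * 50,
               tolerance = 0.05)
})

test_that("freezing the high state removes super-Poisson variability", {
  # the surrogate analogue of attractor stabilisation by a stimulus:
  # hopping produces Fano > 1.4, pinning the chain restores Fano = 1
  hopping <- markov_switching_train(5, 50, 1, 1, 100, n_trials = 1e4, seed = 10)
  frozen <- markov_switching_train(5, 50, 1, 1, 100, n_trials = 1e4, seed = 11,
                                   freeze = "high")
  f_hop <- {
    c <- as.numeric(count_spikes(hopping, 100)$counts); var(c) / mean(c)
  }
  f_frz <- {
    c <- as.numeric(count_spikes(frozen, 100)$counts); var(c) / mean(c)
  }
  expect_gt(f_hop, 1.4)
  expect_equal(f_frz, 1, tolerance = 0.05)
  expect_equal(attr(frozen, "analytic_fano")(100), 1)
})

test_that("regularity and count variability move together across surrogates", {
  # increasing gamma shape makes trains more regular and counts less
  # variable: CV and Fano decrease in lockstep (rank correlation 1)
  shapes <- c(1, 2, 4, 8)
  cvs <- fanos <- numeric(length(shapes))
  for (i in seq_along(shapes)) {
    long <- gamma_renewal_train(shapes[i], 20, 4e5, seed = 20 + i)
    cvs[i] <- cv_isi(long)$cv
    trials <- gamma_renewal_train(shapes[i], 20, 100, n_trials = 4000,
                                  seed = 40 + i)
    counts <- as.numeric(count_spikes(trials, 100)$counts)
    fanos[i] <- var(counts) / mean(counts)
  }
  expect_equal(cor(cvs, fanos, method = "spearman"), 1)
  expect_true(all(diff(cvs) < 0))
  expect_true(all(diff(fanos) < 0))
})
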