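test_that("spike counting tiles trials into half-open windows", {
  sp <- spike_data(trial = c(1, 1, 1), neuron = c(1, 1, 1),
                   time_ms = c(10, 150, 199), n_neurons = 1, n_trials = 1,
                   duration_ms = 200)
  ct <- count_spikes(sp, 100)
  expect_equal(as.numeric(ct$counts[1, 1, ]), c(1, 2))

  # boundary spike at exactly W lands in the second window
  spb <- spike_data(1, 1, 100, n_neurons = 1, n_trials = 1, duration_ms = 200)
  expect_equal(as.numeric(count_spikes(spb, 100)$counts[1, 1, ]), c(0, 1))

  # empty train counts to all zeros over the full geometry
  spe <- spike_data(integer(0), integer(0), numeric(0), n_neurons = 3,
                    n_trials = 2, duration_ms = 300)
  expect_true(all(count_spikes(spe, 100)$counts == 0))

  expect_error(count_spikes(spb, 300), "shorter than")
  expect_error(spike_data(1, 1, -5, 1, 1, 200), "outside")
})

test_that("across-trial moments match a direct two-pass computation", {
  # identical counts -> zero variance; {0,1} -> mean .5, var .5
  sp <- spike_data(trial = c(1, 2), neuron = c(1, 1), time_ms = c(10, 20),
                   n_neurons = 2, n_trials = 2, duration_ms = 100)
  pts <- variance_mean_per_neuron(count_spikes(sp, 100), 1)
  expect_equal(pts$var, c(0, 0))
  sp2 <- spike_data(1, 1, 10, n_neurons = 1, n_trials = 2, duration_ms = 100)
  pts2 <- variance_mean_per_neuron(count_spikes(sp2, 100), 1)
  expect_equal(pts2$mean, 0.5)
  expect_equal(pts2$var, 0.5)

  # random count tables against the brute-force oracle
  set.seed(42)
  for (rep in 1:5) {
    counts <- array(rpois(20 * 30 * 2, 3), dim = c(20, 30, 2))
    tab <- structure(list(counts = counts, window_ms = 100,
                          starts_ms = c(0, 100)), class = "count_table")
    got <- variance_mean_per_neuron(tab, 2)
    want_m <- apply(counts[, , 2], 1, mean)
    want_v <- apply(counts[, , 2], 1, var)
    expect_equal(got$mean, want_m)
    expect_equal(got$var, want_v)
  }
  one_trial <- structure(list(counts = array(1, c(2, 1, 1)), window_ms = 100,
                              starts_ms = 0), class = "count_table")
  expect_error(variance_mean_per_neuron(one_trial, 1), "2 trials")
})

test_that("origin-constrained regression recovers exact and Poisson slopes", {
  expect_equal(fano_regression(data.frame(mean = 1:5, var = 1:5))$slope, 1)
  expect_equal(fano_regression(data.frame(mean = c(1, 2, 3),
                                          var = c(2, 4, 6)))$slope, 2)
  expect_error(fano_regression(data.frame(mean = c(0, 0), var = c(0, 0))),
               "no active neurons")

  # invariance under neuron relabeling
  set.seed(7)
  pts <- data.frame(mean = runif(50, 0, 5), var = runif(50, 0, 8))
  expect_equal(fano_regression(pts)$slope,
               fano_regression(pts[sample(50), ])$slope)

  # Monte-Carlo: homogeneous Poisson counts have unit Fano factor
  sp <- poisson_train(10, 100, n_trials = 1000, n_neurons = 80, seed = 1)
  pts <- variance_mean_per_neuron(count_spikes(sp, 100), 1)
  expect_equal(fano_regression(pts)$slope, 1, tolerance = 0.05)
})

test_that("mean matching equalises count distributions and preserves slopes", {
  set.seed(3)
  pts <- data.frame(mean = runif(100, 0, 6), var = runif(100, 0, 9))
  mm <- mean_match(pts, pts, n_draws = 5)
  expect_equal(mm$a$slope, fano_regression(pts)$slope)
  expect_equal(mm$b$slope, fano_regression(pts)$slope)
  expect_equal(unname(mm$removed_fraction), c(0, 0))

  # disjoint mean ranges cannot be matched
  lo <- data.frame(mean = runif(20, 0, 1), var = 1)
  hi <- data.frame(mean = runif(20, 5, 6), var = 1)
  expect_error(mean_match(lo, hi), "no overlap")

  # hand-enumerated matching: A has 10 points in bin [0,1) and 10 in [1,2),
  # B only the 10 in [0,1); the common distribution keeps exactly A's first
  # bin, so matched A equals the regression on that subset, on every draw
  a <- data.frame(mean = c(seq(0.05, 0.95, length.out = 10),
                           seq(1.05, 1.95, length.out = 10)),
                  var = c(rep(2, 10), rep(8, 10)))
  b <- data.frame(mean = seq(0.05, 0.95, length.out = 10), var = rep(3, 10))
  mm2 <- mean_match(a, b, bin_width = 1, n_draws = 20)
  expect_equal(mm2$a$slope, fano_regression(a[1:10, ])$slope)
  expect_equal(mm2$a$slope_sd, 0)
  expect_equal(mm2$b$slope, fano_regression(b)$slope)
  expect_equal(mm2$common_histogram$count, c(10, 0))
})

test_that("ISI variability estimators recover renewal-process constants", {
  # periodic train
  per <- spike_data(1, 1, seq(10, 990, by = 10), 1, 1, 1000)
  expect_equal(cv_isi(per, min_intervals = 50)$cv, 0)
  expect_equal(cv2(seq(10, 990, by = 10)), 0)
  expect_equal(cv2(c(0, 1, 4)), 1) # intervals (1, 3): 2*2/4

  # Poisson: CV -> 1
  sp <- poisson_train(20, 6e5, seed = 2)
  st <- cv_isi(sp)
  expect_equal(st$cv, 1, tolerance = 0.03)
  expect_equal(st$cv_pooled, 1, tolerance = 0.03)

  # gamma(4): CV -> 1/2
  g4 <- gamma_renewal_train(4, 20, 6e5, seed = 3)
  expect_equal(cv_isi(g4)$cv, 0.5, tolerance = 0.03)

  expect_error(cv_isi(per, min_intervals = 1e6), "intervals")
  expect_error(cv2(c(1, 2)), "3 spikes")

  # CV2 equals an independent pairwise re-computation on a Poisson train
  times <- sort(runif(500, 0, 1e4))
  isi <- diff(times)
  brute <- mean(sapply(seq_len(length(isi) - 1), function(i)
    2 * abs(isi[i + 1] - isi[i]) / (isi[i + 1] + isi[i])))
  expect_equal(cv2(times), brute)
})

test_that("kernel rate estimation conserves spike count", {
  none <- kernel_rate(numeric(0), duration_ms = 1000)
  expect_true(all(none$rate_hz == 0))

  one <- kernel_rate(500, duration_ms = 1000, sigma_ms = 50)
  expect_equal(max(one$rate_hz), 1000 * dnorm(0, sd = 50), tolerance = 1e-6)
  expect_equal(one$time_ms[which.max(one$rate_hz)], 500)

  set.seed(5)
  sp <- sort(runif(200, 300, 700))
  tr <- kernel_rate(sp, duration_ms = 1000, sigma_ms = 50)
  integral <- sum(tr$rate_hz) * 1 / 1000 # dt = 1 ms
  expect_equal(integral, 200, tolerance = 1e-4)
})

test_that("rate distributions report pooled moments", {
  const <- rate_distribution(rep(5, 100))
  expect_equal(const$sd, 0)
  set.seed(8)
  x <- matrix(rexp(5000, 1 / 3), ncol = 5)
  rd <- rate_distribution(x)
  expect_equal(rd$mean, mean(x))
  expect_equal(rd$sd, sd(as.numeric(x)))
  expect_equal(rd$n, 5000)
})
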