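#' Windowed spike counts
#'
#' Counts spikes per neuron, trial and counting window. Windows of length
#' `window_ms` tile `[0, duration)` as half-open intervals `[t, t + W)`, so
#' every spike is counted exactly once; a boundary spike at `t = W` falls in
#' the second window. If the duration is not a multiple of `W` the trailing
#' remainder is not counted.
#'
#' @param spikes a [spike_data()] ensemble.
#' @param window_ms counting-window length, ms (100 ms throughout the
#'   variability analyses).
#' @return A list of class `"count_table"`: `counts` (array neuron x trial x
#'   window), `window_ms`, `starts_ms`.
#' @export
count_spikes <- function(spikes, window_ms) {
  stopifnot(window_ms > 0)
  duration <- attr(spikes, "duration_ms")
  if (duration < window_ms) stop("trial duration shorter than the window")
  if (nrow(spikes) > 0 && (any(spikes$time_ms < 0) || any(spikes$time_ms > duration)))
    stop("spike times outside [0, duration)")
  n_neurons <- attr(spikes, "n_neurons")
  n_trials <- attr(spikes, "n_trials")
  n_win <- floor(duration / window_ms + 1e-9)
  win <- floor(spikes$time_ms / window_ms) + 1L
  keep <- win <= n_win
  idx <- spikes$neuron[keep] +
    n_neurons * (spikes$trial[keep] - 1L) +
    n_neurons * n_trials * (win[keep] - 1L)
  counts <- tabulate(idx, nbins = n_neurons * n_trials * n_win)
  dim(counts) <- c(n_neurons, n_trials, n_win)
  structure(list(counts = counts, window_ms = window_ms,
                 starts_ms = window_ms * (seq_len(n_win) - 1)),
            class = "count_table")
}

#' Across-trial count mean and variance per neuron
#'
#' For one counting window, the across-trial sample mean and unbiased
#' (n - 1) sample variance of each neuron's spike count — the scatter points
#' that the Fano regression is fitted to.
#'
#' @param table a [count_spikes()] result.
#' @param window window index (1-based).
#' @return A data frame with columns `neuron`, `mean`, `var`.
#' @export
variance_mean_per_neuron <- function(table, window) {
  stopifnot(inherits(table, "count_table"))
  x <- table$counts[, , window, drop = FALSE]
  dim(x) <- dim(table$counts)[1:2]
  n <- ncol(x)
  if (n < 2) stop("at least 2 trials are required")
  m <- rowMeans(x)
  v <- (rowSums(x^2) - n * m^2) / (n - 1)
  data.frame(neuron = seq_len(nrow(x)), mean = m, var = pmax(v, 0))
}

#' Fano factor by origin-constrained regression
#'
#' The population Fano factor is the slope of the ordinary least-squares
#' regression of per-neuron spike-count variance on mean, constrained to
#' pass through the origin: `F = sum(m * v) / sum(m^2)`. Neurons with zero
#' mean count stay in the table but contribute nothing to either sum (the
#' ratio variance/mean is undefined at the origin).
#'
#' @param points data frame with columns `mean` and `var` (one row per
#'   neuron), e.g. from [variance_mean_per_neuron()].
#' @return A list of class `"fano_result"`: `slope`, `points`, `n_neurons`,
#'   `n_active`, `matching` (`"none"` here).
#' @export
#' @examples
#' fano_regression(data.frame(mean = c(1, 2, 3), var = c(2, 4, 6)))$slope  # 2
fano_regression <- function(points) {
  stopifnot(all(c("mean", "var") %in% names(points)))
  m <- points$mean
  v <- points$var
  if (any(m < 0) || any(v < 0)) stop("negative mean or variance")
  active <- m > 0
  if (!any(active)) stop("no active neurons")
  slope <- sum(m[active] * v[active]) / sum(m[active]^2)
  structure(list(slope = slope, points = points,
                 n_neurons = nrow(points), n_active = sum(active),
                 matching = "none"),
            class = "fano_result")
}

#' @export
print.fano_result <- function(x, ...) {
  cat(sprintf("Fano factor (origin-constrained slope): %.4f  [%d/%d active neurons, matching: %s]\n",
              x$slope, x$n_active, x$n_neurons, x$matching))
  invisible(x)
}

#' Mean-matched Fano comparison between two conditions
#'
#' Removes the rate confound from a Fano comparison by equalising the two
#' conditions' distributions of mean spike counts before regressing. Mean
#' counts are histogrammed with bins of `bin_width` counts; the greatest
#' common distribution is the bin-wise minimum of the two histograms; within
#' each bin, surplus points are removed uniformly at random from each
#' condition until its histogram equals the common one, and the
#' origin-constrained regression is fitted to the survivors. The removal is
#' repeated `n_draws` times with independent draws; the reported slope is
#' the average over draws (with its spread).
#'
#' @param points_a,points_b data frames with `mean` and `var` columns.
#' @param bin_width histogram bin width in counts (default 1 count per
#'   window).
#' @param n_draws number of independent random matchings averaged.
#' @return A list with elements `a` and `b` (each a `"fano_result"` with
#'   `slope` the across-draw average, `slope_sd` its spread, and
#'   `matching = "mean_matched"`), plus `removed_fraction`, `n_draws`,
#'   `bin_width`.
#' @export
mean_match <- function(points_a, points_b, bin_width = 1, n_draws = 50) {
  stopifnot(bin_width > 0, n_draws >= 1)
  bin_a <- floor(points_a$mean / bin_width)
  bin_b <- floor(points_b$mean / bin_width)
  bins <- sort(unique(c(bin_a, bin_b)))
  ha <- vapply(bins, function(b) sum(bin_a == b), integer(1))
  hb <- vapply(bins, function(b) sum(bin_b == b), integer(1))
  common <- pmin(ha, hb)
  if (sum(common) == 0) stop("no overlap between the two mean-count distributions")
  draw_once <- function(points, bin) {
    keep <- unlist(lapply(seq_along(bins), function(k) {
      idx <- which(bin == bins[k])
      if (length(idx) <= common[k]) idx else sample(idx, common[k])
    }))
    fano_regression(points[keep, , drop = FALSE])$slope
  }
  sl_a <- replicate(n_draws, draw_once(points_a, bin_a))
  sl_b <- replicate(n_draws, draw_once(points_b, bin_b))
  res <- function(sl, points) {
    structure(list(slope = mean(sl), slope_sd = stats::sd(sl),
                   points = points, n_neurons = nrow(points),
                   n_matched = sum(common), matching = "mean_matched"),
              class = "fano_result")
  }
  list(a = res(sl_a, points_a), b = res(sl_b, points_b),
       removed_fraction = c(a = 1 - sum(common) / nrow(points_a),
                            b = 1 - sum(common) / nrow(points_b)),
       common_histogram = data.frame(bin = bins, count = common),
       n_draws = n_draws, bin_width = bin_width)
}

# per-neuron, per-trial interspike intervals of a spike ensemble
isi_list <- function(spikes) {
  if (nrow(spikes) == 0) return(list())
  o <- order(spikes$trial, spikes$neuron, spikes$time_ms)
  key <- interaction(spikes$trial[o], spikes$neuron[o], drop = TRUE)
  lapply(split(spikes$time_ms[o], key), function(t) if (length(t) >= 2) diff(t) else numeric(0))
}

#' Interspike-interval coefficient of variation
#'
#' Characterises spike-train irregularity by the CV of the ISI distribution
#' (std/mean; 1 for a Poisson process, `1/sqrt(k)` for a gamma renewal
#' process of shape `k`). Two pooling conventions are reported: `cv` is the
#' per-train CV averaged over trains with at least two intervals (robust to
#' rate differences across neurons), `cv_pooled` is the CV of all intervals
#' pooled together.
#'
#' @param spikes a [spike_data()] object (long recordings, one or more
#'   neurons/trials).
#' @param min_intervals minimum pooled interval count required.
#' @return A list of class `"isi_stats"`: `cv`, `cv_pooled`, `cv2` (mean of
#'   Holt's CV2 over trains, see [cv2()]), `n_intervals`.
#' @export
cv_isi <- function(spikes, min_intervals = 100) {
  isis <- isi_list(spikes)
  pooled <- unlist(isis, use.names = FALSE)
  if (length(pooled) < min_intervals)
    stop("fewer than min_intervals = ", min_intervals, " interspike intervals")
  per <- vapply(isis, function(x) if (length(x) >= 2) stats::sd(x) / mean(x) else NA_real_,
                numeric(1))
  cv2s <- vapply(isis, function(x) {
    if (length(x) >= 2) mean(2 * abs(diff(x)) / (x[-1] + x[-length(x)])) else NA_real_
  }, numeric(1))
  structure(list(cv = mean(per, na.rm = TRUE),
                 cv_pooled = stats::sd(pooled) / mean(pooled),
                 cv2 = mean(cv2s, na.rm = TRUE),
                 n_intervals = length(pooled)),
            class = "isi_stats")
}

#' @export
print.isi_stats <- function(x, ...) {
  cat(sprintf("ISI stats: CV = %.3f (pooled %.3f), CV2 = %.3f, %d intervals\n",
              x$cv, x$cv_pooled, x$cv2, x$n_intervals))
  invisible(x)
}

#' Holt's CV2 of a single spike train
#'
#' A local irregularity index that needs only consecutive interval pairs:
#' the mean over pairs of `2 * |I[i+1] - I[i]| / (I[i+1] + I[i])`. It is 0
#' for a periodic train, about 1 for Poisson firing, and bounded above by 2.
#'
#' @param times spike times of one train, ms (need not be sorted).
#' @return CV2, dimensionless.
#' @export
cv2 <- function(times) {
  times <- sort(as.numeric(times))
  if (length(times) < 3) stop("CV2 requires at least 3 spikes")
  i <- diff(times)
  mean(2 * abs(diff(i)) / (i[-1] + i[-length(i)]))
}

#' Gaussian-kernel firing-rate estimate
#'
#' Smooths a spike train by convolution with a unit-area Gaussian kernel
#' (default width 50 ms), so that the integral of the trajectory equals the
#' spike count (up to edge losses). Evaluated on a regular grid.
#'
#' @param times spike times, ms.
#' @param duration_ms trajectory length, ms.
#' @param sigma_ms Gaussian kernel width (sd), ms.
#' @param dt_ms evaluation grid step, ms.
#' @param n_pool divide by this count to obtain a per-neuron rate when
#'   `times` pools several neurons (default 1).
#' @return A data frame with columns `time_ms` and `rate_hz`.
#' @export
kernel_rate <- function(times, duration_ms, sigma_ms = 50, dt_ms = 1,
                        n_pool = 1) {
  stopifnot(sigma_ms > 0, dt_ms > 0, duration_ms > 0)
  grid <- seq(0, duration_ms, by = dt_ms)
  nb <- length(grid)
  counts <- numeric(nb)
  if (length(times) > 0) {
    b <- pmin(nb, pmax(1L, round(times / dt_ms) + 1L))
    tb <- tabulate(b, nbins = nb)
    counts <- tb
  }
  half <- ceiling(5 * sigma_ms / dt_ms)
  kern <- stats::dnorm(seq(-half, half) * dt_ms, sd = sigma_ms) # per ms
  padded <- c(numeric(half), counts, numeric(half))
  sm <- stats::filter(padded, kern, sides = 2)
  rate <- as.numeric(sm[(half + 1):(half + nb)]) * 1000 / n_pool # Hz
  data.frame(time_ms = grid, rate_hz = rate)
}

#' Smoothed per-population rate trajectories
#'
#' Pools the spikes of each population of a network simulation, smooths the
#' pooled train with a unit-area Gaussian kernel and divides by the
#' population size, giving each population's mean rate trajectory in Hz per
#' neuron.
#'
#' @param spikes a single-trial [spike_data()] with a `populations`
#'   attribute (as produced by [run_trial()]).
#' @param net the [build_network()] spec the simulation used.
#' @param labels which populations (default: the selective populations).
#' @param sigma_ms,dt_ms kernel width and grid step, ms.
#' @return A data frame: `time_ms` plus one rate column per population.
#' @export
population_rates <- function(spikes, net, labels = NULL, sigma_ms = 50,
                             dt_ms = 1) {
  if (is.null(labels))
    labels <- grep("^S[0-9]+$", levels(net$membership), value = TRUE)
  duration <- attr(spikes, "duration_ms")
  out <- NULL
  for (lab in labels) {
    idx <- neurons_of(net, lab)
    tr <- kernel_rate(spikes$time_ms[spikes$neuron %in% idx], duration,
                      sigma_ms = sigma_ms, dt_ms = dt_ms,
                      n_pool = length(idx))
    if (is.null(out)) out <- data.frame(time_ms = tr$time_ms)
    out[[lab]] <- tr$rate_hz
  }
  out
}

#' Distribution of smoothed rate fluctuations
#'
#' Pools rate-trajectory samples (e.g. the five selective populations'
#' smoothed rates during spontaneous activity) into one histogram and
#' reports its first two moments. During attractor-hopping dynamics the
#' distribution is wide, peaked at zero rate and long-tailed.
#'
#' @param trajectories numeric vector, matrix (one column per trajectory) or
#'   data frame of rate samples in Hz (a `time_ms` column is ignored).
#' @param breaks passed to [graphics::hist()]-style binning via
#'   [base::cut()]; either a bin width in Hz (scalar) or explicit breaks.
#' @return A list of class `"rate_distribution"`: `mean`, `sd`, `density`
#'   (data frame: mid, density), `n`.
#' @export
rate_distribution <- function(trajectories, breaks = 1) {
  if (is.data.frame(trajectories))
    trajectories <- as.matrix(trajectories[setdiff(names(trajectories), "time_ms")])
  x <- as.numeric(trajectories)
  if (length(x) == 0) stop("no rate samples")
  if (length(breaks) == 1) {
    lo <- floor(min(x) / breaks) * breaks
    hi <- ceiling(max(x) / breaks) * breaks
    breaks <- seq(lo, max(hi, lo + breaks), by = breaks)
  }
  cuts <- cut(x, breaks = breaks, include.lowest = TRUE, right = FALSE)
  counts <- as.integer(table(cuts))
  widths <- diff(breaks)
  structure(list(mean = mean(x), sd = stats::sd(x),
                 density = data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                                      density = counts / (sum(counts) * widths)),
                 n = length(x)),
            class = "rate_distribution")
}

#' @export
print.rate_distribution <- function(x, ...) {
  cat(sprintf("rate distribution: mean = %.2f Hz, sd = %.2f Hz (%d samples)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}
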