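# ---- numerical pieces -------------------------------------------------------

# run a block of code with the caller's RNG stream untouched
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# cached 64-point Gauss-Legendre rule on [0, 1]
gl_rule <- function() {
  if (is.null(.af_cache$gl)) {
    r <- pracma::gaussLegendre(64, 0, 1)
    .af_cache$gl <- r
  }
  .af_cache$gl
}

# erfcx that stays finite for large arguments (pracma overflows to NaN
# beyond ~2.6e1): asymptotic series 1/(x sqrt(pi)) (1 - 1/(2x^2) + ...)
safe_erfcx <- function(x) {
  out <- numeric(length(x))
  big <- x > 25
  if (any(big)) {
    xb <- x[big]
    out[big] <- (1 - 0.5 / xb^2 + 0.75 / xb^4) / (xb * sqrt(pi))
  }
  if (any(!big)) out[!big] <- pracma::erfcx(x[!big])
  out
}

# \int_a^b erfcx(-u) du, the Ricciardi first-passage integrand after the
# identity e^{u^2} (1 + erf(u)) = erfcx(-u). On u > 0 the further identity
# erfcx(-u) = 2 e^{u^2} - erfcx(u) isolates the explosive part, which has
# the closed form 2 \int e^{u^2} = sqrt(pi) * erfi(u); what remains is
# smooth and bounded, handled by fixed Gauss-Legendre quadrature.
ricciardi_integral <- function(a, b) {
  stopifnot(b >= a)
  gl <- gl_rule()
  quad <- function(f, lo, hi) {
    if (hi <= lo) return(0)
    h <- hi - lo
    sum(gl$w * f(lo + h * gl$x)) * h
  }
  neg_part <- quad(function(u) safe_erfcx(-u), a, min(b, 0))
  if (b <= 0) return(neg_part)
  a0 <- max(a, 0)
  if (b > 26) stop("integration bound too large") # callers cut off earlier
  pos_part <- sqrt(pi) * (pracma::erfi(b) - pracma::erfi(a0)) -
    quad(pracma::erfcx, a0, b)
  neg_part + pos_part
}

#' First-passage firing rate of the leaky IF neuron
#'
#' Stationary firing rate of a leaky integrate-and-fire neuron driven by
#' Gaussian white noise such that the free (no-threshold) membrane potential
#' has mean `mu` and stationary standard deviation `sigma`
#' (Ricciardi's mean-first-passage-time formula):
#' `rate = 1 / (tau_ref + tau * sqrt(pi) * I)` with
#' `I = integral of exp(u^2) (1 + erf(u))` between the reset and threshold
#' bounds `(V - mu) / (sqrt(2) * sigma)` (the `sqrt(2)` converts the
#' stationary sd to the diffusion amplitude the classical formula is written
#' in). For coloured (synaptically filtered) input the
#' bounds can be shifted by `bound_shift` (approximately
#' `1.03 * sqrt(tau_syn / tau_m)`). The rate is continuous and increasing in
#' `mu`, vanishes for subthreshold `mu` as `sigma -> 0`, and saturates at
#' `1/tau_ref`.
#'
#' @param mu_mv stationary mean membrane potential (no-threshold), mV.
#' @param sigma_mv stationary potential fluctuation, mV (`>= 0`).
#' @param neuron a [neuron_params()] object (threshold, reset, refractory
#'   period and, via `Cm/gL`, the default membrane time constant).
#' @param tau_m_ms effective membrane time constant, ms; defaults to
#'   `Cm / gL` of `neuron`.
#' @param bound_shift dimensionless shift of both integration bounds
#'   correcting for synaptic filtering (0 = white noise).
#' @return Firing rate in Hz (vectorised over `mu_mv`).
#' @export
#' @examples
#' lif_transfer_rate(-60, 5)     # fluctuation-driven firing
#' lif_transfer_rate(-60, 1e-9)  # subthreshold, noiseless: 0
lif_transfer_rate <- function(mu_mv, sigma_mv,
                              neuron = neuron_params("excitatory"),
                              tau_m_ms = NULL, bound_shift = 0) {
  if (is.null(tau_m_ms))
    tau_m_ms <- neuron$capacitance_nf * 1000 / neuron$leak_ns
  stopifnot(all(sigma_mv >= 0), tau_m_ms > 0)
  vthr <- neuron$v_thr_mv; vres <- neuron$v_reset_mv
  tref <- neuron$tau_ref_ms
  one <- function(mu, sigma) {
    if (sigma < 1e-9) {
      if (mu <= vthr) return(0)
      return(1000 / (tref + tau_m_ms * log((mu - vres) / (mu - vthr))))
    }
    b <- (vthr - mu) / (sqrt(2) * sigma) + bound_shift
    a <- (vres - mu) / (sqrt(2) * sigma) + bound_shift
    if (b > 10) { # deeply subthreshold: asymptotic tail of the integral
      if (b * b > 700) return(0)
      I <- exp(b * b) / b * (1 + 1 / (2 * b * b))
      return(1000 / (tref + tau_m_ms * sqrt(pi) * I))
    }
    1000 / (tref + tau_m_ms * sqrt(pi) * ricciardi_integral(a, b))
  }
  mapply(one, mu_mv, sigma_mv)
}

# ---- stationary NMDA gating -------------------------------------------------

# Stationary mean of the saturating NMDA gating as a function of the
# presynaptic rate. The auxiliary variable x and the factor (1 - s) are
# anticorrelated, so the naive closure <s> = a*x/(1 + a*x) with
# a = alpha*tau_d, x = nu*tau_r overestimates; instead the exact gating ODE
# driven by a Poisson train is integrated once on a rate grid (seeded, hence
# deterministic) and interpolated monotonically. Cached per parameter set.
nmda_gating_fn <- function(synapses = synapse_params()) {
  key <- paste0("psi_", synapses$tau_nmda_rise_ms, "_",
                synapses$tau_nmda_decay_ms, "_", synapses$alpha_per_ms)
  if (!is.null(.af_cache[[key]])) return(.af_cache[[key]])
  nu_hz <- c(0, 0.5, 1, 2, 3, 4, 6, 8, 11, 15, 20, 27, 35, 45, 60, 80, 105,
             135, 170, 215, 270, 340, 430, 540, 680, 850, 1000)
  psi <- with_preserved_seed(20120329, {
    nmda_gating_mc_cpp(nu_hz / 1000, synapses$tau_nmda_rise_ms,
                       synapses$tau_nmda_decay_ms, synapses$alpha_per_ms,
                       duration = 2e5, dt = 0.05)
  })
  psi[1] <- 0
  sf <- stats::splinefun(nu_hz / 1000, psi, method = "monoH.FC")
  top <- max(nu_hz) / 1000
  fn <- function(nu_khz) sf(pmin(pmax(nu_khz, 0), top))
  .af_cache[[key]] <- fn
  fn
}

# ---- population self-consistency map ---------------------------------------

# precompute the static structure used by the rate map
mf_structure <- function(net, nu_ext_khz = net$config$nu0_khz) {
  cfg <- net$config
  syn <- cfg$synapses
  P <- nrow(net$populations)
  is_exc <- net$populations$class == "excitatory"
  cls <- ifelse(is_exc, "excitatory", "inhibitory")
  par <- lapply(cls, function(cl) cfg$neurons[[cl]])
  list(P = P, is_exc = is_exc, N = net$populations$size, W = net$W,
       syn = syn, nu_ext = nu_ext_khz, psi = nmda_gating_fn(syn),
       cm = vapply(par, function(p) p$capacitance_nf * 1000, 1),
       gl = vapply(par, function(p) p$leak_ns, 1),
       vl = vapply(par, function(p) p$v_leak_mv, 1),
       vthr = vapply(par, function(p) p$v_thr_mv, 1),
       vres = vapply(par, function(p) p$v_reset_mv, 1),
       tref = vapply(par, function(p) p$tau_ref_ms, 1),
       g_ext = vapply(cls, function(cl) unname(syn$g_ampa_ext_ns[cl]), 1),
       g_a = vapply(cls, function(cl) unname(syn$g_ampa_rec_ns[cl]), 1),
       g_n = vapply(cls, function(cl) unname(syn$g_nmda_ns[cl]), 1),
       g_g = vapply(cls, function(cl) unname(syn$g_gaba_ns[cl]), 1),
       neurons = cfg$neurons)
}

# one application of the population rate map: nu (kHz) -> Phi(nu) (kHz).
# Gaussian-current approximation with effective membrane time constant,
# NMDA current linearised around the self-consistent mean potential, and
# first-passage transfer with synaptic-filtering bound shift.
mf_phi <- function(nu_khz, st) {
  syn <- st$syn
  tau_a <- syn$tau_ampa_ms; tau_g <- syn$tau_gaba_ms
  ve <- syn$v_e_mv; vi <- syn$v_i_mv
  gam <- syn$mg_prefactor; bet <- syn$mg_slope_per_mv
  exc <- st$is_exc
  sA_pre <- ifelse(exc, tau_a * nu_khz, 0)
  sN_pre <- ifelse(exc, st$psi(nu_khz), 0)
  sG_pre <- ifelse(exc, 0, tau_g * nu_khz)
  SA <- as.numeric(crossprod(st$W, st$N * sA_pre))
  SN <- as.numeric(crossprod(st$W, st$N * sN_pre))
  SG <- as.numeric(crossprod(st$W, st$N * sG_pre))
  sext <- tau_a * st$nu_ext
  out <- numeric(st$P)
  for (q in seq_len(st$P)) {
    vbar <- -55
    mu <- vbar; tau_eff <- st$cm[q] / st$gl[q]
    for (it in 1:6) {
      mg <- 1 / (1 + gam * exp(-bet * vbar))
      mgp <- bet * gam * exp(-bet * vbar) * mg^2
      a_n <- st$g_n[q] * SN[q] * (mg + (vbar - ve) * mgp)
      i_n <- st$g_n[q] * SN[q] * mg * (vbar - ve)
      v_n <- if (abs(a_n) > 1e-12) vbar - i_n / a_n else ve
      G <- st$gl[q] + st$g_ext[q] * sext + st$g_a[q] * SA[q] + a_n +
        st$g_g[q] * SG[q]
      if (G < 5) G <- 5
      tau_eff <- st$cm[q] / G
      mu <- (st$gl[q] * st$vl[q] + st$g_ext[q] * sext * ve +
               st$g_a[q] * SA[q] * ve + a_n * v_n + st$g_g[q] * SG[q] * vi) / G
      vbar <- mu - (st$vthr[q] - st$vres[q]) * nu_khz[q] * tau_eff
      vbar <- min(max(vbar, -90), st$vthr[q])
    }
    # shot-noise diffusion: kick k = g tau_A (V - VE) / Cm at rate nu_ext
    # gives stationary potential variance k^2 nu_ext tau_eff / 2
    sigma2 <- st$g_ext[q]^2 * (vbar - ve)^2 * st$nu_ext * tau_a^2 * tau_eff /
      (2 * st$cm[q]^2)
    shift <- 1.03 * sqrt(tau_a / tau_eff)
    nrn <- st$neurons[[if (exc[q]) "excitatory" else "inhibitory"]]
    r <- lif_transfer_rate(mu, sqrt(max(sigma2, 0)), neuron = nrn,
                           tau_m_ms = tau_eff, bound_shift = shift) / 1000
    out[q] <- min(r, 1 / st$tref[q])
  }
  out
}

# ---- fixed points and bifurcation census ------------------------------------

mf_starts <- function(st, n_random, seed) {
  sel <- which(st$is_exc)[-sum(st$is_exc)] # selective pops (all exc but NS)
  P <- st$P
  low <- c(rep(3e-3, P - 1), 9e-3)
  highs <- lapply(sel, function(k) {
    v <- c(rep(1e-3, P - 1), 12e-3); v[k] <- 0.05; v
  })
  inh_high <- c(rep(1e-4, P - 1), 0.03)
  all_high <- c(rep(0.04, P - 1), 0.03)
  rand <- with_preserved_seed(seed, {
    lapply(seq_len(n_random), function(i) stats::runif(P, 0, 0.06))
  })
  c(list(low = low), highs, list(inh_high = inh_high, all_high = all_high),
    rand)
}

#' Stationary states of the network (mean-field fixed points)
#'
#' Solves the population self-consistency equations `nu = Phi(nu)` by damped
#' fixed-point iteration from a multi-start set (the symmetric low state,
#' each single-population-high state, a high-inhibition state, an all-high
#' state and random vectors), merges duplicate solutions, and labels each
#' fixed point stable or unstable by the numerical Jacobian of the rate map:
#' a fixed point of the relaxation dynamics `tau dnu/dt = -nu + Phi(nu)` is
#' stable when every eigenvalue of `dPhi/dnu` has real part below 1 (at the
#' destabilisation boundary a real eigenvalue crosses +1). Input-rate
#' fluctuations are
#' absent in the reduction (the background drive enters only through its
#' mean and Poisson shot noise), matching the regime in which the
#' bifurcation structure is defined.
#'
#' @param net a [build_network()] spec.
#' @param nu_ext_khz external drive, kHz (defaults to the config baseline).
#' @param damping fixed-point damping factor.
#' @param tol_khz convergence tolerance on the rate vector, kHz.
#' @param max_iter iteration cap per start.
#' @param merge_hz duplicate-merging distance, Hz.
#' @param n_random,seed random multi-start count and seed (the solve is
#'   deterministic for fixed arguments).
#' @return A list of class `"fixed_points"`; each element has `rates_hz`
#'   (named vector over populations), `stable`, `max_eigen_re`,
#'   `residual_hz`. Empty (with a warning) if no start converges.
#' @export
find_fixed_points <- function(net, nu_ext_khz = net$config$nu0_khz,
                              damping = 0.1, tol_khz = 1e-6, max_iter = 1e4,
                              merge_hz = 0.5, n_random = 4, seed = 1L) {
  st <- mf_structure(net, nu_ext_khz)
  sols <- list()
  for (start in mf_starts(st, n_random, seed)) {
    nu <- start
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      phi <- mf_phi(nu, st)
      step <- phi - nu
      nu <- nu + damping * step
      if (max(abs(step)) < tol_khz) { ok <- TRUE; break }
    }
    if (ok) sols[[length(sols) + 1]] <- nu
  }
  if (length(sols) == 0) {
    warning("mean-field iteration did not converge from any start")
    return(structure(list(), class = "fixed_points"))
  }
  # merge duplicates
  uniq <- list()
  for (s in sols) {
    dup <- any(vapply(uniq, function(u) max(abs(u - s)) * 1000 < merge_hz,
                      logical(1)))
    if (!dup) uniq[[length(uniq) + 1]] <- s
  }
  labels <- net$populations$label
  out <- lapply(uniq, function(nu) {
    J <- matrix(0, st$P, st$P)
    h <- 1e-5
    f0 <- mf_phi(nu, st)
    for (k in seq_len(st$P)) {
      e <- nu; e[k] <- e[k] + h
      J[, k] <- (mf_phi(e, st) - f0) / h
    }
    ev <- eigen(J, only.values = TRUE)$values
    growth <- max(Re(ev))
    r <- nu * 1000
    names(r) <- labels
    list(rates_hz = r, stable = growth < 1, max_eigen_re = growth,
         residual_hz = max(abs(f0 - nu)) * 1000)
  })
  structure(out, class = "fixed_points")
}

#' @export
print.fixed_points <- function(x, ...) {
  cat(length(x), "mean-field fixed point(s)\n")
  for (s in x) {
    cat(sprintf("  [%s, growth %.3f] ", if (s$stable) "stable" else "unstable",
                s$max_eigen_re))
    cat(paste(sprintf("%s=%.1f", names(s$rates_hz), s$rates_hz),
              collapse = " "), "Hz\n")
  }
  invisible(x)
}

# number of stable states and the largest rate separation among them
census_cell <- function(fp) {
  stable <- Filter(function(s) s$stable, fp)
  n <- length(stable)
  maxdiff <- 0
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      maxdiff <- max(maxdiff,
                     max(abs(stable[[i]]$rates_hz - stable[[j]]$rates_hz)))
  }
  c(n_stable = n, max_rate_diff_hz = maxdiff)
}

#' Bifurcation census over the (cohesion, inhibition) plane
#'
#' Runs the mean-field fixed-point search on a grid of cohesion (`w_plus`)
#' and inhibition (`w_inh`) levels and records, per cell, the number of
#' coexisting stable states and the largest rate difference between them.
#' The diagram separates a monostable low-activity region (one stable state)
#' from a multistable region — at sufficient cohesion and intermediate
#' inhibition — where the five single-population-high attractors coexist
#' with the low state (six stable states; the low state persists just above
#' onset, the subcritical signature).
#'
#' @param w_plus,w_inh monotone grids of cohesion / inhibition levels.
#' @param config base [network_config()] whose other fields are held fixed.
#' @param ... passed to [find_fixed_points()].
#' @return A data frame of class `"bifurcation_map"` with columns `w_plus`,
#'   `w_inh`, `n_stable`, `max_rate_diff_hz`.
#' @export
bifurcation_scan <- function(w_plus, w_inh, config = network_config(), ...) {
  stopifnot(!is.unsorted(w_plus), !is.unsorted(w_inh))
  grid <- expand.grid(w_plus = w_plus, w_inh = w_inh)
  res <- t(apply(grid, 1, function(row) {
    cfg <- config
    cfg$w_plus <- row[["w_plus"]]
    cfg$w_inh <- row[["w_inh"]]
    census_cell(find_fixed_points(build_network(cfg), ...))
  }))
  out <- cbind(grid, as.data.frame(res))
  class(out) <- c("bifurcation_map", "data.frame")
  out
}

#' Working point just below the bifurcation
#'
#' Scans the cohesion axis at a fixed inhibition level and returns the
#' last grid cell before the stable-state census leaves 1 — the nearest
#' cell below the lower boundary of the multistability region. There the
#' activated attractors are not yet stable, but the dynamics around them is
#' already partially attracting, so fluctuations drive frequent transient
#' excursions towards them: spontaneous rate fluctuations are large and
#' across-trial count variability is high, while the mean rate stays at the
#' low-activity level.
#'
#' @param w_inh inhibition level to scan along.
#' @param w_plus cohesion grid (monotone increasing).
#' @param config base [network_config()].
#' @param ... passed to [find_fixed_points()].
#' @return A list `w_plus`, `w_inh`, `census` (the scanned column).
#' @export
choose_working_point <- function(w_inh = 1.0,
                                 w_plus = seq(1.95, 2.1, by = 0.025),
                                 config = network_config(), ...) {
  col <- bifurcation_scan(w_plus, w_inh, config = config, ...)
  multi <- which(col$n_stable > 1)
  idx <- if (length(multi) == 0) nrow(col) else max(1, min(multi) - 1)
  list(w_plus = col$w_plus[idx], w_inh = w_inh, census = col)
}
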