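---
title: "Stimulus-driven variability reduction in a multistable attractor network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus-driven variability reduction in a multistable attractor network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Cortical neurons are noisy twice over: spike timing is irregular within a
trial, and spike counts vary strongly across repetitions of the same trial.
The across-trial variability, measured by the Fano factor
$F = \sigma^2_N / \mu_N$ of spike counts $N$ in a fixed window, typically
*drops* when a stimulus is presented or attention is allocated. This package
implements a circuit-level explanation: a recurrent network whose spontaneous
state sits near the edge of a bifurcation, beyond which several stimulus-
selective attractors become stable. In the spontaneous condition,
fluctuations drive occasional excursions towards these (marginally or truly
stable) activated states, producing large slow rate fluctuations and
super-Poisson counts. An external drive — sensory or attentional — stabilises
one attractor, suppresses the excursions, and the Fano factor falls towards
the Poisson value of 1. The package provides the spiking simulator, a
mean-field bifurcation analysis, the trial-based statistics, surrogate
generators that isolate each statistical mechanism, and the experiment
protocols that put them together.

## The spiking network

The network has $N = 1000$ fully connected integrate-and-fire neurons: 800
excitatory (five stimulus-selective populations of 80 plus 400 non-selective)
and 200 inhibitory. Subthreshold dynamics follow

$$C_m \dot V = -g_L (V - V_L) - I_{syn},$$

with $I_{syn}$ the sum of external AMPA, recurrent AMPA, NMDA and GABA-A
currents, each of the form $g \, w \, s \, (V - V_{rev})$. NMDA conductance is
multiplied by the magnesium-block factor
$[1 + 0.2801\, e^{-0.062 V}]^{-1}$. AMPA and GABA gating decays with 2 ms and
10 ms constants and jumps by one per presynaptic spike (rise times below 1 ms
are neglected); NMDA gating has a 2 ms rise variable $x$ and saturating decay
$\dot s = -s/100\,\mathrm{ms} + 0.5\,\mathrm{ms}^{-1} x (1 - s)$. All cell
and synapse constants are exposed (and overridable) through
`neuron_params()`, `synapse_params()` and `network_config()`; a YAML/JSON
file can override any of them via `read_network_config()`.

Structure is carried entirely by dimensionless weights between the seven
populations. Within a selective population the recurrent weight is the
cohesion level $w_+$; between selective populations (and from the
non-selective pool onto selective ones) it is
$w_- = \max\{0, 1 - f (w_+ - 1)/(1 - f)\}$ with coding fraction $f = 0.1$,
which keeps the mean excitatory efficacy onto any excitatory neuron exactly
at the baseline 1 as $w_+$ varies. Inhibitory-to-excitatory weights carry the
inhibition level $w_{inh}$; all remaining weights are 1 (the inhibitory
self-coupling is configurable). The connections from selective to
non-selective neurons and the inhibitory self-coupling are conventions of
the underlying attractor framework and are listed in
`network_config()$reconstructed`.

Every neuron receives an aggregated external Poisson train through its own
AMPA gating variable. The baseline rate is $\nu_0 = 2.4$ kHz (800 afferents
at 3 Hz); per population the instantaneous rate follows an
Ornstein-Uhlenbeck process with relaxation time 10 ms, rectified at zero on
emission. Integration is forward Euler at `dt = 0.05` ms (configurable down
to 0.02 ms; the smallest time constants are 1-2 ms, so there are at least 20
steps per constant); spikes are recorded at the step boundary where the
threshold is crossed, a 0.05 ms quantisation far below every analysis
window. Because block weights are uniform, recurrent input enters only
through per-population gating sums, giving $O(N + P^2)$ cost per step; a
naive $O(N^2)$ per-synapse path is retained and checked against it on a
miniature network.

### Trial initialisation

A cold start (zero gating, dispersed potentials) is an arbitrary state that
takes seconds of simulated time to forget, mostly because excursion
statistics equilibrate on the timescale of the excursions themselves.
`run_trial(warmup_ms = ...)` therefore simulates a discarded burn-in before
$t = 0$; the experiment protocols default to a 3 s warm-up. The dominant
slow variable is the excursion occupancy itself: excursions towards the
activated attractors last a few hundred ms at the default operating point,
so occupancy equilibrates within a couple of seconds — but a cold-started
trial has zero occupancy and systematically underestimates the
across-trial count variance of stationary spontaneous activity. The
warm-up lets the 500 ms "stabilisation" period of the stimulation protocol
start from stationary conditions rather than manufacture them from
scratch.

## Mean-field reduction and the bifurcation diagram

Stationary states are found with the standard reduction of this model class:
each population is summarised by a rate $\nu_p$; presynaptic gating is
replaced by its stationary mean ($\tau_A \nu$, $\tau_G \nu$ for AMPA/GABA);
currents are Gaussian; and the firing rate is the first-passage (Ricciardi)
rate of a leaky IF neuron with effective time constant $C_m / G$, where $G$
collects leak and all mean synaptic conductances. The NMDA current is
linearised around the self-consistent mean potential
$\bar V = \mu - (V_{thr} - V_{reset})\,\nu\,\tau_{eff}$, the noise term uses
the external AMPA drive only, and both integration bounds carry the
coloured-noise correction $1.03 \sqrt{\tau_A / \tau_{eff}}$. Two numerical
points deserve note:

* **NMDA saturation.** The auxiliary rise variable $x$ and the factor
  $(1-s)$ anticorrelate, so the naive closure
  $\langle s \rangle = \alpha \tau_d \langle x \rangle /
  (1 + \alpha \tau_d \langle x \rangle)$ overestimates the stationary NMDA
  gating. The package instead integrates the exact gating ODE driven by a
  Poisson train once, on a fixed rate grid with a fixed internal seed, and
  interpolates monotonically; the table is cached per parameter set. This
  keeps the reduction consistent with what the simulator actually does.
* **Transfer-function integral.** With
  $e^{u^2}(1 + \operatorname{erf} u) = \operatorname{erfcx}(-u)$ and, for
  $u > 0$, $\operatorname{erfcx}(-u) = 2 e^{u^2} - \operatorname{erfcx}(u)$,
  the explosive part has the closed form $\sqrt{\pi}\,\operatorname{erfi}$,
  and the remainders are smooth and bounded, handled by 64-point
  Gauss-Legendre quadrature; deeply subthreshold inputs use the asymptotic
  tail. The analytic rate is validated against an independent Euler-Maruyama
  first-passage simulation in the test suite (5% tolerance).

`find_fixed_points()` iterates $\nu \leftarrow \nu + 0.1\,(\Phi(\nu) - \nu)$
(tolerance $10^{-6}$ kHz, at most $10^4$ iterations) from a multi-start set:
the symmetric low state, each single-population-high state, a
high-inhibition state, an all-high state, and seeded random vectors.
Duplicates merge below 0.5 Hz. Stability is labelled through the numerical
Jacobian of $\Phi$: the relaxation dynamics
$\tau \dot\nu = -\nu + \Phi(\nu)$ is stable when all eigenvalues of
$\partial\Phi/\partial\nu$ have real part below 1. (A spectral-radius rule
would mislabel strongly contracting states whose undamped map overshoots —
large negative eigenvalues — while the real-part rule coincides with it at
the physical destabilisation boundary, where a real eigenvalue crosses +1.)

At baseline cohesion the diagram has a single symmetric low-activity state
(excitatory cells near 3 Hz, inhibitory near 9.5 Hz, close to the simulated
2.8/9.3 Hz with fluctuations switched off). Raising $w_+$ at intermediate
$w_{inh}$ destabilises nothing immediately — instead, five
permutation-equivalent single-population-high states appear alongside the
still-stable low state: six coexisting attractors, the subcritical
signature. Deeper into the region further (two-population-high) states can
appear; `bifurcation_scan()` reports the full stable census per grid cell.

## Trial statistics

`count_spikes()` tiles $[0, T)$ with half-open 100 ms windows;
`variance_mean_per_neuron()` takes across-trial means and unbiased
variances; `fano_regression()` estimates the population Fano factor as the
slope of the variance-vs-mean scatter constrained through the origin,
$F = \sum m_i v_i / \sum m_i^2$ (zero-mean neurons stay in the table but
contribute nothing — the ratio is undefined at the origin). `mean_match()`
equalises the two conditions' mean-count histograms (bin width 1 count, the
bin-wise minimum as the common distribution, surplus points removed
uniformly at random, 50 draws averaged) so that rate changes cannot pose as
variability changes. Spike-train regularity is summarised by the ISI CV —
reported both per-train-averaged and pooled, since the two conventions
differ under rate mixtures — and by Holt's CV2 from consecutive interval
pairs. Rate trajectories are spike trains convolved with a unit-area 50 ms
Gaussian kernel.

## Surrogates: the mechanism in miniature

The statistics layer is tested against generators whose ground truth is
known (`poisson_train()`, `gamma_renewal_train()`,
`markov_switching_train()`). The Markov-modulated Poisson process is the
attractor-hopping caricature: a Poisson process whose rate switches between
two levels with transition rates $r_{up}, r_{down}$. Its count variance in a
window $T$ has the closed form

$$\mathrm{Var}\,N(T) = \bar\lambda T + \frac{2 \Delta^2 \pi_1 \pi_2}
{\theta^2}\left(\theta T - 1 + e^{-\theta T}\right),$$

($\theta = r_{up} + r_{down}$, $\pi_i$ the stationary state probabilities,
$\Delta$ the rate difference), so `mmpp_fano()` provides an analytic oracle:
slow switching at 100 ms windows gives Fano well above 1.4, fast switching
averages back to 1, and clamping the chain in one state ("stimulation", via
`freeze = "high"`) collapses Fano to 1. The closed form itself is validated
against long Monte-Carlo runs in the tests before being used as an oracle.
Each trial draws its initial state from the stationary distribution,
matching the across-trial stationarity the Fano analysis assumes.

## Operating point and calibration

Three quantities are not fixed by the model definition and were set once, as
follows, before being frozen into the package defaults:

* **Background-rate fluctuations** (`sigma_nu_khz`, `tau_nu_ms`). The low
  state's firing rates and the spontaneous rate distribution (mean near
  3 Hz with a zero-rate peak and a long right tail) pin the fluctuations to
  a small, slow modulation: per-population rate modulations are coherent
  across all 80 neurons of a pool, so even one percent of $\nu_0$
  measurably raises excursion frequency, while a few percent inflates the
  mean rate severalfold. The correlation time matters as much as the
  amplitude: with a fast modulation (tens of ms) excursions are rare,
  deep and multi-second — the network only leaves an activated state when
  finite-size noise happens to align — whereas a slow modulation
  (`tau_nu_ms = 100`, the default) both seeds and terminates excursions,
  giving frequent transient visits of a few hundred ms. The defaults
  (0.75% of $\nu_0$, 100 ms) keep the pooled smoothed-rate distribution of
  the selective populations at a mean near 3 Hz with a standard deviation
  of roughly 3.5-5 Hz at the operating point, and the excursion occupancy
  equilibrates within a couple of seconds, which is what makes short-trial
  Fano estimates reflect stationary activity.
* **Operating point** $(w_+, w_{inh})$. `choose_working_point()` scans the
  cohesion axis at intermediate inhibition ($w_{inh} = 1$, where the
  fluctuation-free low state reproduces the ~3 Hz / ~9 Hz rates) and
  returns the last grid cell (step 0.025) before the mean-field census
  leaves one stable state — just below the lower boundary of the
  multistability region. There the activated states are not yet stable but
  already partially attracting, so visits are frequent and transient. One
  or two cells earlier the excursions become too rare and shallow to
  reproduce the observed spontaneous rate spread; at or beyond the
  boundary the activated attractors become truly stable, visits turn into
  multi-second residencies, and both the mean spontaneous rate and the
  occupancy equilibration time grow sharply.
* **Stimulus and bias rates.** The stimulus is an extra 200 Hz of Poisson
  drive to one selective population; the attentional bias adds 50 Hz of the
  same kind of input (a baseline-shift/contrast mechanism, not a synaptic
  gain change). Both are swept in the protocol functions.

## What the synthetic generators do and do not emulate

The surrogates reproduce exactly the three statistical structures the
analysis relies on — Poisson counts, renewal regularity with tunable CV, and
slow discrete rate switching — with independent trials and stationary
initial conditions. They do not emulate refractoriness, rate covariations
across neurons, or the gradual attractor dynamics of the network (switches
are instantaneous); passing the statistics suite on surrogates therefore
validates the estimators, not the network model. Conversely, the network
tests validate the dynamics against the mean-field and against its own
surrogate-level caricature, not against experimental recordings.

## Problem sizes and numerical choices

Default analyses in the package documentation, tests and acceptance script
use desk-scale versions of the protocols: 200 trials per condition rather
than 1000-2000, a 100 s spontaneous run for the rate distribution, 7x7
bifurcation grids, and $10^4$ surrogate trials; all sizes are arguments.
Degenerate inputs are handled explicitly: empty spike sets count to zero
everywhere, an all-silent population makes the Fano regression fail with
"no active neurons" (scans record the failure and continue), non-overlapping
mean distributions make mean matching fail with "no overlap", and `sigma = 0`
in the transfer function returns the deterministic-drive rate rather than an
error. All randomness flows through explicit integer seeds: trial $i$ of an
ensemble uses `seed + i - 1`, so any single trial or scan cell can be
replayed bit-identically in isolation.

## Known limitations

* The mean-field reduction is quantitative only a few tens of percent from
  the simulator (it neglects recurrent-noise and finite-size effects); it is
  used to locate structure (fixed points, the bifurcation census), with
  simulation as the ground truth near the boundary.
* Deep inside the multistable region the activated attractors become truly
  stable and excursions turn into multi-second residencies; trial-based
  Fano estimates there depend on the burn-in through the slow occupancy
  equilibration. The shipped protocols operate at the census edge, where
  this dependence is mild.
* At the default operating point the spontaneous mean rate and the trial
  Fano factors sit comfortably in the excursion regime, but the spread of
  the smoothed-rate distribution is at the low end of that regime: within
  this parameterisation, configurations with markedly wider rate spread
  (deeper excursions) also carry a higher mean rate and multi-second
  attractor residencies — the two features trade off along every free
  parameter direction explored, and the default resolves the trade-off in
  favour of the low-state mean and transient excursion kinetics.
* Exchangeability of the five selective populations holds by construction;
  heterogeneous per-neuron parameters, sparse connectivity, conduction
  delays and synaptic plasticity are out of scope.
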