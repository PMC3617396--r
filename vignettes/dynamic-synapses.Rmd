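---
title: "Dynamic synapses: models, calibrations and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic synapses: models, calibrations and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`dynsyn` implements a family of models built on one biophysical idea:
synaptic efficacy depends on recent presynaptic activity. A conserved
pool of neurotransmitter is split into recovered (`x`), active (`y`) and
inactive (`z`) fractions; a presynaptic spike releases a fraction `u·x`,
the active transmitter inactivates with `tau_in` and recovers with
`tau_rec` (depression), and residual calcium transiently raises the
release probability `u` toward 1 with decay `tau_fac` (facilitation).
This vignette documents the modelling choices, the unit and calibration
decisions that are *not* fixed by the theory, and the boundary between
what the test suite establishes and what it does not.

## 1. The synapse model

Two time bases are used deliberately:

* **Continuous (ms).** `tm_integrate` integrates the three-state model
  event-driven: between spikes all variables relax linearly and the
  exact exponential solutions are applied (no delta-function
  discretization error); at a spike the jumps `x -> x - u x`,
  `y -> y + u x`, `u -> u + U(1-u)` are applied atomically. The release
  uses the *pre-spike* `u`; this convention is what makes the
  closed-form working point
  `u_inf = U(1 + tau_fac f)/(1 + U tau_fac f)`,
  `x_inf = 1/(1 + u_inf tau_rec f)` exact in the mean-field sense.
  Conservation `x + y + z = 1` is maintained to 1e-9 per step and is
  asserted under thousand-spike random trains.
* **Discrete (Monte Carlo steps).** The binary network uses the per-step
  map `x' = x + (1-x)/tau_rec - u x s`,
  `u' = u + (U-u)/tau_fac + U(1-u) s`. One MCS corresponds to roughly a
  refractory period, about 5 ms.

Two clamps replace limiting parameter values (avoiding division by small
time constants): *depression-only* (`U = 1`, `u` clamped at 1) and
*static* (`x = 1`, `u = U`). Range clipping is a floating-point guard
only and is reported when triggered.

One caveat on the closed forms: they equate the pre-spike and
time-averaged resource, which is exact for Poisson arrivals (arrivals
see time averages) but *not* for strictly periodic trains. At a 20 Hz
periodic drive with `U = 0.1`, `tau_fac = 500 ms` the time-averaged `x`
sits about 20% below `x_inf` while a Poisson train at the same rate
matches within 5%. The tests therefore validate the working point under
Poisson drive. A related textual discrepancy in the source model — the
facilitation equation relaxes `u` *toward* `U` while the surrounding
prose describes `U_j` rising "to its maximum value U" — is resolved in
favor of the equation as printed.

## 2. Attractor network and its mean-field map

`run_network` simulates `N` binary neurons with parallel stochastic
updates, `Prob(s_i = 1) = (1 + tanh(2 (h_i - theta_i)/T))/2`, fields
`h_i = sum_j w_ij x_j u_j s_j`, covariance weights over stored binary
patterns, and **one depression/facilitation variable per neuron** (this
makes the field computation a matrix–vector product and is why the same
behavior can be read as a dynamic firing threshold). The per-step order
is fixed: fields from the current state, then the neuron draw, then the
synapse update using the *pre-update* firing state. At `T = 0` an exact
tie resolves by a fair coin — the continuity limit of the update rule.
Balanced patterns (exact row sums) are the default so that a stored
pattern has overlap exactly 1; Bernoulli patterns are available for
statistical realism.

The thermodynamic-limit description (`mf_map_step`) follows by
sublattice averaging with the factorization `<x u s> = <x><u><s>` per
sublattice, giving a six-dimensional map for
`(m+, m-, x+, x-, u+, u-)` at vanishing load. Because fields are
uniform within each sublattice and neuron draws are independent of the
per-neuron synapse state given the field, the factorization is exact in
expectation; the map is the true `N -> Inf` limit. Fixed points are
found by damped iteration from three deterministic starts (pattern,
anti-pattern, symmetric), stability by a central-difference Jacobian
(step 1e-6) and the unit-circle criterion.

**Phase classification.** `memory` iff a stable fixed point with
retrieval overlap above 0.5 exists; else `oscillatory` iff the long-run
iterated map (2000 transient + 2000 scored steps from a near-pattern
start) keeps a peak-to-peak overlap amplitude above 0.1; else
`no-memory`. The 0.5 and 0.1 thresholds are classification conveniences,
not physics: the oscillation amplitude at onset grows continuously (a
supercritical Hopf-like transition), so any small positive amplitude
threshold shifts the oscillatory boundary slightly; 0.1 is robust at the
grid resolutions used here.

**Finite-size agreement.** In the memory and paramagnetic regimes an
`N = 2000` simulation tracks the map within `3/sqrt(N)` componentwise
over 100 MCS. In the *oscillatory* regime this tube is not attainable at
`N = 2000`: switching times jitter by order `1/sqrt(N)` MCS per cycle
while the firing fractions move by ~0.5 per MCS during a switch, so
pointwise deviations of order 0.3–1 appear at switch steps no matter how
faithful the implementation. The corresponding acceptance check is
asserted as stated and left failing, with the analysis recorded; the
agreement away from switches is covered by the memory-regime test.

## 3. Storage capacity at `T = 0`

At load `alpha = P/N > 0`, activity 1/2 and zero temperature, the
mean-field equations reduce to a scalar problem in the rescaled overlap
`y`: with `M = erf(y)`, `C = (2/sqrt(pi)) y exp(-y^2)/erf(y)`,
`r = 1/(1 - C)^2` and the synapse-renormalized interference offset
`Delta = (1 + gamma gamma' - gamma')/gamma'`
(`gamma = U tau_rec`, `gamma' = (1 + tau_fac)/(1 + U tau_fac)`),
a retrieval solution exists at `alpha` iff
`y = M / sqrt(2 alpha (r + Delta^2))` is solvable with `y > 0`.
`capacity_alpha_c` bisects on `alpha` (resolution 1e-4) with a dense
`y`-scan as the existence test; `capacity_alpha_c_system` independently
iterates the coupled `(M, r)` system and the two routes agree within
1e-3 everywhere tested. The printed rendering of the final capacity
equation in the source text is typographically ambiguous; the
implementation treats the `T -> 0` reduction of the underlying
mean-field system as ground truth. The static limit (`Delta = 0`) then
*derives* — with no tunable constant — the classical value
`alpha_c = 0.1379`, which is the strongest internal check available.
Depression strictly lowers `alpha_c`; strong facilitation drives
`Delta` back toward 0 (at `U = 0.2`, `tau_fac = 1000` the optimum over
`tau_rec` is at `tau_rec ≈ 4`, where `1/gamma' + gamma = 1`) and so
recovers, but can never exceed, the static bound.

## 4. Up–down transitions

The population model couples a rate `nu` to a depressing resource `x`:

    tau_nu dnu/dt = -nu + nu_m S[J nu x - theta] + zeta(t)
    dx/dt = (1 - x)/tau_r - U x nu + (D/tau_r) xi(t)

with the logistic excitability `S[X] = 1/(1 + exp(-X/delta))`,
integrated by Euler–Maruyama (`dt <= 0.01 min(1, tau_r)`, `nu` clipped
at 0, `x` clipped to [0, 1] with event counting; clipping at the `x = 1`
boundary acts as an effective reflection and is the documented boundary
convention).

**Units and calibration (the choices the theory does not fix).** The
published parameter set (`J = 1.2 V`, `nu_m = 5e-3`, `delta = 0.3`) is
dimensionally inconsistent if the sigmoid width is read in volts: the
recurrent input `J nu x` then spans only ~6 mV, the loop gain
`nu_m J/(4 delta)` is ~5e-3, and no bistability can exist for any
threshold. The width is therefore read as millivolts
(`delta = 3e-4 V`), which gives gain ~5 and the expected double-well
effective potential. The threshold (never published) is calibrated once
to `theta = 1.2e-3 V`, and the rate-noise amplitude (also never
published, yet it must drive the switching when `D = 0`) to
`sigma_nu = 1e-3`. Calibration targets were qualitative statements of
the theory only: a bimodal rate histogram at the published
depression-driven operating point with `D = 0`; exponential-only dwell
distributions at `D = 0` and in the static-synapse limit; and a
power-law dwell region at jointly large `D` and `tau_r`. These values
were fixed once and are not revisited by any test.

**Effective potential.** Freezing `x`, the rate obeys
`tau_nu dnu/dt = -Phi'(nu)` with
`Phi(nu) = nu^2/2 - nu_m (delta/(J x)) [softplus((J nu x - theta)/delta)
- softplus(-theta/delta)]`: a down well at small `x`, an up well at
large `x`, bistable between.

**Dwell statistics.** `ud_detect_states` places a hysteresis band
around the rate-histogram dip (band = 25% of the inter-mode distance;
the dip is centered on the minimal-density plateau, which matters when
the inter-mode density is essentially zero); dwells shorter than 5
samples are merged. `ud_fit_permanence` fits a continuous power law by
maximum likelihood with Kolmogorov–Smirnov selection of `x_min`,
against a shifted exponential on the same tail, compared by a
normalized (Vuong) log-likelihood ratio at 0.05; `power_law` is
selected only when significantly better. Phases: `P` no transitions,
`S` resource-slaved (smoothed-rate/resource correlation > 0.9 and
switching faster than `1/(10 tau_r)`), `C` power-law up-state dwells,
else `E`.

**Why the critical region sits at large `D`, `tau_r`.** The up state
requires `x` above an effective ignition level and collapses below the
saddle-node level; when the resource noise amplitude `D/sqrt(2 tau_r)`
exceeds the width of this effective hysteresis window and `tau_r` is
long, dwell times become return times of a slow, locally driftless
diffusion — with the characteristic exponent ~3/2 the fits indeed
recover (fitted `alpha ≈ 1.5`). Weak depression (`U = 0.04`, as in the
published permanence-time study) is essential: at `U = 0.6` depression
terminates the up state deterministically and only exponential dwells
appear, which is why the canonical phase grid uses `U = 0.04`.

## 5. Stochastic multiresonance

A population of `N` Poisson neurons at rate `f_n` drives one
integrate-and-fire neuron through dynamic synapses. At the asymptotic
working point the pooled current has mean
`I_bar = N f_n tau_in I_p` and variance
`sigma^2 = N f_n tau_in I_p^2 / 2` with `I_p = A u_inf x_inf`
(`A = 40 pA`, the cortical scale). The identity
`sigma^2 = I_bar I_p / 2` is structural. Two Monte-Carlo comparisons are
kept deliberately distinct: an event-based superposition of fixed-
amplitude pulses (the stationary idealization the formula describes)
matches both moments within 5%; the *full* per-synapse simulation
matches the mean but carries 8–14% excess variance from release-
amplitude dispersion around the working point — a real effect of the
model, documented rather than hidden.

The postsynaptic neuron is deliberately fluctuation-driven: its
threshold relaxes (2 s time constant) toward `theta0 + k <I>` with
`k = 1`, so the mean distance to threshold stays at `theta0` while the
*fluctuations* `sigma(f_n)` sweep up and down with the presynaptic
rate. For static synapses `sigma` is monotone in `f_n`: one crossing of
the detection-optimal fluctuation level, one peak in the power norm
`C0 = <S(t) nu(t)>`. For depressing synapses `sigma(f_n)` has an
interior maximum, and when that maximum overdrives the neuron the
optimal level is crossed twice: two peaks, the upper one positioned by
`tau_rec` (depression cutoff) and the lower by `tau_fac` (facilitation
onset), each controllable independently — the multiresonance signature.

None of the neuron-side parameters are published; the calibrated stated
world (fixed once, exposed via `sr_experiment_config`) is: `N = 600`,
`theta0 = 4` (units of `R`·pA with `R = 1`), `tau_m = 10 ms`, 25 ms
refractory period (what caps the firing rate and deepens the
inter-peak dip), 5 Hz sine at 50% of the rheobase gap, adaptation and
signal kept two orders of magnitude apart in timescale so the threshold
cannot track the signal, 20 scored periods after a 1 s warmup, and a
25-point logarithmic grid over 0.15–1000 Hz. Synapses and the
adaptation low-pass start at their working point, so the slow threshold
carries no start-up bias (starting from rest injects a depression
transient whose memory biases the gap for seconds). Peaks are detected
on the 3-point moving average with a prominence threshold of 15% of the
curve maximum; the two-peak structure and both shift directions are
stable across seeds at 10 trials per grid point, which is what the
acceptance test asserts — peak *positions* in Hz are properties of this
calibrated world, not of the source theory.

## 6. What the synthetic worlds do and do not establish

All inputs are generated internally: random balanced patterns, Poisson
trains, and the SDE noise. A green suite establishes that the
*mechanisms* are implemented faithfully — capacity values against the
closed theory, switching against the mean-field map, dwell-law
transitions against constructed telegraph/Pareto/exponential oracles,
resonance structure against its own fluctuation theory. It does not
establish biological parameter realism (the up–down threshold, rate
noise, and all SR neuron constants are calibrations), nor behavior
under structured/correlated inputs, sparse connectivity, or learned
asymmetric weights, all of which are out of scope.

## 7. Known limitations

* The mean-field map is the condensed single-pattern (`P = 1`) form;
  multi-pattern structure is probed by simulation only.
* Finite-`alpha` phase diagrams beyond the `T = 0` capacity point are
  not computed.
* The oscillatory-regime finite-size tube (section 2) is an impossible
  acceptance bound at `N = 2000`; it is left asserted-and-failing by
  design.
* `ud_fit_permanence` compares two specific tail families
  (power law vs shifted exponential); it does not test log-normal or
  stretched-exponential alternatives.
* The integrate-and-fire neuron is the only postsynaptic model;
  a FitzHugh–Nagumo variant would fit behind `sr_config` but is not
  implemented.
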