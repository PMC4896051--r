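---
title: "Methods: models, scoring and design choices in ephysopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, scoring and design choices in ephysopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephysopt)
```

# What problem this package solves

Detailed neuronal models — conductance-based point neurons, morphologically
detailed cells, synaptic plasticity models — have parameters that cannot be
measured directly. What *can* be measured are summary features of the
system's behaviour: how many action potentials a current step elicits, the
inter-spike-interval statistics, the amount of potentiation a pairing
protocol induces. `ephysopt` implements the feature-based multi-objective
strategy for this inverse problem: each experimental feature with mean
$\mu_{exp}$ and standard deviation $\sigma_{exp}$ defines one objective

$$ \mathrm{score} = \frac{|\mu_{exp} - f_{model}|}{\sigma_{exp}}, $$

so all objectives share one scale (standard deviations away from the data)
regardless of units, and an indicator-based evolutionary algorithm (IBEA)
searches the bounded parameter box for genomes that drive every score
towards zero.

# The optimiser

## Fitness assignment

IBEA ranks individuals by the pairwise additive epsilon indicator rather
than by Pareto rank. For minimization, on objectives normalized per
dimension to $[0,1]$ over the pooled population,

$$ I(a, b) = \max_i \left( a_i - b_i \right) $$

is the smallest shift that makes $a$ weakly dominate $b$, and each
individual $x$ receives

$$ F(x) = \sum_{y \neq x} -e^{-I(y, x) / (c\,\kappa)}, $$

where $c$ is the maximum absolute indicator over all ordered pairs
(the adaptive rescaling that makes the algorithm invariant to objective
magnitudes) and $\kappa = 0.05$ by default. Environmental selection
removes the worst individual and adds the removed term
$e^{-I(\mathrm{removed}, y)/(c\kappa)}$ back to each survivor, with
normalization and $c$ fixed on the full merged population. Both routines
are checked against brute-force recompute-from-scratch oracles in the test
suite, exactly (1e-12) on hundreds of random instances.

## Variation, selection and population model

These pieces are not constrained by the scientific content of the method,
so the package declares standard choices for bounded real-coded
evolutionary search and documents them as such:

* population model $\mu = \lambda$ = `offspring_size`; each generation the
  offspring are merged with the parents and environmental selection keeps
  $\mu$;
* mating selection: binary tournament on IBEA fitness, ties broken by
  smaller objective sum, then randomly;
* variation: simulated-binary crossover (probability 0.7) followed by
  bounded polynomial mutation (per-gene probability `1/genome_length`),
  both with distribution index $\eta = 10$. Offspring are clipped into the
  bounds, and bounds are re-checked at evaluation entry, so no
  out-of-bounds genome is ever evaluated;
* failed evaluations receive the penalty value (default 250) in **every**
  objective, keeping the population size fixed while making such genomes
  uncompetitive.

The hall of fame archives the best distinct genomes ranked by the *sum* of
objectives (other reducers — max, weighted sum — are available as
objective specifications). The logbook's `min` column tracks the
hall-of-fame best, so it is non-increasing by construction; `mean` and
`max` describe the current population. Checkpoints store the population,
hall of fame, logbook, genealogy and the RNG state *after* the
checkpointed generation, so a resumed run is bit-identical to an
uninterrupted one under the serial map.

# The built-in point neuron

Desk-scale use cases need no external simulator: the package integrates
the classic squid-axon Hodgkin–Huxley system in a single isopotential
compartment,

$$ C_m \dot v = -\bar g_{Na} m^3 h (v - E_{Na}) - \bar g_K n^4 (v - E_K)
   - g_l (v - E_l) + I_{inj}/A, $$

with the canonical rate functions voltage-shifted so rest sits near
−65 mV, $E_{Na} = 50$, $E_K = -77$, $E_l = -54.3$ mV,
$g_l = 3\times10^{-4}$ S cm⁻², $C_m = 1$ µF cm⁻², default temperature
6.3 °C with a $Q_{10} = 3$ kinetic scale — the defaults of the `hh`
mechanism that common simulators provide. Units follow the usual
electrophysiology conventions (mV, ms, nA, S cm⁻², µF cm⁻²); since
S cm⁻² × mV = mA cm⁻² and (mA cm⁻²)/(µF cm⁻²) = V/s, the membrane
equation carries an explicit factor 1000 to express $\dot v$ in mV/ms.

Numerical choices:

* fixed-step classical Runge–Kutta (RK4), default $dt = 0.025$ ms, gating
  initialized at steady state for `v_init`;
* the injected square pulse is piecewise constant, so the current is
  evaluated at the step midpoint and held for all four stages; with pulse
  edges on step boundaries each constant piece is integrated exactly and
  the method keeps its fourth-order self-convergence (verified in the
  tests: halving $dt$ moves samples by ~0.005 mV on spiking sweeps);
* non-finite states abort with a diagnostic rather than propagate.

The default membrane geometry is the packaged one-point SWC soma stub
(radius 5 µm, sphere area $4\pi r^2$ = the area of a 10 µm × 10 µm
cylinder, $\pi \cdot 10 \cdot 10$ µm²). The stub parser deliberately
rejects anything but a single soma sample: there is no cable model to put
a real morphology on. A distance-dependent parameter scaler
(`scaler_expression`) parses arithmetic templates such as the exponential
conductance gradient used for dendritic h-channels; validation happens at
parse time and evaluation is pure arithmetic.

On this model, the two-conductance demo problem (`hh_demo_evaluator()`)
— $\bar g_{Na} \in [0.05, 0.125]$, $\bar g_K \in [0.01, 0.075]$ S cm⁻²,
steps of 0.01 and 0.05 nA for 50 ms, Spikecount targets 1 and 5 with
$\sigma = 0.05\,\mu$ — was verified feasible before freezing the
defaults: a contiguous ~5 % region of the bounds box yields exactly
(1, 5) spikes, and the optimiser reaches objective sum 0 within 10
generations of 100 offspring for every seed tried.

# Feature extraction

A spike is an upward crossing of the detection threshold (default −20 mV,
a robust level for HH-type action potentials) followed by the local
maximum before the next downward crossing. All spike features consider
only peaks inside the stimulus window; the voltage base is the mean
potential before stimulus onset. Twelve features are supported
(`efeature_names()`); their exact definitions are documented in
`?compute_feature`. Conventions the field leaves loose were fixed as
follows: `AP_width` is measured at the detection-threshold level;
`AHP_depth_abs_slow` searches $[{\rm peak}+5\,{\rm ms}, {\rm next~onset}]$;
`adaptation_index2` averages $({\rm ISI}_{i+1}-{\rm ISI}_i)/({\rm ISI}_{i+1}+{\rm ISI}_i)$
from the second ISI on. Numeric parity with any external feature library
is explicitly not claimed; these are this package's normative definitions,
and features whose prerequisites fail return missing, which the scoring
layer converts to the penalty.

# The calcium-based plasticity model

The second scientific core is the bistable-synapse plasticity model. The
synaptic efficacy $\rho$ evolves in a double well,

$$ \tau \dot\rho = -\rho(1-\rho)(\rho_\star-\rho)
   + \gamma_p (1-\rho)\,\Theta[c(t)-\theta_p]
   - \gamma_d\, \rho\,\Theta[c(t)-\theta_d] + \mathrm{Noise}(t), $$

driven by postsynaptic calcium $c(t)$, which jumps by $C_{pre}$ a delay
$D$ after each presynaptic spike and by $C_{post}$ at each postsynaptic
spike, and decays with $\tau_{Ca}$. The noise is activity dependent; the
package uses the standard form for this model family,
$\sigma\sqrt{\tau}\sqrt{\Theta[c-\theta_p]+\Theta[c-\theta_d]}\;\eta(t)$
with $\eta$ unit white noise, i.e. noise acts only while calcium sits
above at least one threshold. The constants not being fitted are fixed
configuration: $\theta_d = 1$, $\theta_p = 1.3$, $\rho_\star = 0.5$ and
initial up-state fraction $\beta = 0.5$.

## Analytic protocol outcomes

For periodic pairing protocols the outcome is computed without
simulation. Calcium between events is a pure exponential, so the time
above each threshold is exact in closed form
(`time_above_threshold()`). With $\alpha_p, \alpha_d$ the fractions of
protocol time above the thresholds, averaging the efficacy equation (and
dropping the cubic term, which is slow compared to the driven linear
terms) leaves an Ornstein–Uhlenbeck process with

$$ \bar\rho = \frac{\Gamma_p}{\Gamma_p+\Gamma_d}, \qquad
   \tau_{e\!f\!f} = \frac{\tau}{\Gamma_p+\Gamma_d}, \qquad
   \sigma_\rho^2 = \frac{\sigma^2(\alpha_p+\alpha_d)}{2(\Gamma_p+\Gamma_d)}, $$

where $\Gamma_x = \gamma_x \alpha_x$. The variance constant was **not**
taken on faith: the test suite integrates the averaged linear SDE with
Euler–Maruyama ($5\times10^4$ paths) and requires the analytic mean and
variance to match within three standard errors before anything else is
built on them. The efficacy at the end of a protocol of duration $T$ is
then Gaussian given its start, yielding the up/down transition
probabilities $U$ and $D$ as normal tail probabilities, and the synaptic
gain

$$ \mathrm{gain} = \frac{a\,b + (1-a)}{\beta\,b + (1-\beta)}, \qquad
   a = \beta(1-D) + (1-\beta)U, $$

with $b$ the up/down weight ratio. Repetitions are treated as independent
(calcium restarts from zero each repetition); the code warns when
`rep_freq * tau_ca >= 0.01`, where that approximation degrades.

## The stochastic oracle

`simulate_gb()` integrates the *full* double-well equation (nothing
averaged, nothing dropped) with Euler–Maruyama at $dt = \tau_{Ca}/100$
while calcium is at or above $\theta_d$, switching to a coarse
deterministic step ($\tau/500$) during silent stretches where only the
cubic drift acts — calcium itself is propagated analytically between grid
points, so the two-speed scheme changes no physics. The analytic layer is
validated against it: transition probabilities within 0.05 absolute, and
end-to-end gains within three Monte-Carlo standard errors, on a
strong-drive fixture chosen so both basins mix ($U \approx 0.39$,
$D \approx 0.50$) while $\tau$ sits at its upper bound so the neglected
cubic term is genuinely negligible (measured bias ≈ 0.0014 in gain at
$5\times10^4$ paths).

# The synthetic plasticity dataset

The in-vitro dataset the original fitting work used is available only as
digitized figure values, which are not printed anywhere reproducible, so
the package ships a clearly labelled *synthetic* stand-in
(`inst/extdata/synthetic_stdp_dataset.tsv`) plus its generator
(`make_stdp_dataset()`). The stated world it emulates:

* protocol family: one presynaptic spike paired with a burst of 3
  postsynaptic spikes at 50 Hz, repeated 60 times at 0.1 Hz — the
  structure of the in-vitro experiments; these values are fixture
  metadata stored in the dataset file, never hard-coded in the model;
* eight offsets $\Delta t \in \{-100, -75, -50, -25, -10, +10, +25, +50\}$
  ms, positive meaning pre-before-post;
* measurement noise: additive Gaussian with sd 0.05 on the synaptic gain,
  written to the `stderr` column (a noise-free table gets unit `stderr`
  so it stays a valid dataset);
* ground truth: the `gb_params()` defaults. Because the fitted parameter
  values behind the published curve are not printed, these were
  calibrated **once**, before any recovery experiment, by least-squares
  matching of the analytic gain curve to a qualitative template of the
  published in-vitro result — depression troughing near
  $\Delta t = -50$ ms (gain ≈ 0.71), potentiation peaking near $+10$ ms
  (gain ≈ 1.32), little change at the far edges — under the fitting
  bounds. They were not revisited afterwards.

What a green recovery test establishes: that the optimiser can drive the
model's predicted gains to within $2\times$ the measurement error of the
noise-free truth from noisy data, and that the recovered curve keeps the
LTD/LTP shape. It does *not* establish parameter identifiability (the
problem is famously degenerate — many parameter sets produce
near-identical curves), nor fidelity to the actual biological values; no
claim is made about either. Likewise the synthetic dataset has perfectly
known protocol structure and i.i.d. Gaussian noise, unlike real summary
tables with heterogeneous n and standard errors.

# Degenerate inputs and tie-breaks

* Objective dimensions with zero range normalize to 0 (they carry no
  selective information that generation).
* If all individuals are identical, the indicator scale $c$ is zero; it
  is replaced by 1, giving equal fitness everywhere.
* Environmental-selection ties on fitness remove the smallest row index;
  tournament ties fall back to objective sum, then to the RNG — all
  reproducible under a fixed seed.
* `time_above_threshold` treats exact threshold touches ($c = \theta$) as
  not above, consistent with the strict inequality in the closed form.
* Spike detection requires an upward crossing: a trace that starts above
  threshold contributes its first peak only after first dipping below.

# Known limitations

* Single compartment only; no cable model, no morphologically detailed
  channel distributions (the distance scaler is provided for
  configuration schemas, not used by the built-in simulator), and no
  bindings to external simulators — only the evaluator contract they
  would implement.
* The analytic plasticity layer inherits the averaging assumptions:
  repetitions independent, cubic term negligible during stimulation,
  Gaussian endpoint distribution. Its accuracy is quantified against the
  stochastic oracle only in the regimes the tests cover.
* The feature set is the desk-scale dozen, per-recording only; no
  multi-trace features.
* Parallel evaluation is supported only through a user-supplied
  order-preserving map function; determinism guarantees apply to the
  serial map.
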