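# ephysopt

Feature-based multi-objective evolutionary optimisation of neuronal
models in R.

Most parameters of biophysical neuron and synapse models cannot be
measured directly, but experiments constrain the model's *behaviour*:
spike counts under current steps, inter-spike-interval statistics, the
amount of synaptic potentiation a pairing protocol induces. `ephysopt`
turns each such constraint, given as an experimental mean μ and standard
deviation σ, into one objective

```
score = |mu - f_model| / sigma
```

(0 = perfect match, k = k experimental standard deviations away) and
searches the bounded parameter space with an indicator-based evolutionary
algorithm (IBEA, additive-epsilon variant): individuals are ranked by the
pairwise epsilon indicator on min–max-normalized objectives, bred with
simulated-binary crossover and bounded polynomial mutation, and archived
in a hall of fame sorted by the sum of the objectives.

The package is self-contained for desk-scale work:

* **optimiser** — adaptive IBEA with hall of fame, logbook, genealogy and
  bit-reproducible checkpoint/restore (`run_optimisation()`,
  `optimisation_config()`).
* **evaluation** — the evaluator/objective abstraction connecting
  parameters, protocols, responses and scores (`evaluator()`,
  `cell_evaluator()`, JSON config round trip).
* **point_neuron** — a built-in single-compartment Hodgkin–Huxley
  simulator (classic squid-axon kinetics shifted to rest ≈ −65 mV, RK4,
  default dt 0.025 ms) with square-pulse protocols, a one-point SWC soma
  stub reader and a distance-dependent parameter scaler.
* **efeatures** — spike detection and twelve voltage-trace features
  (Spikecount, AP height/width, ISI CV, AHP depths, ...) plus the
  |μ−f|/σ scoring layer.
* **stdp_gb** — the calcium-based bistable-synapse plasticity model:
  exact event-superposition calcium, closed-form time-above-threshold,
  analytic up/down transition probabilities and synaptic gain for
  periodic pre/post pairing protocols, a full stochastic-simulation
  oracle (`simulate_gb()`), and a fitting evaluator (`gb_evaluator()`).
* **toolkit** — synthetic fixtures (`make_spike_fixture()`,
  `make_stdp_dataset()`), config/dataset I/O and a CLI.

## Worked example: the two-conductance demo

Fit the sodium and potassium maximal conductances of a single-compartment
HH cell so that a 0.01 nA / 50 ms step elicits exactly 1 action potential
and a 0.05 nA step exactly 5 (targets with σ = 0.05·mean):

```r
library(ephysopt)

ev  <- hh_demo_evaluator()   # bounds: gnabar [0.05,0.125], gkbar [0.01,0.075] S/cm2
cfg <- optimisation_config(offspring_size = 100, max_ngen = 10, seed = 1)
res <- run_optimisation(ev, cfg)
res
#> <optimisation_result> hh_demo
#>   generations: 10   evaluations: 1100
#>   best objective sum: 0
head(res$hall_of_fame, 3)
#>   rank objective_sum step1.Spikecount step2.Spikecount  gnabar   gkbar
#> 1    1             0                0                0 0.09296 0.02757
#> 2    2             0                0                0 0.07868 0.02349
#> 3    3             0                0                0 0.09148 0.02678
```

A best objective sum of 0 means both spike-count targets are matched
exactly; the solution is not unique (several distinct conductance pairs
reach a perfect score). Re-simulating the best genome confirms the
behaviour:

```r
g  <- best_genome(res)
m  <- point_cell_model(gnabar = g[["gnabar"]], gkbar = g[["gkbar"]])
tr <- run_sweep(m, square_pulse(0.05, delay = 100, duration = 50,
                                total_duration = 200))
compute_feature(tr, "Spikecount")
#> [1] 5
```

## Plasticity fitting

The spike-timing-dependent plasticity workflow fits the nine parameters
of the calcium-based bistable synapse model to a summary table (one row
per pairing protocol: Δt, measured synaptic gain, stderr), using the
analytic protocol outcome — no stochastic simulation in the fitting
loop. With the packaged synthetic dataset (ground truth =
`gb_params()` defaults):

```r
p <- gb_params()
gain_curve(p, delta_t_ms = c(-50, 10))
#>   delta_t_ms      gain
#> 1        -50 0.7127585   # LTD: burst 50 ms before the presynaptic spike
#> 2         10 1.3205588   # LTP: burst 10 ms after
```

`gb_evaluator()` plugs the model into the same optimiser
(`err_i = |sg_i - gain_i| / stderr_i`, one objective per protocol).

## Command line

```sh
Rscript inst/cli/ephysopt hh-demo  --seed 1 --out results/demo
Rscript inst/cli/ephysopt stdp-fit --dataset inst/extdata/synthetic_stdp_dataset.tsv \
        --seed 1 --out results/stdp
Rscript inst/cli/ephysopt features --trace results/demo/step1.soma.v.tsv --out results/feat
```

Each run writes `hall_of_fame.csv`, `logbook.jsonl` and a
reproducibility manifest (seed, config hash, versions); identical seeds
give byte-identical outputs.

## Further reading

The methods vignette (`vignettes/ephysopt-methods.Rmd`) documents the
models and their assumptions, the numerical choices (integrator,
tolerances, tie-breaks), what the synthetic-data generators emulate, and
the validation of the analytic plasticity layer against its stochastic
oracle.
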