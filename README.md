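# gpcpower

Generalized pairwise comparisons (GPC) of multi-domain outcomes, with
thresholds of clinical relevance, permutation inference, and a power
simulator for small rare-disease trials.

## What problem this solves, and for whom

Trials in heterogeneous rare diseases — the motivating setting is
mucopolysaccharidosis type IIIA (Sanfilippo A), where treatment is hoped
to slow decline across expressive language, daily living skills,
gross-motor function, sleep and pain at once — cannot summarize benefit
in a single instrument. GPC compares **every treated subject against
every control subject** on all domains simultaneously. Each pair is
scored per domain as a win (+1), loss (−1) or neutral (0): a win requires
the difference, taken in the direction of benefit *d_k*, to strictly
exceed a threshold of clinical relevance *τ_k*. Pairs are aggregated
either **hierarchically** (outcomes ranked by priority; lower priorities
break ties) or as an **equal-weight average** across domains. The
treatment-effect measure is the net benefit

    Δ = (wins − losses) / n_pairs ∈ [−1, 1],

the net probability that a random treated subject does better than a
random control subject. P-values come from the permutation distribution
of Δ under arm-label reshuffling (two-sided, add-one corrected).

Because the endpoint is each subject's **rate of change**
`(score at month 24 − score at month 0) / 2 years`, the package ships a
five-domain longitudinal simulator with correlated random intercepts and
slopes, calibrated to published natural-history summaries (baseline
medians 63, 30.5, 58, 4, 75; control rates 1.31, 0.10, 0.28, −0.01,
−0.21/year; treated rates 3.53, 0.42, 0.94, −0.47, 0.50/year; sleep
improves downward), plus replicated power studies over threshold grids,
aggregation modes and priority orderings. The target audience is trial
statisticians designing multi-domain endpoints for small cohorts.

## Worked example

Simulate a 23-per-arm trial, derive rates of change, and run a
prioritized GPC with thresholds at half a rate-SD per domain:

```r
library(gpcpower)
gen   <- generator_config()                       # documented defaults
trial <- generate_trial(gen, n_per_arm = 23, seed = 42)
rates <- derive_rates(trial)
specs <- specs_from_config(gen, threshold_fraction = 0.5)
permutation_test(rates, specs, "prioritized", B = 1000, seed = 42)
```

Output:

```
GPC permutation test: delta = 0.5614, p = 0.002997 (B = 1000)
```

and the underlying decomposition (`print(test$net_benefit)`):

```
GPC net benefit (prioritized): delta = 0.5614
  pairs: 529  (wins 413.000, losses 116.000, neutral 0.000)
  pairs decided per priority level:
expressive_language daily_living_skills         gross_motor               sleep
                445                  60                  20                   4
               pain         all_neutral
                  0                   0
```

Reading this: of the 529 treated-control pairs, 413 favour treatment and
116 favour control net of the threshold, so a randomly chosen treated
subject is 56 percentage points more likely to fare better than a random
control; 445 pairs were decided by expressive language alone, and the
remaining 84 cascaded to lower priorities after a language-neutral
comparison. The permutation p-value (B = 1000 relabellings) is 0.003.

Power studies:

```r
sce <- scenario_config(n_per_arm = 23, n_replicates = 500)  # desk scale
run_scenario(sce, gen)               # prioritized vs equal-weight curves
run_marginal_power(sce, gen)         # one curve per single domain
run_ordering_sensitivity(sce, gen)   # alternative priority orderings
```

A command-line interface wrapping the same functions lives in
`inst/cli/gpcpower` (subcommands `simulate`, `gpc`, `power`, `report`).

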