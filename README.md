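# retinakit

Quantitative analysis of retinal neuroprotection experiments in rodent
models of retinitis pigmentosa (RP). In RP, rod photoreceptors die from the
mutation and cone photoreceptors die secondarily; a candidate treatment is
judged by whether it (i) slows the kinetics of cone loss and (ii) preserves
cone-driven retinal light responses. `retinakit` implements the three
statistical machines this requires, plus seeded synthetic-data generators
so every stage is testable without laboratory data.

## What it computes

**MEA light responses.** Multi-electrode-array voltage traces are band-pass
filtered (Butterworth, 400–5000 Hz, 2nd order), spikes detected as
crossings of 5× the filtered signal's SD with a 1.5 ms refractory pause,
and counted in 350 ms windows: light-ON, light-OFF, and spontaneous
(immediately before flash onset). An electrode is *light-activated* at an
intensity when a two-tailed paired t test of ON vs spontaneous counts gives
p < 0.01 with t > 2, and enters the analysis only if activated at ≥ 3 of
the 5 photopic intensities. Response strength is the Michelson-style index

    response ratio = (rate_ON − rate_spont) / (rate_ON + rate_spont)  ∈ [−1, 1]

compared between conditions with a Wilcoxon rank-sum test per intensity.

**Cone-survival kinetics.** Cone densities (cones per 100 µm ONL, spider
positions ±10°/±80°) are averaged per arm and age, and cone loss is fitted
as exponential decay — linear on a log2 axis:

    density(t) = 2^(a − b·t),   x-intercept = (a − log2 θ) / b

with θ = 1 cone/100 µm the extinction threshold. The difference of the two
arms' x-intercepts is the treatment's survival delay in days. Per-animal
log2 survival ratios (treated/contralateral control eye) feed a
shared-control estimation analysis: Hedges' g against the earliest
post-treatment age with a 5000-resample BCa bootstrap CI and an unpaired
two-sided permutation t test.

**Expression statistics.** Counts-per-million normalization; the standard
filter (> 1 CPM in ≥ 2 samples of at least one group); a two-tailed
permutation-FDR Student's t test on log2 expression (FDR < 0.05, 250
randomizations, SAM/Perseus-style null-exceedance calibration); ΔΔCT qPCR
fold changes (2^(−ΔΔCT), GAPDH-style housekeeping reference) with a
Mann–Whitney test on per-sample folds.

## Worked example

Simulate a control-like (ON 33.5 /s) and a treated-like (ON 50 /s)
condition over a shared 5 /s spontaneous rate, classify electrodes, and
compare response ratios:

```r
library(retinakit)
pr   <- make_protocol()   # 6 intensities x 20 reps, 350 ms flashes, 2 s dark
ctrl <- simulate_trial_counts(pr, rate_model(5, 33.5), 40, seed = 1)
trt  <- simulate_trial_counts(pr, rate_model(5, 50),  40, seed = 2)
rr <- lapply(list(control = ctrl, treated = trt), function(tc) {
  sel <- select_channels(test_activation(tc), pr)
  response_ratio(tc, sel)
})
compare_groups(rr$control, rr$treated)
#>   intensity statistic  p_value n_control n_treated median_control median_treated
#> 2   5.3e+13        35 1.89e-13        40        40          0.741          0.828
#> 5   1.6e+15        49 5.13e-13        40        40          0.742          0.829
#> ...
```

The treated medians sit near (50−5)/(50+5) = 0.82 and the control medians
near (33.5−5)/(33.5+5) = 0.74; the rank-sum p values show the groups
separate clearly at every intensity.

Fit survival kinetics for two arms with a shared decay slope:

```r
ages <- c(26, 30, 37, 45, 60, 90)
recs <- simulate_survival(list(
  decay_model(5.541, 0.05832, noise_cv = 0.1, arm = "control"),
  decay_model(4.606, 0.05832, noise_cv = 0.1, arm = "treated")),
  ages, n_eyes = 6, seed = 1)
s <- aggregate_survival(recs)
fit_decay(s, "control")
#> Decay fit [control]: density = 2^(5.603 - 0.05937 * day), R2 = 1.000
#> x-intercept (density = 1): PN94.37
fit_decay(s, "treated")
#> x-intercept (density = 1): PN79.05
```

The fitted extinction days land on the generator's closed-form values
(5.541/0.05832 = 95.0 and 4.606/0.05832 = 79.0), about 15–16 days apart.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package: the median response
ratios of the treated-like and control-like simulations through the full
classify-then-ratio pipeline (256 electrodes), and the two survival
x-intercepts plus their day-difference from noisy two-arm simulations, and
writes them as JSON keyed `t1`–`t5`.
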