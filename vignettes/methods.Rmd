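---
title: "Models and methods behind retinakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retinakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinakit)
```

This vignette is the package's own account of the models it implements,
the assumptions behind them, and the design choices made where the
underlying analysis conventions leave room. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The MEA light-response pipeline

### Signal model

A retinal explant on a multi-electrode array yields, per electrode, an
extracellular voltage trace sampled at 25 kHz in which retinal ganglion
cell spikes (~1 ms biphasic deflections) ride on broadband noise. The
pipeline assumes electrode-level analysis: units are *not* sorted, so
"firing rate" means the pooled spike rate seen by one electrode.

**Filtering.** The band of interest is 400–5000 Hz. "2nd-order Butterworth
band-pass" is implemented as a cascade of a 2nd-order high-pass at 400 Hz
and a 2nd-order low-pass at 5000 Hz (bilinear transform with prewarping,
second-order sections). The cascade convention is chosen because the stop
band then follows the textbook single-edge magnitude, e.g. gain
$1/\sqrt{1+(400/50)^4} \approx 0.0156$ at 50 Hz — a value the test suite
verifies empirically; a single order-2 band-pass prototype would instead
give $\approx 0.0133$ there. The default direction is zero-phase
(forward–backward), which preserves spike timing at the cost of doubling
the effective order; a single-pass variant is available and is the one the
closed-form gain applies to.

**Detection.** Threshold $k\sigma$ with $k = 5$, where $\sigma$ is by
default the plain SD of the whole filtered channel (the literal reading of
"standard deviation of the filtered signal"); a MAD-based robust variant
(`sd_scope = "robust"`) resists inflation of $\sigma$ by the spikes
themselves on high-rate channels. Default polarity is `absolute` (either
sign), since extracellular spike polarity depends on cell–electrode
geometry; negative-only is selectable. After each event, crossings within
the 1.5 ms refractory pause are suppressed. A zero-variance channel has no
definable threshold and is flagged rather than silently emitting spikes.

**Windowing.** Counts are taken in half-open 350 ms windows: ON
`[onset, onset+0.35)`, OFF `[onset+0.35, onset+0.7)`, spontaneous
`[onset−0.35, onset)`. The spontaneous window's duration and placement are
a design choice (only "before light onset" is conventional): making it the
same length as the ON window immediately precedes each flash and keeps
counts comparable without rate scaling. The 2 s dark gap guarantees the
spontaneous window never overlaps the previous OFF window; violations are
a hard error naming the offending epochs.

**Activation.** Per (electrode, intensity), a two-tailed paired Student's
t on the per-repetition ON − spontaneous differences (df = reps − 1);
activated iff $p < 0.01$ *and* $t > 2$ on the signed statistic, so
suppression never counts as ON activation. If all differences are
identical (zero variance), t is reported as signed infinity — a perfectly
consistent increase is the strongest possible response — and activation
reduces to "mean difference > 0"; all-zero differences give t = 0. An
electrode is included only when ON-activated at ≥ 3 of the 5 photopic
intensities (the top five; the dimmest default intensity, 8.6e12
photons/cm²·s, is scotopic). With fewer than 5 photopic intensities the
threshold rescales to `ceiling(3/5 · n)` with a warning.

**Response ratio.** Rates are repetition-mean counts divided by 0.35 s;
the ratio $(r_{ON} - r_{sp})/(r_{ON} + r_{sp})$ is scale-invariant and
bounded in $[-1, 1]$. A 0/0 ratio is undefined and *dropped* from medians
rather than set to 0: a silent channel carries no light information, and
imputing 0 would bias group medians toward no effect.

**Group comparison.** Per intensity, a two-sided Wilcoxon rank-sum on
per-electrode ratios, electrodes pooled across retinas (group sizes such
as 161 vs 274 electrodes make electrode pooling the operative convention;
retina identity travels with the data for optional stratification). The
shared rank-sum engine uses midranks for ties and three p-value routes:
the exact no-ties null distribution for both groups ≤ 25; full enumeration
of assignments when there are ties and $\binom{n_1+n_2}{n_1} \le 2\times
10^5$ (identical samples then give exactly p = 1); otherwise the
tie-corrected normal approximation with continuity correction. Literal
exhaustive enumeration at the 25 + 25 boundary would require ~$10^{14}$
assignments, so the exact-distribution route stands in for it where it is
mathematically identical (no ties), and enumeration is reserved for small
tied problems.

### The synthetic world

Two tiers generate test data. The **count tier** draws ON/OFF/spontaneous
window counts directly as independent Poisson variables with mean
rate × 0.35 s — Poisson being the standard physiological null for spike
counts; no statement about over-dispersion is inherited from the assay, so
dispersion is deliberately not added (a config extension point). The
**trace tier** generates inhomogeneous-Poisson spike times whose rate
switches at flash boundaries, enforces a minimum inter-spike interval
equal to the template duration (1 ms default, below the 1.5 ms detector
pause, so ground-truth spikes are individually detectable), convolves them
with a biphasic template whose amplitude is expressed in units of the
noise SD, and adds white Gaussian noise. The mapping from light intensity
to firing rate is supplied explicitly per intensity (no intensity–response
function is assumed); a saturating Naka–Rushton helper builds such
vectors when graded responses are wanted.

Seeding is counter-based: one top-level seed fans out to per-channel (and
per-group) substreams, so simulating 3 channels reproduces the first 3
channels of a 300-channel run — a property the tests assert.

What a green test establishes: that the pipeline recovers what this world
contains — Poisson count statistics, template spikes ≥ 8× noise SD in
white Gaussian noise, rate steps aligned to flash boundaries. Real
recordings add drift, correlated noise, overlapping units, bursting and
adaptation, none of which are modelled; detection performance quoted on
this world is an upper bound.

## 2. Cone-survival kinetics

### Model

Cone density is parametrized as $N(t) = 2^{a - bt}$ (log2-linear in age),
matching the convention of plotting survival on a log2 axis; fitting is
unweighted OLS of $\log_2(\text{mean density})$ on age, on per-age means
("averaging all the analyzed positions from all the animals per stage"),
with an option to fit all records. A pure exponential never crosses zero,
so the "x-axis intersection" is defined as the crossing of a density
threshold θ, default 1 cone/100 µm — log2 = 0, i.e. the literal x-axis of
the log2 plot — giving `x_intercept = (a − log2 θ)/b`. The intercept is
equivariant under time shifts and is reported per arm without taking a
position on arm labels: the delay between arms is their absolute
difference. Fits with $b \le 10^{-8}$ log2 units/day (numerically flat or
rising) have no defined intercept and are flagged rather than erroring.
Nonpositive mean densities cannot enter a log fit and are excluded with a
warning; SEM at n = 1 is reported as 0 with a warning rather than NA so
downstream plotting code need not special-case it.

### Effect sizes

Per-animal log2 survival ratios (treated/contralateral control eye,
positions averaged within eye first) are compared across ages in a
shared-control design: every age's ratios against the earliest
post-treatment age. Hedges' g uses the pooled-SD standardizer with the
small-sample correction $J = 1 - 3/(4\,df - 1)$. The bootstrap CI
resamples both groups with replacement (default 5000 resamples) and
applies BCa correction — bias from the proportion of bootstrap estimates
below the point estimate, acceleration from a delete-one jackknife over
the combined observations — falling back to the percentile interval when
either is degenerate (all bootstrap values on one side, or zero jackknife
spread). The permutation p is the two-sided unpaired equal-variance t
under label permutation with +1 smoothing, $(b+1)/(n_{perm}+1)$; the
permutation count defaults to 5000 (only the bootstrap count is a stated
convention; the permutation count mirrors it).

### Synthetic world

`simulate_survival` draws each record as
$2^{a-b\,\text{age}} \times \mathrm{LogNormal}(0, \sigma)$ with σ set from
the target CV; multiplicative lognormal noise keeps densities positive and
becomes additive Gaussian noise on the log2 scale — exactly the error
model the OLS fit assumes. Default CV 0.1 and 6 eyes per age reflect
typical between-eye variability in cone counts (n = 5–10 animals per age
is the usual design). Positions share one expectation; the
center-to-periphery gradient of real degeneration is deliberately not
modelled, so positional analyses beyond averaging are out of reach of this
generator. Under the default world the fitted x-intercept carries a
standard error of roughly one day, which is why intercepts are asserted to
±3 days (≈3 SE) rather than to integer equality at arbitrary seeds.

## 3. Expression statistics

CPM is plain library-size normalization (`count / library × 1e6`); no
TMM-style composition correction is applied, since the filter and test
operate on the stated "> 1 CPM in ≥ 2 samples within ≥ 1 group" rule
(strict inequality — a gene at exactly 1.0 CPM everywhere is dropped) and
on `log2(cpm + 1)`.

The permutation-FDR t test follows the SAM/Perseus recipe: per-gene
equal-variance t; candidate cutoffs at the observed |t| values; estimated
FDR(c) = (mean permutation count of null |t| ≥ c) / max(1, observed count
≥ c); the smallest cutoff with estimated FDR below target defines the
significant set, which is therefore monotone in the target. Two details
are deliberate choices. First, the *mean* (not median) null exceedance
count is used, and the S0 variance-stabilization constant is 0, since
neither convention is dictated. Second, for equal group sizes the
assignment space is reduced to *partitions*: the two-sided |t| is
invariant under swapping group labels, and keeping both an assignment and
its complement would re-inject every observed statistic (via the mirrored
identity) into the null pool, bounding the estimated FDR below by
1/(#assignments − 1) ≈ 0.053 at 3 vs 3 — making an FDR-0.05 call
impossible at exactly the design size the assay uses. With the reduction,
3 vs 3 has 10 partitions, 9 informative ones, all enumerated whenever the
space fits under the randomization budget.

A caveat the tests document rather than hide: at n = 3 per group the
permutation null is heavy-tailed, and on strongly over-dispersed
negative-binomial counts the realized FDR of this estimator can exceed its
nominal target (this is the regime S0 was invented for). The calibration
checks therefore run on the benchmark the procedure is specified against —
a Gaussian log2-expression matrix with a spiked differential block
(residual SD 0.25 log2 units, typical replicate-level variability for
sorted-cell RNA-seq; 2 log2-unit shifts in 10% of genes) — where recall
≥ 0.8 and realized FDR ≈ nominal are achieved; the negative-binomial
generator remains available for integration and determinism tests.

ΔΔCT aggregates by arithmetic mean of per-sample ΔCT (technical
duplicates averaged first), reports group fold changes $2^{-\Delta\Delta
CT}$, and emits per-sample folds so group differences can be tested
nonparametrically with the shared Mann–Whitney engine.

## 4. Reproducibility plumbing

All generators are pure functions of (parameters, seed). Tabular outputs
are tab-separated UTF-8 with Unix newlines and full-precision numbers —
full precision was chosen over fixed 6-significant-digit formatting so
that write-then-read is an exact identity, which the tests assert.
Recordings are stored as a directory of `meta.json` plus a channel-major
float64 `voltage.bin` (float64 rather than float32 for the same exactness
reason; no HDF5 binding is available in the dependency budget, and the
layout mirrors the HDF5 design: one voltage dataset plus named
attributes). `run_pipeline()` validates its whole configuration before
executing any stage, then writes a manifest with the package version, a
config digest, per-stage seeds, output digests and timestamps; rerunning
an identical manifest reproduces identical digests.

## 5. Known limitations

- Electrode-level analysis only; no spike sorting, no bursting/adaptation
  dynamics, no biophysical retina model.
- The trace-tier noise is white and Gaussian; detection thresholds on real
  data with correlated noise will behave conservatively relative to the
  quoted sensitivity/precision.
- The decay model is a single exponential; biphasic or plateauing
  degeneration would need a different parametrization, and the x-intercept
  is an extrapolation whose meaning depends on θ.
- The permutation-FDR estimator is reliable at the spiked-Gaussian
  benchmark but approximate on heavy-tailed counts at n = 3 (no S0).
- Bootstrap CIs use BCa with a percentile fallback; at very small groups
  (< ~5) coverage claims should not be trusted.
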