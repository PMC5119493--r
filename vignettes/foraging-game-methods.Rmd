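---
title: "Methods: the GAL-ON/GAL-OFF foraging game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the GAL-ON/GAL-OFF foraging game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galgame)
library(dplyr)
```

## The model and its assumptions

`galgame` models clonal yeast populations growing on glucose and galactose
in batch culture as a consumer-resource game between two phenotypes. The
model is deliberately minimal:

* **Threshold kinetics.** A resource is either available or exhausted.
  While available, a lineage grows exponentially at a constant rate; when
  its usable resources are gone, it stops. There is no Monod saturation,
  no pH or byproduct effect. This choice makes every between-event segment
  a linear ODE with closed-form solution, so depletion times, densities
  and mass balance are exact to solver tolerance (`1e-9` relative on the
  resource balance, Newton iteration with bisection safeguard) rather than
  integration step size — and the test suite can hold the simulator to a
  brute-force oracle at `0.1%`.
* **Two variants.** In the *exclusive* game (the idealized thought
  experiment), GAL-ON cells consume only galactose at
  `r_galactose * (1 - cost_rate)` and GAL-OFF cells only glucose at
  `r_glucose`. In the *diauxic* variant (what the organism actually does),
  both phenotypes consume glucose while it lasts — GAL-ON at
  `r_glucose * (1 - cost_rate)` plus `co_consumption` of its galactose
  rate — and after glucose depletion GAL-ON alone grows on galactose at
  the full `r_galactose`. The rate cost is confined to the glucose phase:
  on galactose, expressing the GAL pathway is necessary work, not a
  burden; during the glucose phase it reflects both gratuitous expression
  and the pathway commitment of ON cells. The yield cost
  (`1 - cost_yield`) applies to all GAL-ON conversion.
* **Strategies.** A genotype is a heritable rule `p_on`: the probability a
  cell adopts GAL-ON at the start of a growth cycle. `p_on` of 1 or 0 are
  the engineered pure strategists; interior values are mixed strategists.
  Optional first-order phenotype-switching rates transfer cells between
  compartments during growth (solved by eigen-decomposition of the 2x2
  compartment system, including the defective repeated-eigenvalue case).
  Engineered GAL-OFF strategists never activate galactose growth
  (`lag_off_to_gal = Inf`); wild-type-like genotypes can activate it a lag
  after glucose depletion (`post_depletion_switch`).

Negative frequency dependence needs no extra ingredient: the more GAL-ON
cells, the less galactose each receives after the shared glucose phase,
so GAL-ON doublings fall — and GAL-OFF doublings rise, because a
GAL-ON-rich culture consumes glucose more slowly — as the GAL-ON fraction
grows. The crossing of the two doubling curves is the evolutionarily
stable fraction `f*`; mutual invasibility (each pure strategist's
relative fitness above one when rare) is its signature.

## Parameter defaults and their calibration

The defaults describe the standard assay: 0.03% (w/v) glucose + 0.05%
galactose, a 20 h incubation, inoculation at 3e4 cells/ml, and OD
conversion at 3e7 cells/ml per A600 unit.

| parameter | default | rationale |
|---|---|---|
| `r_glucose` | 0.45 /h | ~1.5 h doubling on glucose |
| `r_galactose` | 0.36 /h | galactose supports slower growth |
| `yield_glucose` | 6e7 cells/ml per % | 0.01% glucose saturates at ~6e6 from 3e4 cells/ml |
| `yield_galactose` | 2.4e7 | galactose is the less efficient carbon source |
| `cost_rate` | 0.5 | GAL-ON glucose-phase penalty (see below) |
| `cost_yield` | 0.1 | conversion penalty of running the GAL pathway |
| `co_consumption` | 0.1 | modest galactose uptake by ON cells during the glucose phase |
| `lag_off_to_gal` | `Inf` | engineered OFF strategists stay silent all assay |

The calibration logic deserves to be explicit. Under threshold kinetics
the GAL-ON payoff — the whole galactose pool once glucose is gone — is
large, so an interior crossing near 40% GAL-ON requires a substantial
glucose-phase handicap and a galactose pool that supports fewer cells
than the glucose pool suggests at face value. Small symmetric costs (a
few percent on rate and yield) leave GAL-ON favored at *every* frequency
in this model; they cannot produce the observed mutual invasibility at
all. The defaults above were chosen once, jointly, to reproduce the
qualitative structure of the system — GAL-ON disadvantaged while glucose
is abundant, an interior crossing near 0.43 at the 0.03/0.05 mix,
equilibrium rising with galactose and falling with glucose, a GAL-ON
boundary at very low glucose:galactose ratios, and convergence of
serial-dilution dynamics to the batch crossing — and then frozen. The 50%
glucose-phase rate penalty is a phenomenological effective value: it
absorbs everything the threshold model leaves out (graded uptake
commitment, induction dynamics), and is larger than a pure expression
burden would be in a saturating-kinetics model.

Two readouts are deliberately imperfect. Saturating density at the
default mix is ~2.9e6 cells/ml, somewhat below the ~4e6 a real culture
reaches, a direct consequence of the reduced galactose yield. And above
the crossing, total 16 h density is flat-to-slightly-declining in the
GAL-ON fraction (the yield cost routes glucose through the cheaper
pathway) rather than still rising; the robust, tested contrast is that
ON-rich cultures have saturated by 16 h while OFF-dominated cultures are
still growing.

## Fitness statistics

Fitness is counted in doublings. For a co-culture measured before and
after incubation,

* absolute fitness: `W_abs = log2((OD_f * f_f) / (OD_i * f_i))`,
* relative fitness: `W_rel = ln((OD_f * f_f)/(OD_i * f_i)) /
  ln((OD_f * (1-f_f))/(OD_i * (1-f_i)))`,

and the two agree exactly (`W_rel = W_abs_focal / W_abs_other`) whenever
both strains grew. Fractions of exactly 0 or 1 make fitness undefined and
raise an error naming the row; clamping to half an event count is
available but only behind an explicit flag, because silent pseudocounts
distort invasion statistics.

## Estimating the equilibrium from assay data

`fit_equilibrium()` fits `W_rel` against the initial GAL-ON fraction with
a least-squares polynomial and reports the stabilizing root of
`fit = 1`, with a bootstrap confidence interval resampling records
(stratified within replicates when a `replicate` column exists). The
family and degree of the fit are not dictated by the assay itself, so the
defaults were chosen by a parameter-recovery study against this package's
own synthetic generator (60 records, default noise, 40 seeds):

| estimator | median bias | 95% CI coverage |
|---|---|---|
| cubic polynomial, percentile CI | -0.011 | 0.00 |
| quintic polynomial, percentile CI | -0.0001 | 0.90 |
| quintic polynomial, normal CI | -0.0001 | 0.95 |
| GCV smoothing spline | +0.0004 | 1.00 (interval ~0.8 wide) |

The cubic is systematically biased because the relative-fitness curve has
a kink at the fraction below which galactose is no longer exhausted
within the 20 h horizon; the GCV spline chases noise and produces
uselessly wide intervals. The quintic with a normal-approximation
bootstrap interval (estimate ± z * bootstrap SE) is unbiased with nominal
coverage, and is the default; cubic, spline and percentile intervals
remain available as arguments. When the fit never crosses 1 inside the
observed range, the endpoint closest to neutrality is returned with a
boundary flag — the regime where one strategist is preferred at all
frequencies.

Threshold gating of cytometry-style tables places the auto-threshold at
the KDE valley (Gaussian kernel, Silverman bandwidth) between the two
largest modes, requiring a secondary mode at least 5% of the main peak;
unimodal tables — like a population in a low-level activation state that
straddles any fixed ON/OFF threshold — are flagged un-gateable rather
than assigned a fraction. Fixed thresholds are preferred inside pipelines
for comparability.

## What the synthetic generator does and does not emulate

`gen_competition_dataset()` reproduces the 60-culture design: 10 initial
GAL-ON fractions x 6 replicates, grown in the diauxic model, measured as
OD with multiplicative lognormal noise (`od_cv = 0.05`, a plausible
plate-reader precision; mean-preserving) and as fractions with binomial
20,000-event counting noise. `gen_cytometry_events()` draws log10
fluorescence from a two-Gaussian mixture (means 1.5 and 3.0, SD 0.25 —
chosen for clear bimodality; no numeric fluorescence scale is implied).

Passing tests on these generators show that the estimators recover known
truth under the model's own noise assumptions. They do not show
robustness to what real data add: instrument drift, autofluorescence,
doublets, density-dependent OD nonlinearity, or biological replicate
effects beyond sampling noise.

## The in-silico evolution experiment

`evolve()` mirrors the laboratory protocol: 26 daily cycles (dilutions
200x, 500x, then 24 x 1000x — `expected_generations()` gives 255.8
doublings of regrowth, the "about 250 generations" of the protocol), in
0.2 ml wells tracked as integer cell counts, so the ~580-cell bottleneck
after a 1000-fold dilution carries real drift. Each cycle realizes
phenotypes binomially, grows the population in the diauxic model, applies
mutation, and samples bottleneck survivors binomially. Outcomes are
classified on the pooled GAL-ON fraction of the final five cycle starts
(`> 0.95` fixed, `< 0.05` lost, otherwise an interior mix; a population
below one cell is extinct).

Mutation needs two sources to reproduce the experiment's phenomenology:

* **Standing variation.** The founders are the engineered pure
  strategists; a GAL-OFF founder cannot divide at all in pure galactose,
  so de-novo mutation during the experiment cannot rescue it (no
  divisions, no mutants). Rescue must already be on the plate: the
  doxycycline induction preculture grows the founder for `log2(200) ~ 7.6`
  generations, seeding the inoculum with pre-existing strategy mutants at
  frequency `mutation_rate * preculture_generations`.
* **Jackpot clones.** A de-novo mutant arising mid-cycle reaches the
  bottleneck as a clone, not a single cell; clone sizes follow the
  `~1/U` Luria-Delbrück tail (capped by the parent count). Without this,
  every mutant faces a 1/1000 survival lottery alone and essentially none
  establishes.

With `mutation_rate = 3e-5` per division — an effective rate for any
lesion that disables or constitutively activates the engineered induction
circuit, not a per-base-pair rate — the inoculum carries ~1.5 expected
pre-existing GAL-ON mutants. That single number reproduces the observed
three-condition contrast: in pure galactose most replicates are swept by
a constitutive GAL-ON mutant while the unrescued minority washes out to
extinction; in mixed sugars populations converge to the *cycle game's*
interior equilibrium (~0.39 — slightly below the 20 h assay crossing of
0.43, because the deeper 1000-fold bottleneck lengthens the glucose phase
where GAL-ON pays its cost); and in pure glucose GAL-ON stays below 5%.
The default mutation kernel (45% to `p_on = 0`, 45% to `p_on = 1`, 10%
uniform) encodes the two mutation classes the circuit offers in quantity
plus rare tuning mutations; which founder backgrounds evolve genetic
coexistence versus clonal mixed strategists depends on this kernel, and
the package exposes, but does not resolve, that dependence.

`colony_assay()` implements the discrimination step: colonies founded by
single cells sampled by genotype frequency are regrown clonally; colonies
split between ~0 and ~1 GAL-ON indicate coexistence of pure strategists,
while colonies that each reproduce an interior fraction indicate a clonal
mixed strategist (interior meaning 0.05-0.95; a simple majority of
interior colonies classifies the population as clonal-mixed).

## Numerical choices and degenerate inputs

* Depletion times: Newton with bisection fallback, residual below
  `1e-9 * resource`; no consumers returns `Inf`, not an error.
* `stable_fraction()`: a 21-point scan for sign changes, bisection to
  `1e-4` on the fraction; no sign change returns the favored boundary
  with a flag; multiple crossings are all returned with a warning, never
  silently resolved.
* `optimal_fraction()`: minimizes the joint depletion time (the
  growth-optimal mix exhausts both sugars simultaneously in the exclusive
  game), coarse grid then golden-section refinement to `1e-3`; a
  single-resource environment returns the corresponding boundary.
* Problem sizes: oracle-equivalence tests run 20 randomized small games
  against forward Euler at `dt = 1e-4` h; mass balance runs 100; the
  recovery study runs 50 seeded 60-record datasets with 200 bootstrap
  draws; the evolution contrast runs 8 replicates x 26 cycles per
  condition. These sizes give stable pass/fail behavior for the
  properties tested while keeping the default suite quick.
* All stochastic entry points take explicit seeds and leave the caller's
  RNG state untouched (`withr::with_seed`); replicate `r` of `evolve()`
  derives an independent stream from the base seed.

## Known limitations

* Threshold kinetics make depletion-time structure (and hence the kink in
  the relative-fitness curve) sharper than Monod kinetics would; the
  phenomenological `cost_rate` is correspondingly inflated.
* The stable fraction depends on the inoculum depth (bottleneck size) —
  a real and tested property of batch games, but it means `f*` must
  always be quoted with its cycle conditions.
* No ratio-sensing: wild-type cells in this package do not tune `p_on` to
  the sugar mix; strategies are fixed rules changed only by mutation.
* The evolution module's mutation parameters are effective values
  calibrated to reproduce observed outcome frequencies, not measured
  rates.
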