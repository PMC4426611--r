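---
title: "Methods: flow-through sulfur flux and tracer-based carbon fixation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow-through sulfur flux and tracer-based carbon fixation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventflux)
```

## The measurement problem

Hydrothermal-vent molluscs such as *Alviniconcha* spp., *Ifremeria nautilei*
and *Bathymodiolus brevior* host intracellular chemoautotrophic bacteria that
fix carbon using the energy of sulfur oxidation. Quantifying what an intact
symbiosis does with sulfur requires incubating live animals in pressurized
flow-through aquaria and watching two currencies at once:

* **Sulfur**, resolved as total sulfide, thiosulfate and polysulfides by an
  in-line voltammetric microelectrode that samples each aquarium's effluent
  in a repeating cycle, and
* **Carbon**, traced by spiking the input seawater with ¹³C-bicarbonate and
  measuring how much label each animal's symbiont-bearing gill accumulates
  over the incubation.

`ventflux` implements the full reduction from these raw observations to
mass-specific rates, plus a synthetic generator that emits complete
in-silico experiments with known ground truth so every stage can be
validated quantitatively.

## From scans to interval concentrations

The electrode visits four channels (three experimental aquaria, then a
reference line — either an empty control aquarium's effluent or the input
water) in 30-minute intervals; the four-interval pass is a 2-h *set*. Within
an interval it fires two bursts of 21 scans (minute 0 and minute 15, one
scan per ~2 s), i.e. nominally 42 scans. Assignment of scans to intervals is
by timestamp window, so cadence jitter is tolerated; a scan whose channel
contradicts the schedule is a hard error naming the offending window.

Immediately after a channel switch the sensed concentration still carries
the previous channel's water. The first `discard_n = 10` scans of each
interval (24% of 42, rounded half-up) are therefore discarded, once per
interval, and the remaining scans averaged into the *interval
concentration*.

Censoring: each analyte has a detection limit (sulfide and polysulfides
0.20 µM, thiosulfate 30 µM). Censored scans still participate in the
average — summary tables of the original measurements report means whose
minima are below detection, which is only possible if censored values enter
the averaging — but the substitution value is not documented anywhere we
could find, so it is exposed as an option (`"zero"` by default, `"half-limit"`,
`"limit"`, or any number). An interval whose resulting mean falls below the
limit is itself flagged `is_bdl`. Reported minima/maxima are over interval
concentrations, not raw scans; we chose the interval level because that is
the quantity the rest of the pipeline consumes.

## Mass-specific net rates

For each set, the experimental interval concentration minus the reference
interval concentration, times the flow (L h⁻¹), divided by the total wet
gill mass in that aquarium, gives the signed mass-specific rate in
µmol g⁻¹ h⁻¹ (µM · L h⁻¹ / g). Negative is net uptake (oxidation), positive
net excretion. Each experimental interval is paired with the single
reference interval of its own set; the flow rate is configuration, never
inferred from data.

Rates are computed only after the aquarium has approached steady state: at
least 10 h elapsed *and* at least three volume turnovers
(`max(min_elapsed_h, min_turnovers · volume/flow)`). Below-detection
intervals enter rate arithmetic as the substitution value and flag the rate;
pairs censored on both sides are excluded from summaries. A compound absent
from the reference but above detection in an effluent across ≥ 2 consecutive
gated sets is reported as *sustained excretion*.

## The tracer chain

Carbon fixation per animal comes from a four-step chain. With `A%` denoting
atomic percent ¹³C:

1. **Mixing fraction.** The symbiont-free foot is the individual's
   unlabelled baseline (it receives no appreciable translocated gill carbon
   on this timescale), so
   `%¹³C_inc = 100 · (A%_gill − A%_foot) / (A%_water − A%_foot)`.
2. **Incorporated mass.** `W¹³C = (%¹³C_inc/100) · DW_g · %C`, with `DW_g`
   the gill sample dry weight and `%C` its carbon content (accepted as
   fraction or percent, with an explicit unit declaration).
3. **Dry-specific rate.** `DryC_inc = 10⁶ · W¹³C / (MW · t · DW_g)`
   µmol ¹³C g⁻¹ dry h⁻¹, with `MW = 13.00335` g mol⁻¹ (the exact ¹³C
   isotope mass) and `t` the duration in hours. This is the only form of the
   conversion dimensionally consistent with the stated output unit.
4. **Wet-specific rate.** `C_inc = DryC_inc · DW_g / W_g`.

Gills that read at or below the foot baseline — possible under measurement
noise — are clamped to zero with a flag by default (`clamp = FALSE` reports
raw values). Converters between δ¹³C (VPDB, ratio 0.0111802) and atomic
percent are provided for users whose mass-spectrometry output is in per-mil.

## Allometry

Animals whose gills were not directly weighed get a predicted gill mass from
an ordinary least-squares line of gill wet mass on body wet mass, fitted per
genus on the weighed animals. We regress gill on body (not the reverse)
because gill mass is the prediction target. The fit is linear on the raw
scale by default, with a log-log (power-law) option; predictions at or below
zero are floored with a warning. Measured masses always override
predictions, and per-aquarium totals used by the flux stage are the sum of
measured-plus-predicted gills, so the two stages cannot drift apart.

## Stoichiometry

Carbon and sulfur currencies are linked by the molar ratios 6.21 (mol
sulfide per mol C fixed) and 6.64 (mol thiosulfate per mol C fixed), which
embed an assumed 10% efficiency of energy conservation; the efficiency is
stored for documentation only. Two derived quantities:

* **Attribution**: the predicted oxidation flux of the `top_k` most
  productive individuals (`C_inc · gill mass · ratio`, summed) as a percent
  of the measured aquarium flux (`|rate| · total gill`). Monotone in
  `top_k`, and exactly 100% when the aquarium flux is built from the same
  individuals.
* **Excretion fraction**: excretion over |uptake| on a *sulfur-atom* basis
  (thiosulfate carries two sulfur atoms, sulfide one; the polysulfide chain
  length is configurable 1–8 and defaults to per-molecule accounting, since
  no chain-length convention is stated for the reported polysulfide band).
  With standard deviations supplied, a band is propagated by interval
  arithmetic on the ± 1 sd bounds. The reported bands for *B. brevior*
  (5–5.2%) and *I. nautilei* (11–47%) are not recoverable from the printed
  mean rates under any atom convention we tried; the interval mode documents
  rather than forces such statements.

## Exact small-sample tests

With 3–10 animals per aquarium, asymptotic rank tests are unreliable, so
both tests enumerate the complete permutation null of the rank statistic:

* `mann_whitney_exact()`: U from midranks; two-sided
  `p = 2 · min(P(U ≤ u), P(U ≥ u))`, capped at 1 — the convention under
  which sizes 3 and 4 with U = 1 give exactly 4/35 ≈ 0.114. The exact p is
  rational with denominator `choose(n₁+n₂, n₁)` and the fraction is exposed.
* `kruskal_wallis()`: tie-corrected H; p by full enumeration of all distinct
  group assignments, Monte-Carlo permutation, or χ², with the method
  recorded.

Exactness is gated on the *arrangement count* (defaults 10⁶ for two groups,
3·10⁵ for k groups) rather than on a raw sample-size bound, because the
count is what determines feasibility: sizes 5 + 5 + 4 need
14!/(5!·5!·4!) = 252 252 arrangements and enumerate in seconds, while
two groups of 12 + 13 would need ~5·10⁶. For continuous data the null
depends only on the group sizes, so `kw_null_distribution()` can be computed
once and reused across replicates — that is how the suite verifies the
test's type-I error at aquarium-scale sizes with 1000 simulations.

## The synthetic generator

The generator is the package's reference instrument: it draws a cohort,
emits the scan series a voltammetric electrode would record, and writes
tissue isotope tables that are the *exact algebraic inverse* of the tracer
chain, so recovery can be checked against known truth.

What it emulates, and the conditions chosen (fixed once, as the scenario
definition):

* **Cohorts.** Genus-specific body-mass distributions (means 38–42 g, sd
  8–9 g) and gill masses from a genus allometric line plus noise, giving
  ~4–5 g wet gill per animal, consistent with reported cohort totals.
  Preset cohort sizes per genus are 5/5/4 (sulfide rate), 3/4/3
  (thiosulfate rate), 5/5/4 (sulfur-free), 10/5/6 (sulfide variation) and
  8/10/6 (thiosulfate variation).
* **Hydraulics.** Flow 0.75 L h⁻¹ and volume 2 L per aquarium. The flow
  back-computes from the reported sulfide-variation cohort (≈ 250 µmol h⁻¹
  uptake drawing a 350 µM supply down by ≈ 330 µM implies ≈ 0.76 L h⁻¹);
  the volume makes three turnovers (8 h) complete inside the 10-h gate, as
  described for the original incubations. Duration 24 h.
* **Positional depletion.** The true fixation rate of the animal at stack
  position *p* is `base · (1 − a)^(p−1)` — a phenomenological geometric
  knob (not a hydrodynamic model) emulating upstream animals depleting the
  substrate for downstream ones. Presets use a = 0.2 (rate) and a = 0.5
  (variation). Base rates (0.7 and 3 µmol C g⁻¹ h⁻¹) were chosen so that
  aquarium-level depletion leaves measurable effluent and, in the sulfide
  variation preset, excreted thiosulfate straddles its 30 µM detection
  limit across aquaria — reproducing the reported pattern in which some
  genera's excretion registers and others' stays below detection.
* **Chemistry.** Steady-state mass balance
  (`effluent = input − Σ uptake·gill / flow`, floored at 0 with a warning)
  with a linear ramp over the first three turnovers so the gating rule has
  something to exclude; a transient ODE model would add nothing the
  post-gate analysis could see. Excretion rules convert a sulfur-atom
  fraction of uptake into the excreted analyte's effluent concentration.
* **Measurement.** Two 21-scan bursts per interval; the first 10 scans of
  each interval relax exponentially (fraction 0.3 per scan) from the
  previous channel's concentration; additive Gaussian noise (sd 2 µM);
  scans whose underlying concentration is below the analyte limit are
  emitted censored. Gill atom-percent noise is 0.001 A% (typical
  isotope-ratio mass-spectrometry precision); the label brings input DIC to
  5 atom% against a 1.11 atom% natural baseline.

Everything is deterministic under the configured seed, which is written into
every output header.

What it does **not** emulate — and hence what passing tests do not show
about real data: temporal drift of vent-supplied input water (synthetic
min–max ranges are narrower than real ones), oxygen dynamics, temperature,
genus- or phylotype-specific physiology, host detoxification pathways, and
any real hydrodynamics inside the aquaria.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_experiment(scenario_preset("sulfide_variation", seed = 42))
dir <- tempfile()
write_scenario(sim, dir)
run <- run_pipeline(dir, scenario_pipeline_config(sim))
run$rate_summary
run$excretion
cat(report_text(run), sep = "\n")
```

The recovered mass-specific uptake matches each aquarium's generated truth
to well within 5% at the default noise, and the excretion report returns
the configured 27% sulfur-atom fraction.

## Numerical and scale choices

* Discard-percentage rounding is half-up (10/42 → 24%).
* Interval means compare to detection limits directly; exact-test tail
  comparisons use a 10⁻⁹ epsilon to make rank ties robust to float noise.
* Output CSVs serialize floats at 6 significant digits so reruns are
  byte-identical and diffable.
* Test and validation problem sizes: 24-h scenarios (48 intervals, ~6000
  scan rows), 500-replicate tracer-noise checks, 1000-replicate type-I
  simulations against a precomputed 252 252-point exact null. The whole
  suite runs in well under a minute.

## Known limitations

* The censoring substitution (0/limit-half/limit) is a bounded guess; with
  heavily censored data the choice materially moves means, and rates whose
  inputs were censored carry flags for exactly this reason.
* Attribution assumes the stoichiometric ratios apply uniformly across
  individuals; real symbiont populations need not oblige.
* The allometric line is fitted per genus per experiment; with fewer than a
  handful of weighed animals its prediction error is not propagated into
  rate uncertainties.
* One reference interval per set is the pairing the set structure defines;
  if reference chemistry drifts within a set, an interpolating pairing
  between neighbouring reference intervals (not currently implemented)
  would be preferable.
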