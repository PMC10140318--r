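---
title: "Methods: gating, kinetics and marker analysis for oxygen-level cultivation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gating, kinetics and marker analysis for oxygen-level cultivation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probioflow)
```

probioflow analyses oxygen-level cultivation studies of probiotic
lactic acid bacteria: online flow cytometry follows viability in real
time while conventional assays quantify growth, fermentation products,
membrane lipid composition and probiotic functionality markers. This
vignette documents the models behind each stage, the tunable parameters
that matter, what the synthetic-data generator does and does not
emulate, and the numerical conventions adopted where the underlying
protocols leave choices open.

## Viability gating of online flow-cytometry data

Cells double-stained with SYBR Green I and propidium iodide (PI)
separate into four subpopulations in the (FL1-H, FL3-H) plane: intact
cells (green-bright, red-dim), two classes of membrane-damaged cells
with progressively more PI uptake, and cell debris with low overall
stain uptake. Gating proceeds in three steps.

**Preprocessing.** Events with FL1-H below the acquisition threshold
(default 500 channel numbers; no threshold on FL3-H) are discarded,
mirroring the instrument trigger. Retained events are transformed to
$(\log_{10}\mathrm{FL1},\ \log_{10}\max(\mathrm{FL3},1))$. The log
transform matters because raw channel values span four decades and
cosine distance on raw intensities degenerates to comparing the
dominant channel only; the floor of 1 on FL3 keeps PI-negative events
finite at coordinate 0.

**Spherical k-means.** Feature vectors are unit-normalised and Lloyd
iterations minimise the total cosine distance to the cluster centroids,
with the best of `restarts = 20` seeded initialisations kept.
Initial centroids are drawn by k-means++ seeding under cosine distance
rather than uniformly: intact cells typically outnumber the other
populations five-to-one or more, and uniformly drawn centroids then
land in the dominant cloud in almost every restart, after which Lloyd
reliably splits the intact population instead of resolving the small
damaged clusters. Squared-distance-weighted seeding places initial
centroids across the angular range, and on well-separated synthetic
clouds it recovers the generating partition in essentially every
restart. Convergence is declared when assignments stabilise (or after
300 iterations); an emptied cluster is re-seeded from the worst-fitted
point. All randomness derives deterministically from one seed, so a
gated run is exactly reproducible.

Because cosine distance is magnitude-blind, clustering separates
populations by their FL3:FL1 *angle* — the stain-ratio axis that orders
intact → damaged A → damaged B. Labelling uses this ordering for the
three cell clusters, with angle ties broken by median raw FL3. Debris,
however, is defined by low overall uptake, not by ratio, so it is
identified first as the cluster with the lowest median raw FL1; this is
the one point where raw magnitudes re-enter. One model is fitted per
sample (per time point), matching how replicate-restarted clustering is
usually applied to online cytometry series; a pooled model across
samples would hide abundance shifts in exchange for stability and is
deliberately not the default.

**Fixed gates and agreement.** The fixed-gate alternative partitions
the plane with user-defined oriented lines. `wedge_gates()` builds the
angular analogue of the clustering (boundary rays through the origin),
`quadrant_gates()` the classic quadrant layout. All inequalities are
non-strict and the first-listed region wins on shared boundaries, so
boundary events are assigned deterministically. Method agreement is
scored per population as the squared Pearson correlation between the
two count series — the convention used when automated gating is
benchmarked against manual gating, where values above 0.9 are read as
good agreement.

Counts convert to concentrations as
`count / acquired_volume × dilution_factor` (events per mL of
undiluted culture), with 20 µL acquisition volume and 1000-fold online
dilution as defaults. The four subpopulation counts sum to the total
exactly, by construction, before any volume scaling.

## Growth and fermentation kinetics

**Growth rate.** `estimate_mu_max()` fits $\ln(\text{signal})$ against
time over every window of at least `min_points = 4` samples and keeps
the window with the steepest slope among those with $R^2 \ge$
`r2_min = 0.98`, ties going to the earliest window. This makes the
"unrestricted exponential phase" an explicit, reproducible choice
rather than a hand-picked range. If no window reaches the floor the
best-fitting window is returned with a degraded-fit flag rather than an
error, so flat or noisy series still yield a diagnosable result. The
estimator is invariant to positive rescaling of the signal, which is
why OD readings and cytometry totals can be compared directly.

**Yields, rates, carbon balance.** Yields are net product formed over
glucose consumed between the first and last samples; biomass yield uses
harvest CDW minus a configurable inoculum biomass (default 0 — a start
OD of 0.2 contributes about 0.09 g/L, visible in the biomass yield but
negligible elsewhere). Specific rates divide by harvest CDW and the
time from inoculation to glucose depletion, defined as the first sample
at or below a configurable floor (0.1 g/L). The end-point carbon
balance counts C-mol on both sides: glucose C6 and citrate C6 consumed
against lactate C3, acetate C2, ethanol C2, succinate C4, biomass
(configurable composition, default CH$_{1.8}$O$_{0.5}$N$_{0.2}$ at
24.6 g/C-mol) and CO₂. CO₂ is not measured off-gas; it is estimated
from heterofermentative stoichiometry as moles of ethanol plus acetate
net of acetate attributable to citrate (citrate lyase yields an acetate
without a phosphoketolase CO₂). This convention makes exactly
stoichiometric glucose fermentations close at 100%; profiles with
citrate co-consumption under-recover slightly because the CO₂ released
by oxaloacetate decarboxylation is deliberately not imputed. Balances
outside [90, 110]% raise a warning, not an error.

## Membrane lipid summaries

FAME tables hold µg FAME per mg CDW per fatty acid and replicate,
already normalised to the internal standard (C17:0) upstream —
chromatogram integration is out of scope. The summary statistics follow
the conventions of composition tables: per-FA means and SDs, total FA
as the sum of means with SD propagated as the square root of the summed
per-FA variances, UFA and SFA sums over class-assigned means, and the
UFA:SFA ratio of those sums. Relative abundance has two modes because
they genuinely differ on noisy replicates: the primary mode divides
each replicate's FAME by that replicate's total and averages the
percentages (each replicate is a complete composition); the
ratio-of-means mode divides mean by total mean and is what printed
tables of means can support. Saturation is parsed from shorthand
(C16:0 → SFA, C18:1 → UFA); cyclopropane fatty acids are outside the
shorthand rule and default to UFA — they derive from unsaturated
precursors, behave comparably in terms of membrane fluidity, and this
assignment reproduces the class sums of the bundled reference
composition. Below-LOQ cells carry value 0 with a flag so sums stay
defined while reports can annotate them.

`fame_reference_dsm17938()` bundles a published-scale reference
composition for *L. reuteri* DSM 17938 under three aeration regimes.
Only the palmitic and oleic rows are certain identities; the remaining
identifiers are synthetic placeholders chosen to be consistent with the
published class totals, and are documented as such.

## Probiotic functionality markers

Freeze-drying survivability is the CFU ratio after/before drying in
percent — deliberately plate-count based; a cytometry-intact-based
variant would measure membrane integrity, not culturability, and the
two are not conflated. Values above 100% are flagged, not clamped.

Acid-challenge assays are summarised as per-timepoint log₁₀ reductions
and a death rate from the least-squares fit of log₁₀ CFU on time over
uncensored points. Censoring follows plate-count practice: a
zero-colony plate bounds the concentration from above, so such points
carry the LOD value and a censored flag instead of zero (which would be
−∞ in log space), are excluded from the fit, and are counted. The
per-assay "detected at the final timepoint" flag supports
survived-in-k-of-n statements.

Bile-tolerance lag is the first upward crossing of the OD cutoff
(default 0.5), linearly interpolated on the 15-min reading grid —
quarter-hour precision matches how such lags are conventionally
reported. No smoothing is applied by default, so a transient spike
above the cutoff is honoured; a 3-point median mode exists for noisy
readers. No baseline (bile-free control) subtraction is performed.
5′-nucleotidase activities are averaged with the technical/biological
nesting preserved: technical replicates are averaged within each
biological replicate first, so technical pseudo-replication cannot
shrink the reported SD.

## The synthetic-data generator

The generator produces every input with the statistical structure the
analysis assumes, under one master seed that expands deterministically
into per-stage seeds.

**Batch cultures.** Biomass is flat through a lag, grows exponentially
at `mu_max`, and arrests when glucose is exhausted; products form
proportionally to glucose consumed at fixed yields; citrate is either
depleted linearly by 3 h or untouched; DOT decays linearly to zero by
`dot_depletion_h`, stays there while glucose lasts, and recovers only
in aerated scenarios. This is a piecewise description, not a kinetic
ODE model: the analysis stages consume magnitudes and timings, and
published profiles constrain only those. Defaults are anchored to a
1-L MRS batch under gentle aeration: growth at 0.74 h⁻¹ after a 3-h
lag, 18 g/L glucose exhausted just before 7 h, DOT depleted at 2.55 h,
harvest CDW near 1.6 g/L. Measurement noise is additive Gaussian at a
configurable CV (default 2%) per series; the noiseless series are
retained so estimators can be validated against generating values. The
per-condition yield defaults in `default_run_config()` keep the
air-versus-anaerobic contrast (acetate up, ethanol down under air) but
are adjusted to be approximately carbon-closing under the package's
balance convention, rather than copied verbatim from any one
experiment: yield sets that overshoot closure would make every default
run warn about its own mass balance.

**Event clouds.** Each subpopulation is an isotropic log-normal cloud
in (log₁₀ FL1, log₁₀ FL3) — the typical shape of fluorescence
populations; real data constrain the cluster geometry only loosely, so
location, dispersion and abundance trajectories are explicit
configuration, not hidden constants. Default centroids are ordered in
angle (debris 15°, intact 28°, damaged A 40°, damaged B 50°) with
neighbouring separations above four angular SDs, and debris carries the
lowest FL1 magnitude, a few percent of which falls below the
acquisition threshold and exercises the preprocessing filter. Event
numbers track biomass, with the effective dilution factor chosen so
that counting recovers the profile's true concentration; sampling every
30 min emulates roughly two online samples per hour. Every synthetic
event keeps its generating label, so confusion matrices against the
gating are exact.

**Assays.** FAME replicates are mean-preserving log-normal
perturbations (multiplicative noise is the natural error structure of
chromatographic quantification; negative masses are impossible; zero
means stay zero). Acid-challenge counts decline log-linearly with
Poisson plating noise at a per-timepoint serial dilution targeting
about 100 colonies. Bile curves are flat baselines followed by logistic
growth to `od_max` on a 15-min grid.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: instrument drift and spectral spillover
between FL1 and FL3, doublets and non-elliptical cluster shapes,
kLa-driven DOT dynamics, product inhibition or diauxic behaviour,
medium-derived fatty-acid incorporation, and plate-count overdispersion
beyond Poisson. Results on synthetic data validate the estimators'
correctness, not the biology.

## Numerical choices and degenerate inputs

- Windows in the growth-rate search are compared with a 10⁻¹² slope
  margin; ties go to the earliest window, making results independent of
  window enumeration order.
- k-means restarts keep the first solution within 10⁻¹² of the best
  objective, so restart order cannot flip the result.
- DOT depletion and bile lag interpolate linearly between bracketing
  samples; crossings exactly at a sample return that sample's time, and
  series that never cross report a status rather than an arbitrary
  number.
- Zero-norm feature vectors (possible only below the FL1 threshold)
  are rejected before clustering; all-identical directions are valid
  for k = 1 and rejected for k larger than the number of distinct
  directions.
- Constant signals yield slope 0 with a degraded-fit flag; empty
  conditions, zero glucose consumption, and missing channels raise
  errors that name the offending quantity.

## Problem sizes used in the shipped checks

The bundled tests and the acceptance script run entirely on synthetic
data at deliberately modest sizes: gated time courses of 10,000 events
per sample across 12 samples and 20 seeds for the method-agreement
study, 100 seeded cultures for growth-rate and yield recovery, and
exhaustive clustering oracles at 12–200 events. These sizes were chosen
as the smallest at which the stochastic claims stabilise; all scale
linearly if larger studies are needed.

## Known limitations

- The damaged-A/damaged-B distinction is an angular ordering
  convention; instruments or stains with different spectral behaviour
  may need an explicit cluster-to-population map (supported via
  `label_map`).
- The CO₂ estimate makes the carbon balance exact only for
  phosphoketolase-type fermentations; respiration or alternative sinks
  would require measured off-gas.
- FCS support covers the list-mode float subset this pipeline writes;
  integer or log-amplified FCS files from other acquisition software
  are out of scope.
- No statistical testing is performed; summaries are shaped for
  external tools (`compare_lipid_conditions()` emits the long format
  ANOVA-style tooling expects).
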