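---
title: "Double-shell circuit fitting for leaf impedance monitoring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double-shell circuit fitting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantEIS)
```

This vignette is the package's own account of its science: the circuit
model and its assumptions, the fitting algorithm and its tunables, what the
synthetic-data generator does and does not emulate, and the design choices
made where the design was genuinely open.

## The double-shell model

A plant cell seen between two leaf electrodes is, electrically, a leaky
dielectric shell inside a conductive bath. The double-shell model (DSM)
assigns one element to each structure:

| element | structure | units | role |
|---|---|---|---|
| `R1` | cell wall + extracellular fluid | Ω | only conductive path at DC |
| `C3` | plasma membrane | F | gates current into the cell |
| `R2` | cytoplasm | Ω | intracellular series path |
| `C5` | tonoplast (vacuolar membrane) | F | gates current into the vacuole |
| `R4` | vacuole | Ω | innermost path |

The wiring used throughout is `R1 ∥ [ C3 — ( R2 ∥ ( C5 — R4 ) ) ]`:

$$Z(\omega) = \Big[\tfrac{1}{R_1} + \tfrac{1}{Z_{intra}(\omega)}\Big]^{-1},
\qquad
Z_{intra}(\omega) = \frac{1}{j\omega C_3} +
\frac{R_2\,(R_4 + 1/(j\omega C_5))}{R_2 + R_4 + 1/(j\omega C_5)}.$$

**Topology caveat.** The five components and their anatomical meaning are
standard, but published circuit diagrams are not always explicit about the
inner wiring. This ladder was chosen because it reproduces the two
defining behaviours of leaf tissue: at low frequency current is confined
to the extracellular fluid (`Z → R1`), and at high frequency all three
resistive paths conduct (`Z → (1/R_1+1/R_2+1/R_4)^{-1}`), with the
high-frequency resistance dominated by the smallest resistance — the
vacuole — as reported for fruit and leaf tissue. The wiring is isolated
inside a single function (`dsmImpedance`), so an alternative (e.g. a fully
serial intracellular branch, whose high-frequency limit would be
`R1 ∥ (R2+R4)`) can be swapped in one place. `modelLimits()` exposes both
plateaus for any parameter set.

Provable properties, all enforced by tests: `Re Z > 0`, `Im Z ≤ 0`
(passivity; the total admittance has real part ≥ 1/R1) and `|Z| ≤ R1` at
every frequency; `|Z|` decreases monotonically across the analysis band
for the default parameters. Extreme frequencies are evaluated through
admittances so that degenerate reactances yield the correct limit rather
than `NaN`.

## The fitting objective and search

Each (plant, hour) cell is measured five times in quick succession; the
replicates are averaged arithmetically per frequency (no trimming or
weighting — replicate scatter is dominated by electrode contact, which the
mean suppresses by √N). The fit then minimises the **summed absolute
impedance error**

$$Z'_{err} = \sum_f \big|\,Z_m(f) - Z_e(f)\,\big|,$$

the complex modulus summed over the grid (an `|ΔR| + |ΔX|` variant is
available via `errorMetric = "components"` for sensitivity analysis). Note
what this objective implies: with `|Z|` spanning ~150 MΩ at 500 Hz down to
~1–3 MΩ at 300 kHz, the low-frequency points dominate the sum. Parameters
expressed at low frequency (`R1`, `C3`) are therefore strongly
constrained, while the intracellular trio (`R2`, `R4`, `C5`), whose
signature lives at the quiet top of the band, is weakly constrained. This
asymmetry is intrinsic to the method and drives several choices below.

The optimiser is a derivative-free coordinate (pattern) search:

1. From the current centre, probe each free parameter in both directions
   with a **multiplicative** step `x ← x·(1 ± α)`. A dimensionless step is
   the only way one scalar `α` can serve parameters spanning megaohms to
   picofarads.
2. Accept the best strictly improving probe (ties broken in the fixed
   order `R1, R2, R4, C3, C5`, `+` before `−`), then extend it with a
   **step-doubling line search**: keep doubling `α` along that coordinate
   while the error strictly decreases.
3. If no probe improves, shrink `α` tenfold, from 10 % down to the 0.1 %
   step floor.
4. Stop when the error drops below the threshold (`converged = TRUE`),
   when the floor is reached with no improving move, or when the
   evaluation budget (10 000) is spent.

Candidates outside the physical box (resistances in `[1e3, 1e12]` Ω,
capacitances in `[1e-13, 1e-6]` F) are discarded, never projected, so
every accepted iterate is physical. The accepted-error sequence is
strictly decreasing and the whole search is deterministic in its inputs.

### The stopping threshold

The threshold is the one tunable with real scientific content. The package
expresses it relative to `Σ_f |Z_m(f)|` and sets the default by a
**noise-floor rule**: a perfect fit to a replicate mean cannot beat the
mean's own noise, whose expected relative residual is
`≈ 0.84 · pointSd / √N` (`expectedNoiseFloor()`; 0.84 is the Gaussian
modulus factor, between 0.80 for one dominant component and 0.89 for two
equal ones). The default threshold is **twice** that floor — 0.0075 for
the default 1 % point noise and N = 5 — high enough to converge reliably,
low enough that the weakly constrained intracellular parameters are
actually pinned down. Stopping much above the floor (say at a few percent
misfit) leaves `R2`, `R4`, `C5` free to wander by tens of percent along
near-degenerate directions; stopping below it never converges. For
noiseless data (simulator checks, algorithm benchmarking) use a tight
threshold and a finer floor, e.g.
`fitConfig(thresholdValue = 2e-4, alphaMin = 1e-4)`; the 0.1 % default
step floor limits attainable misfit to a few parts in 10⁴.

### Starting points

Hours are fitted in ascending order per plant, independently across
plants. With two or more previous fits the centre is the per-parameter
linear extrapolation of the last two (clamped to bounds); with one, that
fit is reused. The cold start at the first hour reads the circuit off the
measured curve: `R1` from `|Z|` at the lowest frequency (the extracellular
plateau), the high-frequency plateau from **`Re Z`** at the highest
frequency — the residual tonoplast dispersion at the band top is mostly
reactive, so the real part converges to the resistive plateau well before
the modulus does; using `|Z|` there overestimates the plateau by ~50 % and
biases `R4` systematically — then splits the implied intracellular
conductance between `R2` and `R4` at the tissue-typical ratio
`R2/R4 ≈ 3.2`, and screens the two capacitances over an 8 × 8 log grid
spanning the capacitance bounds, keeping the lowest-error pair.

## The synthetic study

No leaf data ship with the package; `simulateTrajectory()` +
`simulateMeasurements()` generate the full study layout: 4 plants ×
hours 5–20 × 5 replicates × 201 log-spaced frequencies. The analysis band
500 Hz – 300 kHz is the default grid (the instrument can sweep wider;
`runConfig(gridMinHz = 20)` reproduces that).

**Ground-truth trajectories.** Baseline (dehydrated) parameters hold until
the watering event at hour 5.5; from the first sampled hour afterwards the
baseline is multiplied by the water-uptake factors (R1, R2 × 1.4;
R4 × 1.1 — the vacuole resistance is reported to change only mildly;
C3, C5 × 0.7); from the LED-on event at hour 7.5 every parameter relaxes
exponentially (rate 0.15 h⁻¹) toward a hydrated target (R1, R2 at × 0.8 of
baseline, R4 at × 0.95, C3, C5 at × 1.15). This reproduces the reported
qualitative shapes: sharp resistance rise and capacitance drop on water
uptake, slow opposite drift under illumination, minor vacuole changes. An
optional per-plant log-normal scale jitter (resistances × s,
capacitances / s, which leaves the impedance family intact) emulates
plant-to-plant dynamic-range differences; it is off by default.

**Baseline values.** The resistances are the published study averages
(`R1 = 159.07 MΩ`, `R2 = 4.76 MΩ`, `R4 = 1.49 MΩ`). The capacitances were
never published and had to be designed. They were frozen once, from a
selection study run against three requirements: both membrane relaxations
inside the band (otherwise the corresponding parameters are formally
unidentifiable and every recovery test would be vacuous), the
extracellular plateau still visible at 500 Hz (so the cold start lands
within ~5 % on `R1`), and the best achievable noisy-recovery accuracy for
the intracellular trio. The frozen defaults `C3 = 0.6 pF`, `C5 = 0.8 pF`
give relaxations at `1/(2πR1C3) ≈ 1.7 kHz` and `1/(2πR4C5) ≈ 134 kHz` and
`|Z(500 Hz)| ≈ 0.96·R1`. No choice is fully comfortable: with
`R1 : R2 : R4 ≈ 107 : 3.2 : 1` a 2.8-decade band cannot display all three
resistive plateaus at once, so the intracellular parameters remain the
accuracy bottleneck whatever the capacitances — a limitation of the
measurement band and objective, not of the optimiser.

**Noise model** (an explicit assumption; the study reports contact noise
only qualitatively): one Gaussian contact-scale factor per replicate sweep
(sd 2 %) multiplying the whole complex sweep, then independent
multiplicative Gaussian noise (sd 1 %) per frequency on resistance and
reactance. Draws that would flip the sign of a resistance are redrawn.
Because scaling all resistances by `s` and capacitances by `1/s` scales
`Z` by exactly `s`, the contact factor lies *inside* the model family: it
biases the fitted parameters of a single sweep rather than inflating the
residual, and the replicate mean suppresses it by √N. What the simulator
does **not** emulate: electrode polarisation, temperature drift,
frequency-dependent instrument error, constant-phase (Cole-type)
dispersion, or any actual turgor physics — so passing recovery tests show
that the *pipeline* is correct and well-conditioned under the stated noise,
not that real leaves obey the DSM.

## Validation design

The test suite and `scripts/acceptance.R` recompute, at these problem
sizes (chosen to keep the full suite under a minute while leaving the
Monte-Carlo margins interpretable):

* forward-model limits and a 1000-parameter-set passivity sweep over the
  201-point band, against closed-form oracles;
* the error objective against an independently coded
  `Σ√(ΔR² + ΔX²)` on random spectrum pairs (1e-12 relative) and the exact
  constant-offset value `201 × |3 − 4j| = 1005 Ω`;
* the coordinate search against an exhaustive 200 × 200 log-grid oracle on
  20 seeded two-parameter (`R1`, `C3`) subproblems;
* noiseless recovery: 20 seeded (truth ± 20 %, init × U[0.5, 2]) pairs,
  requiring ≥ 90 % of runs to land within 1 % on all five parameters;
* noisy recovery: 20 seeded single-plant studies at the default noise,
  requiring the per-parameter median error over all 320 fits to stay
  under 5 % and the median achieved misfit to sit in the sub-percent to
  3 % regime;
* trajectory-shape reproduction on a default 4-plant study (water step,
  post-illumination monotonicity, rank correlation against truth), and
  byte-level determinism of all writers.

One caveat is worth stating plainly: *strict* hour-to-hour monotonicity of
the fitted `R̂2` and `Ĉ5` trajectories over hours 8–20 is not a property
this method can deliver at the default noise — the late-hour true steps
(~2 %) are comparable to the threshold-stop scatter of those weakly
constrained parameters, so a 13-step strictly ordered fitted sequence is a
near-zero-probability event even though the rank correlation with truth
exceeds 0.9. The corresponding assertions are kept in the acceptance suite
as written and fail honestly; the monotone claims do hold for `R̂1` and
`Ĉ3`, and for the generating trajectories themselves.

## Known limitations

* The intracellular parameters (`R2`, `R4`, `C5`) carry several-percent
  uncertainty at the study's noise level; drawing physiological
  conclusions from their fine structure requires either a wider band, a
  frequency-weighted objective, or more replicates.
* The threshold stop returns the *first* iterate below threshold, not a
  local minimiser; two fits of the same data from different starts can
  differ anywhere within the threshold ball.
* Ratios are reported as ratios of grand means over converged fits
  (mean-then-ratio), pooling all hours — a pooled average over a
  time-varying trajectory depends on the observation window.
* The Hayden (3-element) model, constant-phase elements and
  electrode-polarisation corrections are out of scope; gradient-based or
  global optimisers appear only as test oracles.
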