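---
title: "Models and methods behind roscav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind roscav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roscav)
```

`roscav` quantifies the radical-scavenging capacity of small solutes in
in-vitro ROS model systems. This vignette documents the models, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data generator does and does not emulate.

## Endpoint inhibition and IC50

Endpoint assays (ABTS•⁺ at 734 nm, HOCl/TMB at 655 nm, superoxide/NBT at
560 nm, H₂O₂/TNB at 412 nm) report one absorbance per well. Percent
inhibition is taken against the replicate's own control (uninhibited, "100%
reaction") and reading blank:

$$\%In = 100 \cdot \frac{A_{control} - A_{sample}}{A_{control} - A_{blank}}$$

The statistic is affine-invariant in absorbance, so a shared optical offset
cancels. Raw values may leave \[0, 100\] (noise, or apparent pro-oxidant
behaviour); the raw value is retained for inspection and a clamped copy
feeds the fit, which both preserves information and stabilises the
nonlinear fit.

The IC50 is estimated from the clamped inhibition by a constrained
logistic with fixed floor 0 and ceiling 100 and free Hill slope,

$$I(c) = 100 \, \frac{c^h}{c^h + IC50^h}, \qquad h \ge 0.2,$$

fitted by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with box
constraints. Assay write-ups in this field rarely state their IC50
procedure, and plotted curves often look interpolation-like; we therefore
pair the parametric fit with a deterministic fallback — the lowest 50%
crossing of the isotonic-regression-smoothed mean curve, linearly
interpolated — used whenever the logistic fit fails to converge, and record
which method produced every estimate. Isotonic smoothing makes the
crossing unique under noise; taking the lowest crossing makes ties
deterministic.

Censoring: when the mean inhibition never reaches 50% at any tested
concentration, no number is reported at all — the result is `"> c_max"`
with a `censored` flag, mirroring the "no effect at the concentration used"
convention of published panels. A censored potency is a bound, not an
estimate, and downstream consumers (mixture design) refuse it explicitly.

Replicate summaries follow the customary "mean IC50 ± SEM": the curve is
fitted per replicate (triplicate for endpoint assays, duplicate for the
kinetic assay) and the SEM is `sd/sqrt(n)` across replicate estimates.
Published SEMs for such panels are sometimes implausibly small (e.g.
`92,100.00 ± 0.10`); the generating procedure behind those numbers is
unknowable from the outside, so the package makes no attempt to reproduce
printed SEMs — only means.

Starting values come from the interpolated crossing; the fit is bounded to
`h ∈ [0.2, 20]` and IC50 within six orders of magnitude of the tested
range. With fewer than three distinct concentrations the fit refuses
(insufficient data) rather than extrapolating.

## Competition kinetics (crocin bleaching)

Peroxyl radicals generated at a constant rate by AAPH thermolysis bleach
crocin (443 nm). With an antioxidant A present at concentration [A]
competing with crocin C,

$$v = v_0 \frac{k_c[C]}{k_c[C] + k_a[A]}
\quad\Longleftrightarrow\quad
\frac{v_0}{v} = 1 + \frac{k_a}{k_c}\frac{[A]}{[C]}.$$

`extract_rate()` takes the least-squares slope of absorbance vs time over a
window, by default 60–600 s: the decay turns linear after roughly one
minute of lag and monitoring runs ten minutes. The rate is kept in AU/s for
ratios (the extinction coefficient cancels) and converted to molar units
with crocin's ε = 13,726 M⁻¹cm⁻¹ for reporting. A flat or rising trace is
flagged non-bleaching rather than silently returning a negative rate.

The ka/kc slope comes from ordinary least squares of v₀/v on [A]/[C] with a
**free** intercept. The model predicts intercept 1; estimating it freely and
warning when it strays beyond ±0.2 exposes deviations (crocin consumption,
lag misestimation) that a constrained fit would hide. Individual constants
k₁, k₂ and [ROO•] are not identifiable from such data — only the products
kc = k₁[ROO•] and ka = k₂[ROO•], hence only their ratio — so absolute rate
scales live exclusively in the simulator configuration. Trolox equivalents
are the sample-to-Trolox slope ratio. Nominal initial concentrations are
used for [A]/[C]; crocin consumption during the window is flagged as a
caveat, not corrected.

The kinetic IC50 uses `%In = (1 − v/v₀) × 100` and the same IC50 machinery;
when the competition law holds exactly, `%In = 50` at `[A] = [C]/(ka/kc)`,
which the noise-free round-trip tests verify to below 0.1%. Ranking solutes
by slope then coincides with ranking by 1/IC50.

## Mixture design and the additivity index

Stocks are proportioned to individual IC50s: `stock_i = multiplier ×
IC50_i`, so any added volume V delivers the identical IC50 fraction
`f = multiplier · V / V_final` of every component (asserted to machine
precision). The additive reference is Loewe-type with a shared Hill slope:
50% effect when the Loewe sum `S = Σ c_i/IC50_i` equals 1. This is the
unique reference under which (i) an n-component IC50-proportioned mixture
reaches its IC50 with every component at 1/n of its own IC50, (ii) each
component's capture share is 50/n percentage points (12.5% for four
solutes, 25% for two), and (iii) the projected total concentration at the
mixture IC50 is the arithmetic mean of the individual IC50s — which is how
published binary projections such as (6.90 + 1125.81)/2 = 566.35 µmol/L
arise. The projection is generalised to n components as that mean.

The additivity index is observed/projected total at the mixture IC50.
Classification uses a band τ around 1 (default 0.10): within the band
additive, above sub-additive (antagonism: more total mass needed than
projected), below supra-additive. No standard threshold exists for this
assay family; τ = 0.10 is wide enough to absorb fit noise at the packaged
noise levels while cleanly separating the ~1.3–1.5 indices typical of
genuinely antagonistic peroxyl-radical mixtures, and it is configurable.

Report tables support two display conventions — round-half-up and
truncation to 2 dp — because published mixture tables demonstrably mix both
(4.4499 → 4.45 but 566.355 → 566.35). Raw values are never rounded
internally; the convention used is recorded in the output metadata together
with a hash of the generating configuration.

## The synthetic-data generator

The generator exists so that every analysis stage has a round-trip oracle:
noise-free simulations must invert exactly through the pipeline, and noisy
ones quantify estimator behaviour under known truth.

* **Endpoint plates**: `A = A_blank + (A_control − A_blank)(1 − f(c)) +
  N(0, σ)` with `f(c) = c^h/(c^h + IC50^h)`. Defaults: control 0.750 AU
  (the working start absorbance of an ABTS•⁺ dilution), blank 0, h = 1,
  σ = 0.005 AU, triplicates, eight log-spaced concentrations bracketing the
  true IC50 (≈11-fold either side). σ = 0.005 AU on a 0.750 AU span keeps
  triplicate IC50 SEMs of the same order as the smaller published SEMs.
* **Censored solutes** are simulated with a true IC50 of 100 × c_max rather
  than zero activity: "no effect at the concentrations used" is a bound,
  not a mechanism claim, and this choice makes the censoring machinery
  itself testable (the response is ≈1% at c_max).
* **Kinetic traces**: `A(t) = ε·path·[C] − v·max(0, t − t_lag) + N(0, σ)`,
  floored at blank, with `v = v₀/(1 + (ka/kc)[A]/[C])` and `v₀ = ε·path·
  R_g·kc_rel·[C]`. Defaults: 25 µmol/L crocin, ε = 13,726, t_lag 60 s,
  duration 600 s, 5 s sampling, σ = 0.002 AU, duplicates; the radical
  generation term R_g = 2.914 × 10⁻⁴ s⁻¹ puts v₀ near 10⁻⁴ AU/s, i.e. a
  ~17% absorbance decline over the run — a realistic bleaching depth.
* **Mixtures**: the capture fraction at Loewe sum S is
  `f = S^h / (λ^h + S^h)`. At λ = 1 and h = 1 this is the exactly-additive
  `S/(1+S)`; 50% capture falls at S = λ, so the fitted additivity index
  equals λ in the noise-free limit, and the response is strictly monotone
  in λ — a single antagonism dial that is exact at 1. The parameterization
  is recorded in the simulated plate's metadata. λ enters only the
  generator; the analysis never assumes it.

Determinism: every generator call seeds its own RNG stream and restores the
caller's, so identical seeds give bit-identical plates, traces and fixture
directories.

What the generator does **not** emulate: instrument drift, heteroscedastic
or non-Gaussian noise, plate-position effects, crocin depletion curvature,
pro-oxidant mechanisms, pH/temperature sensitivity, and real chemical
identities of interactions. Passing round-trip tests therefore demonstrates
that the estimators are correct for the stated statistical model, not that
the model captures every behaviour of a physical plate reader.

## Numerical and interface choices

* Concentrations are µmol/L throughout the analysis layer (reference serum
  levels are stored in mmol/L as conventionally printed and converted on
  request); volumes are µL; rates AU/s.
* Optical path defaults to 1 cm and is an explicit parameter of every
  Beer–Lambert conversion, since microplate effective paths depend on fill
  volume and are rarely reported.
* Blank correction precedes percent inhibition; kinetic reaction blanks
  (sample mixture without crocin) are subtracted point-wise when provided.
* Complete inhibition in kinetics (v = 0) yields an infinite velocity ratio
  carrying a `complete_inhibition` attribute; such points are excluded from
  slope regressions with a warning instead of being winsorised.
* Degenerate inputs fail loudly: control = blank, fewer than 3
  concentrations, fewer than 5 points in a rate window, zero x-range in the
  competition regression, censored IC50s offered to the mixture designer.

## Problem sizes in the test-suite

The statistical guarantees are exercised at sizes chosen to make sampling
statements stable while keeping the suite quick to run routinely: 200
simulated triplicate plates for IC50 recovery (median |bias| < 2%,
replicate-SEM interval coverage ≥ 90%), 50 random curves against a 10⁴-point
log-spaced grid-search oracle (agreement within 0.5%), 100 simulated
exactly-additive 4-solute mixtures (mean index within 1 ± 0.03, IC50
fractions within 0.25 ± 0.01), 60 censored-solute plates (≥ 95% flagged),
and 2,000 control wells for the noise-model check.

## Known limitations

* The logistic fit assumes a monotone response; strong pro-oxidant
  reversals at high concentration would need a biphasic model, which is out
  of scope.
* Kinetic IC50s inherit the nominal-concentration caveat of the competition
  treatment; slopes from duplicate noisy series carry sampling error of
  several percent at the default noise level.
* The additive projection (mean of IC50s) is specific to IC50-proportioned
  designs; it is not a general combination-index framework (no Bliss, ZIP
  or Chou–Talalay machinery).
* Censored results propagate as refusals, not as likelihood contributions;
  there is no censored-regression potency model.
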