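---
title: "Equivalent-circuit modelling and moisture estimation for drying tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent-circuit modelling and moisture estimation for drying tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eisdry)
```

## The model

Biological tissue carries alternating current through two parallel paths:
the extracellular fluid (resistive) and, at higher frequencies, through the
cells themselves, whose membranes behave as capacitors. The resulting
complex impedance `Z(ω)` falls from a low-frequency plateau (extracellular
path only) to a high-frequency plateau (membranes shorted, intra- and
extracellular paths in parallel) — the β-dispersion. A small lumped circuit
of resistors, capacitors and constant phase elements (CPEs) captures this:

* resistor: `Z = R`;
* capacitor: `Z = 1/(jωC)`;
* CPE: `Z = 1/(P·(jω)^n)` on the principal branch, i.e. modulus
  `1/(P·ω^n)` at constant phase `−n·90°`. The CPE interpolates between a
  resistor (`n → 0`, `Z → 1/P`) and a capacitor (`n = 1`, `C = P`), and is
  the standard description of the "depressed" (semi-elliptical) Nyquist
  arcs that real membranes produce.

Circuits are written as expressions (`-` series, `|` parallel, with `|`
binding tighter so `Re|(Ri-Cm)` reads naturally) and evaluated recursively:
series nodes sum impedances, parallel nodes sum admittances. Five models
are built in: Hayden, simplified Hayden, CPE-modified, double-shell, and a
two-relaxation series model `R1-(R2|CPE1)-(R3|C1)` (called `proposed`).

All built-ins are passive: with positive parameters, `Re(Z) > 0`,
`Im(Z) ≤ 0` (phase in `[−90°, 0°]`) and `|Z|` is non-increasing in
frequency. The test suite checks these properties on dense grids and checks
the evaluator against an independent brute-force complex-arithmetic oracle
on hundreds of random circuit trees.

### Sign conventions

The imaginary part is stored *signed* (`im_ohm ≤ 0` for capacitive
behaviour). The classical bioimpedance notation `Z = R − jX` treats the
reactance `X` as a magnitude; that `X` is `−im_ohm` here. Signed storage
keeps Nyquist plotting (`−Im(Z)` against `Re(Z)`) and fitting residuals
unambiguous. Whether instrument phase readings are signed or magnitudes
varies by vendor; files written by this package always carry signed values,
in degrees, alongside the cartesian pair.

### The proposed two-relaxation topology

For dehydration tracking the package defaults to
`R1-(R2|CPE1)-(R3|C1)`: a series access resistance plus two relaxation
blocks, one CPE-dispersive and one ideal. Two dispersive blocks are the
minimal structure that can outperform the single-arc CPE-modified model on
tissue whose arc is not a single depressed semicircle; the topology is a
package default, configurable through `parse_circuit()`, not a claim about
any particular published circuit. It has 6 free parameters (three
resistances, one capacitance, and the CPE pair).

## Fitting

`fit_model()` minimises the sum of squared residuals, where the residual
vector interleaves real and imaginary differences per frequency. Two
weightings exist:

* `modulus` (default): each Re/Im residual pair is divided by the measured
  `|Z|` at that frequency. This makes the objective scale-free across a
  spectrum spanning orders of magnitude and is the choice used throughout
  the package's own analyses.
* `unit`: raw ohm residuals, for users who want absolute-error fits.

The optimizer is Nelder–Mead simplex (via `stats::optim`), the standard
derivative-free choice for complex nonlinear least squares on small
circuits. Three numerical decisions matter:

1. **Log transform.** Resistances, capacitances and CPE factors are
   optimised as `log10` values and clipped to generous physical bounds
   (`R ∈ [1e-3, 1e9]` Ω, `C, P ∈ [1e-15, 1]`), which enforces positivity
   without penalty terms; CPE exponents are optimised directly and clipped
   into `(0, 1]`.
2. **Restart jitter.** The CNLS surface is multi-modal; `n_restarts = 4`
   additional starts (log-uniform factor in `[0.2, 5]` around the initial
   point, seeded and reproducible) guard against bad basins. The worked
   test cases show a start at the parameter bound edge being rescued by the
   restarts.
3. **Repeated passes.** A single Nelder–Mead simplex loses precision as it
   collapses; each start therefore launches fresh simplex passes from the
   current best vertex until the objective stops improving (relative
   threshold `xtol_rel`, default `1e-10`; per-pass convergence `ftol_rel`,
   default `1e-10`, tightened to `1e-15` where machine-precision recovery
   is wanted). On noiseless self-generated 27-point spectra this reaches
   objectives near `1e-30` and recovers parameters to `~1e-14` relative for
   the identifiable models.

Initial estimates, when not supplied, come from the spectrum geometry:
resistances are scaled so the model's low-frequency plateau matches the
measured one, then capacitances/CPE factors are scaled so the model's
`−Im(Z)` peak frequency lands on the measured peak (using
`ω_peak ≈ 1/(RC)`, with the CPE scaled by the frequency ratio to the power
`n`).

### Goodness of fit

`goodness_of_fit()` reports mean absolute and root-mean-squared percentage
errors separately for real and imaginary parts, each point relative to the
measured component: `mae_real_pct = (100/N)·Σ|ΔRe|/|Re_meas|`,
`rmse_real_pct = 100·sqrt(mean((ΔRe/Re_meas)²))`. These are undefined when
a measured component is exactly zero (e.g. a purely resistive spectrum has
`Im ≡ 0`), and the function refuses such input rather than silently
dropping points; `fit_model()` then returns the fit without metrics.
`compare_models()` tabulates the four metrics per model, best
`mae_real_pct` first.

### Identifiability

Not every classical circuit is identifiable from its own spectrum. The
4-parameter Hayden model has a bilinear impedance
`(A + jωB)/(C + jωD)`, which carries only three observable degrees of
freedom (`R₀ = A/C`, `R∞ = B/D`, `τ = D/C`); a one-parameter family of
`(Re, Rm, Ri, Cm)` values produces the identical spectrum, so fitted Hayden
parameters are not unique even at machine-zero objective — the historical
reason the simplified Hayden model exists. The package fits it anyway
(the *spectrum* is reproduced perfectly); users should interpret individual
Hayden parameters with care. The double-shell model is identifiable, but
only if both of its relaxations are observable: its default parameters are
chosen so the two time constants sit inside the 0.5–10 kHz measuring band
about a decade apart. With out-of-band time constants the 5-parameter fit
becomes numerically sloppy (flat objective directions), which is a property
of the data window, not of the optimizer.

## Moisture content and calibration

Moisture relative to solid content is `M = (m_t − s·m_o)/(s·m_o)` in g/g,
with the initial solid fraction `s` defaulting to 0.13 — the conventional
assumption for onion bulbs. The quantity is dry-basis-like and is never
converted to wet basis. Weights below the bone-dry estimate `s·m_o` give a
negative `M` with a warning rather than an error, since balance noise can
produce them.

Calibrations are ordinary least-squares polynomials (degree 1 or 2) of `M`
on either `|Z|` at a spot frequency or impedance per unit weight
`Zpu = |Z|/(m/1000)` (Ω/kg), with SSE, `R² = 1 − SSE/TSS` and
`RMSE = sqrt(SSE/N)`. `calibration_sweep()` fits one degree-1 calibration
per requested frequency, pooling all samples and days, matching requested
frequencies to the measured grid by nearest point within 1% relative
tolerance (grids differ between runs; silent mismatches would be worse than
a hard error). The per-unit-weight denominator is the *current-day* weight
`m_t`: normalisation "per unit weight" is read as compensating sample size
at measurement time. This is an assumption — initial weight is equally
defensible — and is trivially changed by passing different weights to
`impedance_per_unit_weight()`.

## The synthetic drying experiment

`simulate_drying()` stands in for an unpublished bench experiment. Its
defaults are the study conditions the package targets:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 10 | bulbs in the cohort |
| `n_days` | 21 | daily weighings/spectra, day 0–20 |
| `initial_weight_range_g` | 75–96 | uniform draw per sample |
| `solid_fraction` | 0.13 | initial solids |
| `drying_rate_per_day` | 0.01 | relative daily water loss |
| `truth_circuit` | `cpe_modified` | generating circuit |
| `frequencies` | 27 points, 0.5–10 kHz | log-spaced, containing 0.5/1.1/5/10 kHz |
| `noise_sd_rel` | 5e-4 | multiplicative noise on Re and Im |

The drying law is geometric — water mass `w(t) = w(0)·(1 − rate)^t` with
fixed solid mass — chosen for strict monotonicity and two-parameter
simplicity; at the default rate, `M` falls by a factor `0.99²⁰ ≈ 0.82` over
the study. The 1%/day rate is a realistic ambient-storage figure for bulbs
at ~20 °C and moderate humidity. The noise level mirrors a 0.05%-accuracy
LCR meter. The 27-point grid is log-spaced but guaranteed to contain the
four conventional analysis frequencies, since real spot-frequency lists are
chosen to include the frequencies later analysed.

Moisture drives the circuit through a per-parameter power law
`value(M) = base·(M/M₀)^b` with `M₀ = (1 − s)/s`: resistances use
`b = −1` (electrolyte resistance grows as water leaves), capacitances and
CPE factors `b = −0.5` (membrane disruption during drying *increases*
membrane capacitance), exponents `b = 0`. Under this map every `|Z|` rises
strictly as `M` falls, at every grid frequency — the qualitative signature
of the real experiment — and the map is fully configurable.

### What the simulator does and does not show

Passing end-to-end tests on simulated data demonstrates that the pipeline
is self-consistent (the fitter recovers the generator's parameters, the
weight log reproduces the truth moisture to 1e-12, calibrations find the
constructed relations), **not** that any particular circuit is the right
model for a given vegetable. Known gaps between simulator and reality:

* Circuit parameters depend on moisture only, not on sample size, so all
  samples share one impedance trajectory. Consequently the per-unit-weight
  normalisation — which in real data compensates size differences —
  *adds* scatter here (degree-2 Zpu calibrations reach R² ≈ 0.7 while
  per-frequency calibrations exceed 0.99). A size-aware map would need a
  geometry model the package deliberately does not include.
* Which spot frequency calibrates best is map-dependent: under the default
  map the high-frequency end (5–10 kHz) wins and 0.5 kHz ranks last, in
  line with the β-dispersion argument that high-frequency current samples
  the whole tissue, but the 5 kHz / 10 kHz ordering can swap between noise
  realisations. The package reports the ranking; it does not assert it.
* No temperature/humidity covariates, no rotting or sprouting, no
  electrode-polarization artefacts, frequency-independent noise.

## Problem sizes and runtimes

The shipped tests and the analysis script use the full default study
(10 × 21 records, 27-point spectra), 500 random circuits for the oracle
check, 20 noisy replicates for recovery statistics, and single-spectrum
model comparisons; the complete suite runs in a few minutes on one core.
Larger cohorts or denser grids scale linearly in records × frequencies.

## Limitations

* Only R, C and CPE elements: no Warburg, inductive or transmission-line
  elements, and no automatic topology search.
* Local optimisation with restarts; no global optimizer and no confidence
  intervals on circuit parameters.
* No Kramers–Kronig consistency checking of measured spectra.
* Calibrations are plain OLS — no robust or weighted variants — and, like
  all such calibrations, transfer poorly across varieties; refit per
  cultivar and storage condition.
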