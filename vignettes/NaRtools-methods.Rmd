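---
title: "Models and methods behind NaRtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind NaRtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NaRtools)
```

NaRtools analyzes the three assay families used to characterize
sodium-pumping rhodopsins: time-resolved flash-photolysis spectroscopy,
whole-cell electrophysiology plus pH-electrode pump assays, and
distance-based phylogenetics. This vignette documents the models, the
defaults and why they were chosen, the numerical decisions, and what the
synthetic-data generators do and do not emulate.

## The photocycle model and its simulator

After photon absorption a microbial rhodopsin traverses an ordered series of
spectroscopically distinct intermediates before thermally reverting to the
dark state. `PhotocycleModel` encodes this as a **linear, irreversible,
sequential chain** with one first-order rate constant per step; the last
step returns to the dark state. Branched or reversible schemes are
deliberately out of scope: the observed decay schemes for this protein
family are linear, and the sequential restriction keeps the kinetics exactly
solvable by the Bateman closed form, so the simulator introduces no
integration error. A consequence is that **duplicate rate constants are
rejected** rather than handled by the confluent (repeated-eigenvalue)
solution; callers hitting this edge perturb one rate by ~0.1%, which changes
the surface by far less than any realistic noise floor.

Each state absorbs as a Gaussian band (center nm, width nm, relative
amplitude). The simulated observable is

$$\Delta A(\lambda, t) = \sum_i c_i(t)\,[\varepsilon_i(\lambda) -
\varepsilon_{dark}(\lambda)],$$

which automatically contains the ground-state bleach: molecules residing in
intermediate $i$ no longer absorb as dark pigment. Mass conservation
($\sum_i c_i + c_{recovered} = f$, the excited fraction) holds to 1e−10 in
the tests, and $\Delta A \to 0$ at long times because the model always
recovers fully.

Defaults mirror the acquisition conditions of multichannel flash photolysis
of NaRs: probe grid 360–710 nm in 10-nm steps (36 channels) and 200
log-spaced delays from 1 µs to 10 s, which keeps ≥ 10 points per decade
around every lifetime between the fastest (tens of µs, K decay) and slowest
(~1.5 s) constants encountered. Noise is i.i.d. Gaussian and homoscedastic
across wavelengths and delays — the simplest model consistent with
photomultiplier detection dominated by shot noise, and the assumption under
which the global fit weights all residuals equally.

The **photolyzed fraction** under a typical excitation flash is not
identifiable from the surface shape (it only scales the amplitudes), and no
measured value is available; the default of 0.1 is a representative choice
for moderate flash energies and is documented here once. The preset models
(`kr2PhotocycleModel()`, `fdnarPhotocycleModel()`, `srnarPhotocycleModel()`)
fix the lifetimes at the published fitted constants (26 µs / 1 ms / 7.9 ms /
112 ms; 40 µs / 1.63 ms / 15 ms / 55 ms; 590 ms / 1540 ms); band centers and
widths are representative of the family (blue-shifted M near 400–430 nm,
red-shifted K/O near 590–600 nm, dark maxima at 525 and 550 nm) since only
the lifetimes are constrained by the measurements being emulated.

The excited-fraction validity range is [0, 1] rather than (0, 1]: a zero
fraction produces an identically zero surface, which is useful as a null
control for model-order selection and costs nothing in safety.

## Global fitting by variable projection

The fitted model is
$\Delta A(\lambda,t) = \sum_{i=1}^{n} \mathrm{DAS}_i(\lambda) e^{-t/\tau_i}
+ \mathrm{offset}(\lambda)$.
For a *sequential* scheme with distinct rates the kinetics are a linear
combination of exactly the exponentials $e^{-k_i t}$, so the fitted
$\{\tau_i\}$ are the reciprocal rate constants and multi-exponential fitting
is exact, not approximate, on noiseless sequential surfaces.

Numerical design:

- **Separable least squares.** For fixed $\{\tau_i\}$ the amplitudes are
  linear; they are solved exactly per wavelength by QR, and only
  $\log_{10}\tau$ is searched nonlinearly (`nlminb`, PORT). This is the
  standard, numerically stable formulation for this model class — the
  nonlinear problem has $n$ dimensions instead of $n + n\cdot n_\lambda$.
- **Deterministic multistart.** Seeds are drawn from a fixed grid of 8
  points per decade of the time span. Models are grown greedily: the
  $n$-component starts augment the best $(n-1)$-component solution with each
  grid point (plus one evenly spaced start); the best few initial candidates
  are refined and the lowest RSS wins. The procedure involves no randomness,
  so fits are bit-reproducible.
- **Bounds and ties.** $\log_{10}\tau$ is bounded two decades beyond the
  time span; coincident trial taus are rejected inside the objective
  (infinite RSS) so the linear solve never sees a singular design. Recovered
  components are always reported in ascending $\tau$, making results
  invariant to the optimizer's path.
- **Offset term.** Included by default to absorb any non-decaying baseline
  (e.g. a permanently bleached photoproduct); disable with
  `fitOffset = FALSE`. On fully recovering synthetic surfaces it fits to ~0.
- **Model order by BIC.** The source measurements fix the number of
  exponentials per protein without stating a criterion; `selectComponents()`
  makes that choice explicit with BIC under i.i.d. Gaussian residuals,
  including an $n = 0$ (offset-only) null model so that pure-noise surfaces
  select "no kinetics".

Whether a biexponential decay of a late red-shifted state reflects two
sequential O states or a biexponential relaxation of one state cannot be
decided by the fit; the fitting layer only reports exponentials, and the
interpretation is left to the assignment layer.

`fitTraceMultiexp()` is the single-channel analog used for photocurrent
off-kinetics. Identifiability is checked: a near-zero amplitude or a
time constant at the search bound (e.g. fitting one exponential to a
constant trace) is flagged and warned about rather than silently reported.

## Photocycle assignment and turnover

`assignIntermediates()` labels each component from the positive lobe of its
DAS relative to the dark-state maximum: a blue shift beyond 60 nm is L/M (M
absorbs near 400 nm against dark pigments at 520–550 nm); red-shifted
components split into K below 1 ms and O at or above it. Both thresholds
come from classic microbial-rhodopsin spectroscopy rather than from any
single dataset, and both are arguments with the defaults stated. A DAS
peaking exactly at the dark maximum (or lacking a positive lobe — typical
for the dark-recovery component, whose DAS mirrors the bleach) is left
unassigned with a warning rather than forced into a category.

Cycle time is defined operationally as the **sum of the fitted sequential
lifetimes** — the measurements being reproduced give no operational
definition, and for an irreversible chain this is the mean first-passage
time back to the dark state. Turnover is 60/cycle time per minute, so a 15-s
photocycle is exactly 4 ions/min. Note one deliberate non-reconciliation:
for the slow SrNaR pump the fitted constants sum to ~2.13 s (≈ 28 min⁻¹)
while the turnover argument quoted for it corresponds to a ~15-s cycle. The
package surfaces both numbers and encodes no guess about the missing factor
(e.g. photon-absorption-limited cycling at finite light intensity).

## Electrophysiology metrics

The photocurrent simulator uses the canonical pump-current shape: during
light, a transient peak inactivating exponentially to a steady state; after
light-off, mono-exponential relaxation to baseline (~10 ms class constants).
Outward pump current is positive everywhere in the package. Epoch
contributions superpose, so pulse trains are supported, and per-epoch peak
amplitudes may vary — which is how adaptation experiments are emulated.

Metric definitions the source leaves qualitative are made explicit and
configurable:

- steady state = mean over the **last 20%** of the light epoch;
- baseline = pre-light mean, subtracted before any metric (all metrics are
  invariant to a constant baseline);
- off-kinetics from a 1-exponential fit to the post-light segment;
- I–V by OLS, flagged voltage-insensitive when |slope| < 0.02 pA/mV (about
  5% of typical fitted slopes);
- action-spectrum peak by parabolic interpolation through the maximum and
  its neighbours — adequate for band-like spectra on a 10-nm grid, and the
  reason a 520 vs 550 nm pair resolves a 30-nm shift well within half the
  grid spacing; edge maxima are returned un-interpolated with a warning;
- light saturation by `nls` on $I = I_{max} P/(P + P_{1/2})$;
- spikes as upward threshold crossings (−20 mV default) with a 2-ms
  refractory lockout; silencing efficacy as the first-spike latency shift T
  and the change in evoked spike count.

Input traces are assumed leak-subtracted and series-resistance compensated
upstream; no equal-photon-flux conversion is applied to action spectra
(the emulated experiments normalize at equal power).

## Pump-assay classification

The pH-electrode assay is classified from the drift-corrected slope over the
first 30 s of illumination: below −3 standard errors is H⁺ export
(acidification), above +3 SE is Na⁺-export alkalinization (secondary proton
uptake), otherwise none. The 30-s window and the 3σ rule turn a qualitative
trace-shape judgement into a testable statistic. Drift correction subtracts
the pre-illumination OLS slope, which by linearity makes the classification
exactly invariant to constant offsets and to linear baseline drift. With a
paired CCCP trace the slope ratio is reported; the generator's CCCP factor
(default 2) multiplies the alkalinization slope of a Na⁺ pump and divides
the acidification slope of an H⁺ pump. No conversion of ΔpH to absolute ion
flux is attempted — that requires buffer capacity and cell counts that the
assay as emulated does not provide.

## Phylogenetics

The tree methodology is re-implemented rather than delegated: p-distances
with **pairwise deletion** of gapped columns (complete deletion available as
a flag — the emulated workflow removes poorly aligned loop regions before
alignment, making pairwise deletion the natural default), the Poisson
correction $d = -\ln(1-p)$ under the uniform-rate, equal-exchange model (no
gamma rate variation, matching the stated method), and Saitou–Nei
neighbor-joining with:

- deterministic tie-breaking (lowest index pair in the Q-matrix);
- negative branch-length estimates clamped to 0 (the MEGA-compatible
  convention), raw values retained in an attribute;
- an exactness guarantee: on additive matrices the output tree's path-length
  matrix reproduces the input, which the tests verify on random trees, and
  the topology is cross-checked against an independent NJ implementation.

Bootstrap supports resample alignment columns with replacement, rebuild the
full chain per replicate, and report for each internal edge of the
**full-data tree** the percentage of replicates containing the same
bipartition (mapping to the full-data tree, not a consensus — stated here as
this package's choice, since the emulated analysis does not say which it
used). Saturated distances (p ≥ 0.99) warn; p ≥ 1 is an error, and bootstrap
replicates that hit saturation are skipped rather than crashing the run. The
default of 1000 replicates matches the emulated analysis.

The alignment simulator evolves sites independently along a known tree:
substitution events are Poisson with intensity equal to the branch length
(substitutions/site) and each event picks uniformly among the 19 alternative
residues, so two sequences at distance $d$ differ at an expected fraction
$p = \tfrac{19}{20}(1 - e^{-20d/19})$ — precisely the model the Poisson
correction inverts, which makes generator and estimator mutually consistent
and the whole chain testable against closed forms.

## What the generators do not emulate

Passing tests on synthetic data show the *analysis* is correct under the
stated models; they do not certify performance on real recordings. The
simulators omit: instrument response (laser pulse width, monochromator
bandwidth, electrode response times), wavelength-dependent noise,
spectrotemporal artifacts, reversible or branched photocycles, leak currents
and series-resistance errors, buffer-capacity nonlinearity of pH traces,
among-site rate variation and non-uniform amino-acid exchangeabilities.
Real-data entry points (`readSurfaceCSV`/`readSurfaceTSV`, `readTraceCSV`,
`readAlignmentFasta`) accept measured data in plain formats, and all metric
functions are generator-agnostic.

## Problem sizes and runtime

The default surface (36 × 200) global-fits in well under a second per model
order; the test suite and the acceptance script use these defaults
unchanged, with bootstrap sizes of 50–200 replicates in unit tests (the
1000-replicate default is exercised where supports are the quantity under
test at small alignments). The sizes are stated here as the package's test
conditions so results are interpretable, and they match the acquisition
grids of the emulated experiments.
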