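# NaRtools

Analysis toolkit for the functional characterization of light-driven
sodium-pumping rhodopsins (NaRs) — microbial retinal proteins that use a
photon to move a Na⁺ ion (or, without sodium, a proton) out of the cell.
Their function is probed with three very different assays, and this package
implements the computational side of all three, together with synthetic-data
generators carrying known ground truth so every stage can be validated
end-to-end:

- **Flash-photolysis spectroscopy.** After a laser flash the pigment cycles
  through spectrally distinct intermediates (K → L/M → O → dark). The
  transient absorption surface ΔA(λ, t) is fitted globally with a shared set
  of exponentials,

  ΔA(λ, t) = Σᵢ DASᵢ(λ) · exp(−t/τᵢ) + offset(λ),

  by **variable projection**: for any trial {τᵢ} the decay-associated
  spectra (DAS) are solved exactly by linear least squares, so the nonlinear
  search runs over log τ only. Model order is chosen by BIC, intermediates
  are labelled from their DAS signatures, and the photocycle time Σᵢτᵢ sets
  the maximal pump turnover 60/Στ per minute.
- **Electrophysiology and pump assays.** Peak and steady-state photocurrents,
  inactivation ratio, the ~10 ms light-off relaxation constant, I–V slope,
  action-spectrum peak (parabolic interpolation on the 10-nm grid),
  light-saturation hyperbola, pulse-train adaptation, spike detection and
  optical-silencing metrics, and pH-electrode pump-assay classification
  (H⁺ export / Na⁺ export / none, with ±CCCP slope ratios).
- **Phylogenetics.** Amino-acid p-distances (pairwise deletion), the Poisson
  correction d = −ln(1 − p), a from-scratch neighbor-joining implementation
  with deterministic tie-breaking, and nonparametric bootstrap supports
  (1000 replicates by default) mapped onto the full-data tree, with Newick
  and PHYLIP square-matrix I/O.

## Worked example

Simulate the slow biexponential photocycle of the *Salinarimonas rosea* pump
(SrNaR) and recover its lifetimes by global fitting:

```r
library(NaRtools)

surf <- simulatePhotocycle(srnarPhotocycleModel())
surf
#> TransientAbsorptionSurface: 36 wavelengths x 200 times
#>   lambda 360-710 nm; t 1e-06-10 s; noise sd 0

fit <- fitGlobal(surf, 2)
round(taus(fit), 4)
#> [1] 0.59 1.54

ct <- cycleTurnover(taus(fit))
sprintf("cycle time %.2f s -> %.1f ions/min", ct$cycleTime, ct$turnoverPerMin)
#> "cycle time 2.13 s -> 28.2 ions/min"
```

The two recovered time constants (590 ms and 1540 ms) are the generating
L/M-decay lifetimes; their sum is the photocycle time and bounds the pump at
~28 ions per minute — orders of magnitude slower than KR2-class pumps, which
is why SrNaR photocurrents show a sharp transient that inactivates almost
completely. The same fit on a KR2-like four-intermediate surface labels the
components from their DAS:

```r
kfit <- fitGlobal(simulatePhotocycle(kr2PhotocycleModel()), 4)
assignIntermediates(kfit, darkLambdaMax = 525)
#> PhotocycleAssignment: K -> L/M -> O -> O -> dark
#>   O detected: TRUE; cycle time 0.1209 s; turnover 496.2 min^-1
```

A configurable multi-stage pipeline (`runPipeline()`, with a thin CLI at
`inst/exec/nartools.R`) chains simulation → global fit → photocycle
assignment (or the ephys/pump/phylo stages) and writes a checksummed
manifest for reproducibility.

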