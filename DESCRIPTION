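Package: NaRtools
Title: Photocycle Kinetics, Photocurrent Metrics and Phylogenetics for
    Sodium-Pumping Rhodopsins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for the functional characterization of
    light-driven sodium-pumping rhodopsins (NaRs). Simulates and globally
    fits flash-photolysis transient-absorption surfaces with
    variable-projection multi-exponential models and decay-associated
    spectra, assigns photocycle intermediates (K, L/M, O) and computes
    cycle time and turnover, quantifies whole-cell photocurrent and
    pH-electrode pump-assay traces (peak and steady-state currents,
    off-kinetics, I-V slope, action-spectrum peak, light saturation,
    pulse-train adaptation, spike silencing, transport-mode
    classification), and reconstructs neighbor-joining phylogenies from
    Poisson-corrected amino-acid distances with nonparametric bootstrap
    supports. A synthetic-data module generates every pipeline input with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
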