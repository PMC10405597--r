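Package: saxsensemble
Title: Ensemble Modelling of Flexible Proteins Against SAXS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconciles predicted protein structures carrying per-residue
    confidence estimates (AlphaFold pLDDT convention) with experimental
    small-angle X-ray scattering (SAXS) data. Generates conformer pools by
    torsion-angle Monte Carlo over user-selected or automatically proposed
    low-confidence segments, computes contrast-weighted pair-distance
    distributions P(r) and Debye-equation intensities I(q) from dry atomic
    models, performs Guinier and regularized indirect Fourier transform
    analysis of experimental profiles with a standardized dmax selection
    rule, and selects non-negative least-squares weighted ensembles against
    P(r) or I(q) targets with full ensemble statistics (rms <Rg>, <dmax>,
    maximum dmax with its population fraction) and chi-square fit
    diagnostics. A synthetic-data module provides pseudo-atomic flexible
    proteins and simulated experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
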