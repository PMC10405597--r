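---
title: "Ensemble modelling of flexible proteins against SAXS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble modelling of flexible proteins against SAXS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsensemble)
```

## The problem

Structure predictors emit a single static model with a per-residue
confidence score (pLDDT, stored in the B-factor column). Proteins with
flexible linkers between folded domains are not single structures in
solution: small-angle X-ray scattering (SAXS) measures the ensemble
average, and for such proteins the predicted profile can disagree sharply
with experiment even when every folded domain is predicted well.

`saxsensemble` reconciles the two. Low-confidence segments are treated as
potentially flexible; conformational space is expanded by torsion-angle
Monte Carlo over those segments; each conformer's pair-distance
distribution P(r) and scattering intensity I(q) are computed from the dry
structure; and a non-negative least-squares (NNLS) fit selects a weighted
ensemble that reproduces the experimental P(r) or I(q). The result is a
small set of conformers with population fractions, an ensemble
root-mean-square radius of gyration ⟨Rg⟩ = sqrt(Σ fᵢ Rgᵢ²), a
fraction-weighted ⟨dmax⟩, and the largest member dmax with its fraction,
plus χ² diagnostics against the measured data.

## The model, piece by piece

### Contrast-weighted P(r) and I(q) from dry structures

Every heavy atom is a united atomic group: implicit hydrogens contribute
their electrons to the parent atom (predicted models carry no hydrogens,
so no placement step is needed). A group with `b` electrons and radius `r`
displaces solvent worth `b0 = 10 (r / 1.93)³` electrons — ten electrons
per water molecule, scaled by the group volume relative to a bulk water of
radius 1.93 Å. All scattering quantities use the effective contrast
`w = b − b0`.

P(r) is the histogram, on a 1 Å grid, of `wᵢ wⱼ` over all ordered pairs
i ≠ j; a distance falls in bin `floor(r/Δr)` and bins are reported at
centers `(k + 0.5) Δr`. Self terms are excluded (P(0) = 0, as indirect
transform conventions assume) and kept separately so that
`pr_to_iq()` can restore them analytically; the bookkeeping identity
`Σ p = (Σw)² − Σw²` holds exactly and is tested. Each bin also records the
contrast-weighted mean distance of its pairs, which the intensity
transform uses in place of the bin center — an isolated atom pair is then
reproduced exactly, and the transform agrees with the direct Debye double
sum to well under 0.5% at 0.1 Å bins for q ≤ 0.5 Å⁻¹.

`debye_iq()` evaluates `I(q) = Σ wᵢ² + Σᵢ≠ⱼ wᵢwⱼ sin(q rᵢⱼ)/(q rᵢⱼ)`
directly. No hydration layer is modelled anywhere: profiles are computed
on the dry structure. For real proteins the hydration contribution shifts
P(r) by roughly one ångström; that is small compared with the
conformational differences this package targets, but it is a known,
deliberate omission, and absolute χ² values against real data inherit it.

The group electron counts and radii ship as a versioned text table
(`inst/extdata/scattering_groups.tsv`). The exact table used by reference
hydrodynamics software is not public; ours is a documented substitute with
standard united-atom assignments, and everything downstream treats it as
replaceable input.

### Flexible segments and the Monte Carlo sampler

`suggest_flexible_segments()` proposes maximal runs of at least
`min_length` residues with pLDDT below a threshold (default 60). The
suggestion is advisory; an explicit segment specification always wins.

`sample_pool()` perturbs, per trial, one backbone dihedral (φ or ψ; the
virtual-bond pseudo-dihedral for single-bead chains) of one residue drawn
uniformly from the flexible segments, by a uniform angle within
±`max_step_deg` (default 30°). All atoms C-terminal of the rotated bond
move rigidly, so bond lengths and angles are untouched and rigid-domain
internal geometry is preserved to machine precision. A trial is accepted
iff it is clash-free: no non-bonded pair (1-2 and 1-3 neighbours excluded)
closer than `overlap_fraction` (default 0.8, because united-atom radii are
inflated relative to van der Waals) times the sum of group radii. There is
no energy function and no Ramachandran filter — clash rejection only, a
documented simplification relative to samplers that restrict torsions to
allowed regions. Accepted conformers accumulate from the current
structure, i.e. the pool is a random walk in torsion space; runs are
bit-reproducible from the seed.

`subselect_pool()` keeps the last conformer of each complete stride block
(`floor(n/stride)` models), and `compare_rg_distributions()` quantifies
how representative the thinned pool is via the maximum per-bin difference
of density-normalized Rg histograms.

### Experimental data: Guinier, IFT, and the dmax rule

`guinier_fit()` fits ln I against q² over the widest window with
q·Rg ≤ `max_qrg`, iterating the window from the fitted Rg to
self-consistency because Rg is unknown a priori. On noise-free Guinier-law
data it is exact to relative 1e-6 for any `max_qrg` ≤ 1.3.

`ift()` inverts I(q) to P(r) as a non-negative 1 Å histogram on
[0, dmax] with P(0) = P(dmax) = 0, by σ-weighted least squares with a
second-difference smoothness penalty α. The system is solved in
scale-normalized form so the estimate is exactly linear in the data and α
has a data-independent meaning. When α is not given it is chosen by the
discrepancy principle — the largest α with fit χ² ≤ 1, falling back to
the smoothest solution within 20% of the best attainable χ². On
noise-free sphere data the recovered Rg is within 1% of √(3/5)·R and the
P(r) shape within 2% of the closed form r²(1 − 1.5x + 0.5x³).

`select_dmax()` implements a standardized maximum-dimension rule: scan
candidate dmax on a 2 Å grid and pick the smallest for which *releasing*
the P(dmax) = 0 constraint leaves the endpoint below 1% (configurable) of
the P(r) peak — i.e. the constraint is not doing any work. The scan warns
if it extends beyond π/q_min, the largest dimension the data can
characterize; `data_quality()` reports that limit and the number of
Guinier-region points.

An optional flat non-negative background column (`fit_background`) absorbs
q-independent terms. It exists because coarse bead models (below) carry a
constant self-scattering of order 1% of I(0) that a pure P(r) transform
cannot represent; it is off by default for real atomic data.

### NNLS ensemble selection

`nnls_solve()` is a Lawson–Hanson active-set solver for
min ‖Ax − b‖₂ subject to x ≥ 0, written here because it is the core
fitting engine; its KKT optimality is asserted in tests and it is
cross-checked against an independent implementation. Columns of A are the
pool profiles on the target grid, b the experimental target, and optional
row weights 1/σ implement error weighting. `fit_ensemble()` drops members
below 1e-8 of the largest coefficient (numerical dust), renormalizes
fractions to sum 1, and reports the composite profile and χ².

Two behaviours deserve emphasis. First, smooth scattering profiles make A
severely rank-deficient — the information content of I(q) is roughly
dmax·q_max/π Shannon channels, an order of magnitude fewer than a typical
pool size — so the *support* of an NNLS solution is not unique even at
zero noise: different member subsets can compose the same curve. The fit
(composite, χ², ⟨Rg⟩, ⟨dmax⟩) is well determined; individual member
identities are not. Consequently the package's recovery tests score
ensembles at the component level: each selected member is attributed to
the nearest ground-truth component in normalized profile space and
fractions are summed, the same aggregation a practitioner applies when
reading clustered Rg histograms. Second, error weighting of P(r) targets
down-weights the long-r tail, where indirect-transform errors are largest,
and systematically under-selects extended conformers; P(r) fits therefore
default to no error weighting, with weighting available as a flag for the
comparison.

`scale_and_chi2()` scales a model curve onto experiment with the closed
form c = Σ(I_m I_e/σ²)/Σ(I_m²/σ²) and reports
χ² = Σ((cI_m − I_e)/σ)²/(N−1) — one degree of freedom spent on the scale;
the denominator is a package convention, stated here because absolute χ²
on oversampled grids is optimistic anyway (experimental I(q) is never
rebinned before fitting). `refit_union()` pools the members selected by
any earlier fit, plus extra models such as the unmodified starting
structure, and refits against I(q); nesting guarantees its residual never
exceeds the parts'.

## The synthetic-data module

`make_flexible_model()` emulates the target class of systems: compact
folded domains joined by extended flexible linkers. It is pseudo-atomic —
one bead per residue at the Cα position, fixed 3.8 Å virtual bonds,
self-avoiding compact domains (5 Å minimum non-neighbour separation,
compatible with the default clash criterion) grown inside spheres whose
volume allots ~115 Å³ per residue, and linkers grown as directionally
biased extended walks. Confidence is 90 in domains and 30 in linkers, so
segment suggestion exercises the same code path as real predicted
structures. Beads carry 54 electrons (an average residue) with a 3 Å group
radius. Using beads keeps Monte Carlo and Debye stages fast while running
identical code to the all-atom case; what the bead model does *not*
emulate is side-chain packing, real secondary structure, hydration, or
beamline error structure, so passing tests demonstrate the machinery and
its statistics, not atomic-level realism.

`simulate_experiment()` composes the ensemble-average intensity of chosen
pool members, adds Gaussian noise with σ(q) = rel·I(q) + floor (default
2% relative — typical of good modern data at low-to-mid q), stores the
generating σ as the error column, and returns the noise-free composite
P(r) as ground truth.

One caveat found while validating the round trip simulate → `ift()` →
`fit_ensemble()`: the IFT's smoothness regularization biases the P(r)
target by an amount comparable to the differences between pool members,
so component fractions recovered through an IFT are coarse (±0.15 here)
even though ensemble observables (⟨Rg⟩ to 2%) and direct-target recovery
(±0.05) are solid. This mirrors the known practical advice to check any
real-space ensemble fit against the measured I(q).

## Study sizes and numerical choices

The shipped tests and the acceptance script use a two-domain, ~80-residue
bead protein, pools of 1600 trials thinned to 300 representative members,
q from 0.0025 to 0.5 Å⁻¹, and ten noise seeds per recovery experiment —
sizes chosen so the whole study reruns in a couple of minutes on one core
while keeping every statistical claim testable. Monte Carlo acceptance for
this system runs near 98% (bead chains with purely steric rejection are
permissive; all-atom proteins reject far more). Other defaults: 1 Å P(r)
bins; 30° maximum dihedral step; overlap fraction 0.8; Guinier windows at
qRg ≤ 1.0–1.3 with a parasitic-scattering skip count; dmax scan step 2 Å
with a 1% released-endpoint threshold. Degenerate inputs (empty segments,
all-zero contrast, stride larger than the pool, extrapolating
interpolation, negative σ) raise immediate, specific errors.

## Limitations

Dry-structure profiles only (no hydration shell); single chains; no
side-chain sampling; no Ramachandran restriction; no Bayesian IFT or
posterior weight uncertainty; member-level NNLS weights are not unique and
should be read through clusters, not identities. Real-data absolute χ²
depends on error estimates that vary between processing pipelines by large
factors; comparisons should be made between fits to the same data, not
across datasets.
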