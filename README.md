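# saxsensemble

Ensemble modelling of flexible proteins against small-angle X-ray
scattering (SAXS) data, starting from predicted structures that carry
per-residue confidence (AlphaFold pLDDT convention).

A single predicted structure cannot represent a protein whose folded
domains are connected by flexible linkers: solution SAXS measures the
time- and ensemble-averaged scattering, and for such proteins the
predicted profile often disagrees sharply with experiment. This package
implements a rapid real- and reciprocal-space ensemble method for
structural biologists facing exactly that disagreement:

1. **Assess** the unmodified structure: Guinier analysis of the data
   (`guinier_fit`), data-quality checks against the π/q_min sampling limit
   (`data_quality`), regularized indirect Fourier transform with a
   standardized dmax selection rule (`ift`, `select_dmax`), and a scaled
   χ² of the predicted intensity against experiment (`scale_and_chi2`).
2. **Expand** conformational space: low-confidence segments
   (`suggest_flexible_segments`) are sampled by torsion-angle Monte Carlo
   with steric-clash rejection (`sample_pool`), thinned by a
   sub-selection stride (`subselect_pool`), and verified representative
   via Rg-histogram comparison (`compare_rg_distributions`).
3. **Compute** per-conformer profiles on the dry structures: the
   contrast-weighted pair-distance distribution P(r) (`compute_pr`), with
   united-atom contrasts `w = b − b0` and solvent displacement
   `b0 = 10 (r/1.93 Å)³`, and the Debye-equation intensity (`debye_iq`)

   I(q) = Σᵢ wᵢ² + Σᵢ≠ⱼ wᵢwⱼ sin(q rᵢⱼ)/(q rᵢⱼ).

4. **Select** an ensemble by non-negative least squares
   (`nnls_solve`, `fit_ensemble`): minimize ‖Ax − b‖₂ subject to x ≥ 0,
   where the columns of A are pool profiles and b is the experimental
   P(r) or I(q); fractions, composite profile, χ²,
   ⟨Rg⟩ = sqrt(Σ fᵢRgᵢ²), ⟨dmax⟩ and the maximum member dmax with its
   fraction are reported (`ensemble_stats`), and the union of all
   selected members is refitted against I(q) (`refit_union`).

A synthetic-data module (`make_flexible_model`, `simulate_experiment`)
generates pseudo-atomic multi-domain proteins and simulated experiments
with known ground truth, so the entire pipeline is testable offline.

## Worked example

A two-domain protein with a ten-residue flexible linker, a simulated
three-component experiment (50/30/20% mixture of compact, intermediate
and extended conformers, 2% noise), and the full pipeline:

```r
library(saxsensemble)

model <- make_flexible_model(n_domains = 2, linker_length = 10, seed = 3)
model
#> <protein_model> synthetic_2x82: 82 residues, 82 atoms [scattering factors assigned]
suggest_flexible_segments(model)
#> <segment_spec> 37-46

pool <- sample_pool(model, suggest_flexible_segments(model),
                    n_trials = 1600, seed = 11)
sub  <- subselect_pool(pool, 5)
q    <- seq(0.0025, 0.5, by = 0.0025)
sim  <- simulate_experiment(sub, c(30L, 180L, 300L), c(0.5, 0.3, 0.2),
                            q, noise_rel = 0.02, seed = 7)

cfg <- run_config(n_trials = 1600, stride = 5, seed = 11, max_qrg = 1.0)
run_pipeline(cfg, model = model, iq = sim$iq, pr_target = sim$pr_truth)
#> <run_report>
#>   baseline: chi2 10.79, Rg 20.1 Å, dmax 52 Å
#>   pool: 1587 accepted / 1600 trials, 317 selected
#>   fit_pr: chi2 8.696e-23, 3 members, <Rg> 20.5 Å, <dmax> 55 Å, max dmax 59 Å (20%)
#>   fit_iq: chi2 0.8725, 9 members, <Rg> 20.6 Å, <dmax> 55 Å, max dmax 59 Å (25%)
#>   fit_union: chi2 0.8725, 9 members, <Rg> 20.6 Å, <dmax> 55 Å, max dmax 59 Å (25%)
```

Reading the report: the single starting structure fits the heterogeneous
"experiment" at χ² ≈ 11; the NNLS ensembles bring that to χ² < 1 — an
order-of-magnitude improvement — while the ensemble ⟨Rg⟩ and the maximum
dmax (with a 20–25% population on the most extended selected conformer)
recover the generating mixture. The P(r)-target fit finds the three truth
members exactly (its χ² against the noise-free real-space target is
numerically zero); the I(q)-target fit reaches an equivalent composite
through a slightly larger support, illustrating the documented
non-uniqueness of NNLS member selection on rank-deficient profile sets.

With real inputs, point `run_config()` at a structure file (PDB/mmCIF
with pLDDT in the B column), a SASBDB-style `.dat` intensity file and
optionally a GNOM-style `.out` P(r); or use the command-line wrapper:

```sh
Rscript inst/scripts/fit-ensemble run --config run.yaml
Rscript inst/scripts/fit-ensemble guinier data.dat --skip 25 --max-qrg 1.0
Rscript inst/scripts/fit-ensemble ift data.dat --dmax 170
Rscript inst/scripts/fit-ensemble simulate --seed 7 --out-dir sim/
```

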