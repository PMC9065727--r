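# nmrdyn

Solution NMR sees what crystals hide: a protein whose deposited structure
looks rigid can tumble through an ensemble of conformations, exchange
between states on the microsecond–millisecond scale, and wave flexible
loops that never diffract. `nmrdyn` is an R toolkit for quantifying that
heterogeneity from three complementary observables — amide ¹D(NH) residual
dipolar couplings (RDCs), ¹⁵N spin relaxation, and CPMG relaxation
dispersion — together with the ensemble-geometry analysis and the
accelerated-MD parameter bookkeeping that a combined NMR/MD refinement
workflow needs. It is aimed at structural biologists and NMR
spectroscopists who have per-residue data tables and (multi-model) PDB
coordinates and want a tested, scriptable path from those to ensemble
sizes, exchange parameters and flexibility maps.

## What it computes

**RDC ensemble refinement.** For a unit N–H vector *v* and a traceless
symmetric Saupe matrix *A* (Hz), the predicted coupling is the quadratic
form *D = vᵀA v*, equivalently
*Dₐ[(3cos²θ − 1) + (3/2)R sin²θ cos2Φ]* in the tensor frame. Ensembles
sum member contributions with populations folded into the magnitudes.
Tensor fitting is linear least squares by SVD; agreement is the RDC
R-factor √(Σ(Dobs − Dcalc)² / 2ΣDobs²), which is ~0.71 for uncorrelated
predictions. `select_ensemble_size()` clusters a conformer pool
(K-medoids on the Cα-RMSD matrix), fits the medoids jointly for rising K,
and stops when the R-factor stabilizes.

**¹⁵N relaxation.** Mono-exponential fits of R1/R1ρ decays, R2 extraction
with optional off-resonance correction, the empirical
τc(25 °C) = 0.0005998·MW + 0.1674 ns calibration with viscosity scaling
to 30 °C, the rigid-limit ratio R2/R1 ≈ ((4πν_N τc)² + 7)/6, and flagging
of residues with depressed R2/R1.

**CPMG dispersion.** Carver–Richards two-site exchange (p_B, k_ex, Δω,
R2⁰), cross-validated in the test suite against an independent
Bloch–McConnell matrix-exponential propagation of the echo train; global
multi-residue/multi-temperature fitting with selectable parameter
sharing; per-residue significance by F-test plus an effect-size guard.

**Ensemble geometry & aMD.** Kabsch superposition, per-atom fluctuations
and B = 8π²⟨u²⟩ profiles, Cα displacement maps, representative-member
selection, and dual-boost accelerated-MD parameters
(E_D = E_D′ + 3.5·N_res/5, α_P = 0.2·N_atom, …) from short-MD energy
statistics.

**Synthetic data.** Every input the pipeline consumes can be generated
with known ground truth (`make_toy_ensemble`, `simulate_rdcs`,
`simulate_relaxation_decays`, `simulate_dispersion`), so each stage is
testable end-to-end without external data.

## Worked example

Plant three distinct conformers (a helix-loop-helix with the loop hinged
into three orientations) among nine decoys, simulate noise-free RDCs from
the three with known tensors, and ask the selector how many ensemble
members the data demand:

```r
library(nmrdyn)

pool    <- make_conformer_pool(n_planted = 3, decoys_per = 3, seed = 7)
tensors <- lapply(1:3, function(k)
  alignment_tensor(da = c(9, -11, 13)[k], rhombicity = c(0.2, 0.4, 0.6)[k],
                   euler = c(0.3, 0.5, -0.2) * k))
obs <- simulate_rdcs(conformer_ensemble(pool$pool$members[pool$planted]),
                     tensors, noise_sigma = 0, seed = 8)
res <- select_ensemble_size(pool$pool, obs, k_max = 7)
res$curve
#>   K     r_factor
#> 1 1 1.581752e-01
#> 2 2 1.686185e-03
#> 3 3 6.105099e-16
#> 4 4 6.105099e-16
#> 5 5 6.105099e-16
res$k_star
#> [1] 3
res$fit
#> <ensemble_fit_result> 3 member(s), 35 RDCs, R-factor = 0.0000
```

A single conformer misfits the ensemble-generated couplings (R = 0.16);
three members — exactly the planted count — drive the R-factor to
numerical zero, and the curve is flat beyond. The tumbling side is one
line each:

```r
tauc_from_mw(54000, temperature = 30)   # 54 kDa protein
#> [1] 28.67465                          # ns; ~29 ns
expected_r2r1(29e-9, nu_n = 81.1e6)     # rigid-limit R2/R1 at 800 MHz
#> [1] 146.7482                          # ~147
```

A 54 kDa globular protein at 30 °C is predicted to tumble with
τc ≈ 29 ns, giving a rigid-limit R2/R1 near 147; residues falling well
below that ratio in measured profiles are candidates for enhanced
flexibility (`flag_flexible_residues()`).

End-to-end drivers `run_ensemble_pipeline()` and
`run_dynamics_pipeline()` wire these stages together from a config list
(or YAML file) and write TSV reports.

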