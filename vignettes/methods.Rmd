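---
title: "Models and methods behind nmrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmrdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdyn)
```

nmrdyn characterizes the conformational heterogeneity of proteins in
solution from three complementary NMR observables — residual dipolar
couplings (RDCs), ¹⁵N spin relaxation, and CPMG relaxation dispersion —
plus ensemble-geometry analysis and the bookkeeping needed to set up
dual-boost accelerated MD. This vignette explains the models, their
assumptions, the tunable parameters, and the design decisions taken where
the methodology left genuine freedom.

## RDC back-calculation and the alignment tensor

A backbone amide RDC reports the orientation of the N–H bond vector
relative to the molecular alignment adopted in a dilute anisotropic
medium. For a unit bond vector $v$ and a traceless symmetric Saupe matrix
$A$ (in Hz), the predicted coupling is the quadratic form

$$ D = v^{\top} A v
     = D_a\left[(3\cos^2\theta - 1)
       + \tfrac{3}{2} R \sin^2\theta \cos 2\Phi\right], $$

where $(\theta, \Phi)$ are the polar angles of $v$ in the tensor's
principal axis system, $D_a = A_{zz}/2$ is the magnitude and
$R = (A_{xx}-A_{yy})/(3 D_a) \in [0, 2/3]$ the rhombicity. For a
conformational ensemble the observed coupling is the population-weighted
sum over members, each with its own tensor; the fractional populations are
absorbed into the tensor magnitudes and are never reported separately,
because a scaled tensor and a scaled population are indistinguishable in
this model. The general rhombic form is the default; a `form = "printed"`
switch evaluates the axial expression with the rhombic coefficient fixed
at $3/2$ for comparison with reduced parameterizations.

Because $D$ is linear in the five independent Saupe elements, fitting one
or several tensors to observed couplings is a linear least-squares problem
solved by singular value decomposition (`svd_fit_tensor`,
`ensemble_fit`). Members that share rigid-core bond geometry make the
stacked per-member design blocks rank deficient; the minimum-norm
pseudo-inverse resolves this deliberately — the data then constrain only
the summed tensor of the degenerate members, which is exactly the physical
content available.

Agreement is scored with the RDC R-factor

$$ R = \sqrt{\frac{\sum_i (D^{\mathrm{obs}}_i - D^{\mathrm{calc}}_i)^2}
                  {2 \sum_i (D^{\mathrm{obs}}_i)^2}}, $$

which is 0 for perfect agreement and ≈ $1/\sqrt2 \approx 0.71$ for
uncorrelated predictions. This denominator convention (twice the summed
squared observations) is the standard quality-factor normalization for
RDC work and is adopted here because it reproduces the familiar 0–1
scale.

## Ensemble-size selection

`select_ensemble_size` iterates the protocol: cluster the conformer pool
into $K$ groups by K-medoids (PAM) on the pairwise Cα-RMSD matrix, fit the
$K$ medoid structures jointly, record the R-factor, and increase $K$ until
the R-factor stabilizes. Two details are our own choices:

* **Monotone refinement.** Medoid sets at successive $K$ are not nested,
  so the raw cluster-then-fit curve need not decrease. At each $K$ the
  selector also evaluates the previous best member set augmented by the
  single best new medoid — a nested model whose R-factor cannot exceed the
  previous one — and keeps the better candidate. The reported curve is
  therefore non-increasing by construction while still following the
  clustering protocol.
* **Stability rule.** "Stable" is defined as relative improvement below
  `stability_tol` (default 1%) for two consecutive steps; when the
  previous R-factor is already below $10^{-8}$ the step counts as stable
  outright, since relative changes of numerical zeros are noise. The
  returned $K^*$ is the size at which the curve entered the stable
  plateau.

The atom set defining "backbone RMSD" for representative-member selection
is fixed to N, CA, C, O; ties go to the lowest member index so results are
deterministic.

## ¹⁵N relaxation

Relaxation decays are fit as $I(t) = A e^{-Rt}$ by bounded
Levenberg–Marquardt with log-linear starting values; rates are constrained
non-negative and a fit pinned at zero with a genuinely negative
unconstrained slope is flagged as clipped. The default delay schedules are
the standard constant-series sets (R1: 0–840 ms in eight steps; R1ρ:
0.2–20 ms in nine steps) shipped as `r1_delay_schedule()` /
`r1rho_delay_schedule()`.

R2 is extracted from R1ρ through
$R_2 = (R_{1\rho} - R_1\cos^2\beta)/\sin^2\beta$ with
$\tan\beta = \nu_{SL}/\Omega$. The default is on-resonance
($\Omega = 0$, $R_2 = R_{1\rho}$): with a 1 kHz spin lock the correction
is small for most amide offsets, and per-residue offsets can be supplied
when that approximation is not acceptable.

The rigid-tumbling reference uses the empirical calibration
$\tau_c(25°C) = 0.0005998\,\mathrm{MW} + 0.1674$ ns, rescaled to 30 °C by
the Stokes–Einstein–Debye ratio $(298/303)(0.7973/0.8903)$ with the two
water viscosities entered as fixed constants (0.8903 and 0.7973 cP at 25
and 30 °C). The expected ratio
$R_2/R_1 \approx ((4\pi\nu_N\tau_c)^2 + 7)/6$ then gives the horizontal
reference line against which depressed ratios indicate sub-τc mobility.
For a 54 kDa protein at 30 °C this machinery predicts τc ≈ 28.7 ns and a
rigid-limit ratio ≈ 147 at a 800 MHz spectrometer (¹⁵N frequency taken as
0.1013756 × the ¹H field = 81.1 MHz). Flexible residues are flagged below
mean − n·SD with n = 1 by default (a median/MAD option is available); the
1-SD cutoff is our choice of a conservative default, not a universal
constant, and should be read as a ranking device rather than a sharp
classification.

## CPMG relaxation dispersion

Two-site exchange is modelled with the Carver–Richards closed form
(`carver_richards`), parameterized by the minor population $p_B$, exchange
rate $k_{ex}$, per-residue shift difference $\Delta\omega$ (rad/s) and
per-residue intrinsic rate $R_2^0$, with
$\psi = k_{ex}^2 - \Delta\omega^2$,
$\zeta = -2\Delta\omega k_{ex}(p_A - p_B)$ and the usual $D_\pm$,
$\eta_\pm$ auxiliaries. A numerically safe log-space branch replaces the
$\cosh$ term when $\eta_+$ would overflow (very low effective fields with
fast exchange).

`r2eff_bloch_mcconnell` is an independent numerical reference: it builds
the complex 2×2 evolution matrix of the coupled transverse magnetizations,
propagates an explicit τ–180°–τ echo train by matrix exponentials (ideal
pulses implemented as complex conjugation, with ν_CPMG = 1/(2δ) for pulse
spacing δ), and reads out either

* the **asymptotic decay rate** of the full train propagator (default) —
  the quantity the closed form models, agreeing with it to ~10⁻¹¹ s⁻¹
  across $p_B \le 0.2$, $k_{ex} \in [50, 5000]$ s⁻¹,
  $\Delta\omega \le 6$ ppm; or
* the **detected major-state amplitude**, which additionally carries the
  transient projection of the initial condition onto the fast-decaying
  normal mode. This end effect grows with $p_B$ (a few s⁻¹ at
  $p_B = 0.2$) and is a real feature of constant-time experiments that the
  closed form ignores; keeping both readouts makes the size of that
  approximation measurable rather than hidden.

Global fitting (`fit_dispersion_global`) is weighted multi-start
Levenberg–Marquardt. The default sharing scheme — $k_{ex}$ and $p_B$ per
temperature, $\Delta\omega$ per residue shared across temperatures,
$R_2^0$ per residue per temperature — reflects that a shift difference is
a near-temperature-independent structural quantity while rates and
populations are not; fully global and fully local schemes are selectable
because multi-temperature data do not by themselves decide the question.
Flat curves leave $p_B$ and $\Delta\omega$ jointly unidentifiable (only
the product $p_A p_B \Delta\omega^2$ is constrained even in favorable
regimes); the fitter warns rather than pretending otherwise.

Dispersion significance combines an F-test (flat one-parameter model vs
the four-parameter exchange model, p < 0.01) with an effect-size guard
($R_{ex}$ above twice the median measurement error). The combination is
our choice: the F-test alone passes occasional noise wiggles at the
nominal rate, and the effect-size guard alone would miss shallow but
well-determined dispersions. The lowest simulated field defaults to
100 Hz, the practical floor for large proteins with fast intrinsic R2,
which limits sensitivity to slow exchange — a limitation inherited by any
analysis of such data, not a property of the implementation.

## Ensemble geometry

Fluctuation profiles superpose all members onto an iteratively refined
mean structure (two rounds — stable for ensembles of tens of members;
further rounds change nothing at these sizes) and report per-atom
mean-square displacements with B-factors via the crystallographic
convention $B = 8\pi^2\langle u^2\rangle$. The superposition anchor
defaults to all backbone atoms and can be restricted to one domain to
mirror domain-wise analyses (fit on a rigid domain, measure everywhere).
Displacement profiles between a member and a reference are computed after
Cα superposition and are therefore invariant to rigid motions of either
input.

## Dual-boost aMD parameters

`amd_parameters` evaluates the standard dual-boost prescription:
$\alpha_D = \alpha_1 N_{res}/5$, $E_D = E_D' + \alpha_D$,
$\alpha_P = \alpha_2 N_{atom}$, $E_P = E_P' + \alpha_P$, with
$\alpha_1 = 3.5$ kcal mol⁻¹ residue⁻¹ and $\alpha_2 = 0.2$ kcal mol⁻¹
atom⁻¹ and the primed quantities being mean dihedral and total potential
energies from a short conventional MD run. The module computes inputs for
an external simulator and never runs MD; energy traces are plain
three-column TSV, and $N_{res}$/$N_{atom}$ count the full solvated system.

## The synthetic-data generator

`make_toy_ensemble` builds an idealized helix-loop-helix backbone from
standard φ/ψ geometry (−57/−47 helical, −75/+145 extended loop) and
creates members by a rigid hinge rotation of the loop segment plus
isotropic coordinate jitter. A hinge rotation — rather than a translation
— is essential: it changes both positions and N–H bond orientations, so
the planted disorder is visible to RDCs as well as to fluctuation
analysis. The rotation angle is set so the farthest loop atom moves by the
requested amplitude (default 5 Å, a large but realistic loop excursion).

Defaults are fixed once and match the acquisition design the package
models: RDC noise 1.5 Hz (under the sub-2 Hz error of intensity-based
coupling measurement), 2% intensity noise on relaxation decays, 0.3 s⁻¹
noise on R2,eff, ten CPMG fields from 100–1000 Hz with a 40 ms
constant-time delay, and the delay schedules above. The generator is
deterministic given a seed and never touches the global RNG stream.

What the generator does *not* emulate: anisotropic tumbling,
non-idealized peptide geometry, spectral overlap and peak-picking errors,
temperature-dependent $\Delta\omega$, multi-site exchange, and alignment
media that perturb the structure. Passing closure tests therefore
demonstrates correctness of the estimators under the stated noise models,
not robustness to every pathology of real spectra.

## Problem sizes and numerical choices

The test-suite and acceptance computations use deliberately desk-scale
problems: 20-residue vector sets for tensor recovery, a 12-member pool
(3 planted conformers + 9 decoys, ~35 RDCs) for size selection, 10
residues × 10 fields × 50 replicates for exchange-rate recovery, and 100
replicates for relaxation-rate bias. These sizes were chosen as the
smallest at which the statistical claims are meaningful, and they match
the conditions stated alongside each claim. Tie-breaks everywhere go to
the lowest index; altloc parsing keeps the highest occupancy (tie → "A");
all tolerances quoted above are enforced by the test suite rather than
asserted in prose.

## Known limitations

* Populations and tensor magnitudes are inseparable in the RDC model; no
  per-member weights are ever reported.
* The Carver–Richards form assumes equal intrinsic R2 in both states and
  ideal 180° pulses; pulse-sequence-specific relaxation differences are
  absorbed into $R_2^0$.
* τc prediction is an empirical MW calibration for globular proteins at
  two temperatures only; it is not a hydrodynamic calculation.
* The clustering granularity of a real trajectory (frame stride, metric
  atoms) is a user decision; the package clusters whatever pool it is
  given.
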