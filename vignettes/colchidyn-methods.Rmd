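---
title: "Methods: quantifying conformational exchange in an engineered lipocalin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying conformational exchange in an engineered lipocalin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colchidyn)
```

## The scientific problem

Colchicalin is an anticalin — an engineered lipocalin derived from the human
Lcn2 scaffold — that binds the plant toxin colchicine with picomolar
affinity. Crystal structures of the free and ligand-bound protein show a
large rearrangement of loop L3 (residues 95–105) at the open end of the
β-barrel: in the free state the loop occludes the pocket, in the complex it
is pushed outward. The question this package's workflow addresses is *how*
the free protein reaches a binding-competent conformation: by induced fit
after the ligand arrives, or by conformational selection from an exchange
between pre-existing open and closed states.

The workflow combines four kinds of evidence:

1. **Fast (ps–ns) backbone dynamics** from ¹⁵N relaxation (R₁, R₂, hetNOE):
   is the protein's core and tumbling unchanged by binding?
2. **Slow (µs–ms) exchange** from CPMG relaxation dispersion at two static
   fields: which residues feel chemical exchange, at what rate and minor
   population?
3. **A global kinetic network** from discrete simulation trajectories,
   coarse-grained to a few metastable states and *augmented* with the
   dispersion data so that exchange absent from the simulations (because
   they never crossed between conformations) is still quantified.
4. **Structural and ensemble observables**: loop RMSDs and atom
   displacements after a barrel-frame superposition, S² order parameters,
   and r⁻⁶-averaged NOE distances.

## Models and conventions

### Model-free relaxation and the tumbling time

The spectral density is the Lipari–Szabo form
$$J(\omega) = \tfrac{2}{5}\Big[\frac{S^2\tau_c}{1+(\omega\tau_c)^2}
  + \frac{(1-S^2)\tau'}{1+(\omega\tau')^2}\Big],\qquad
  \tau'^{-1} = \tau_c^{-1} + \tau_e^{-1},$$
with the standard amide constants rNH = 1.02 Å and Δσ = −172 ppm (community
defaults; `predict_rates()` exposes both). R₁, R₂ and hetNOE are the usual
dipolar + CSA combinations of J at {0, ωN, ωH±ωN, ωH}.

`estimate_tau_c()` inverts the per-residue R₂/R₁ ratio — which cancels the
overall scale of J and is therefore insensitive to S² when internal motion
is very fast — by bisection over τc ∈ [0.1, 100] ns. Residues with
hetNOE < 0.7 are excluded (fast internal motion), and per-residue estimates
outside median ± 1.5·IQR are trimmed before averaging; the trimming is this
package's convention for suppressing residual-exchange outliers, since no
exclusion list is published for the original experiment. The error bar is a
seeded Monte-Carlo resampling of the rates within their quoted errors
(n = 1000 by default).

Two flag statistics mirror the experimental analysis: hetNOE strictly below
0.7 marks fast ps–ns motion, and R₁·R₂ strictly above 20 s⁻² marks µs–ms
exchange (the product removes the tumbling-anisotropy dependence that
inflates R₂ alone). Both thresholds are arguments, both inequalities
strict. Chemical shift perturbations use the standard amide weighting
$\Delta\delta = \sqrt{\Delta\delta_H^2 + (0.14\,\Delta\delta_N)^2}$.

### CPMG dispersion: closed form and propagator

The CPMG convention throughout is ν_CPMG = 1/(4 τcp) with echo element
[τcp – 180° – τcp], so a relaxation delay T_relax contains
N = 2 T_relax ν_CPMG echoes; T_relax defaults to 40 ms. Pulses are ideal
(instantaneous phase conjugation); off-resonance and pulse-imperfection
effects are out of scope. kex is quoted in rad·s⁻¹, following the
convention of the experimental literature for this system; numerically it
is the sum of forward and backward first-order rates. The Rex threshold is
5 s⁻¹ on R2,eff differences; the experimental literature quotes the same
cut both as "5 Hz" and "5 rad·s⁻¹", which differ by 2π, and this package
standardises on the s⁻¹ reading.

Two forward models are implemented and cross-checked:

* `cr_r2eff()` — the Carver–Richards closed form for two-site exchange with
  equal intrinsic R₂, with Δω converted from ppm at the given field. The
  arccosh term overflows at very low ν_CPMG; the implementation switches to
  the exact logarithmic asymptote there.
* `bm_r2eff()` — a numerical Bloch–McConnell propagator for N states: one
  complex transverse component per state evolving under
  A = Kᵀ + iΩ − diag(R₂), with the 180° pulse as conjugation.

The propagator offers two read-outs. `mode = "amplitude"` mimics the
experiment: R2,eff = −ln(|ΣM(T_relax)|/|ΣM₀|)/T_relax, which contains a
finite-delay amplitude contribution from the fast-decaying minor modes.
`mode = "rate"` returns the asymptotic decay rate of the echo train (the
dominant eigenvalue of the two-echo propagator). The Carver–Richards
expression is *exactly* the asymptotic rate — the two agree to machine
precision across the full parameter sweep — so all dual-route checks,
generated synthetic curves and the augmentation objective use
`mode = "rate"`, keeping every fit convention-matched; the amplitude
read-out converges to it as T_relax grows and is kept as the default
because it is what a spectrometer measures. In the deep slow-exchange
corner (kex ≪ Δω in rad/s) both routes agree on genuine echo-modulation
oscillations of R2,eff versus ν_CPMG; monotonic decay is only guaranteed
outside that regime.

`fit_dispersion()` fits (pA, kex, Δω) shared across fields plus one R₂⁰
per field by weighted Levenberg–Marquardt from a 20-point multistart grid
(log-spaced kex, several pA and Δω levels), against a flat no-exchange
alternative; the two are compared by AICc with ties resolved toward
no-exchange. Parameter uncertainties come from a seeded 200-resample
point bootstrap restarted at the best fit. The (pA, Δω) ↔ (1−pA, −Δω)
relabelling degeneracy is fixed by the pA ≥ 0.5, Δω ≥ 0 convention.
Fits are per residue; ¹³C methyl curves go through the same machinery in a
single-quantum approximation. Rex is evaluated as the model difference
between a low (10 Hz) and a high (10 kHz) pulsing frequency.

### Markov state models and experiment augmentation

`estimate_msm()` maximises the reversible likelihood by the standard
fixed-point iteration on symmetric flux variables, which enforces detailed
balance to machine precision; disconnected counts are restricted to the
largest strongly connected set. The lag time is user-chosen against an
implied-timescale plateau (`implied_timescales()`); no automatic selection
is attempted. `coarse_grain()` assigns microstates to metastable sets from
the slowest right eigenvectors by an inner-simplex (PCCA-like) vertex
search with barycentric memberships, crisped by argmax for rate reporting;
fuzzy memberships are retained in the output. `generator_from_tmatrix()`
takes the eigendecomposition logarithm, clips (and reports) any small
negative off-diagonals, and repairs row sums.

`augment_with_experiment()` is the step that turns mutually disconnected
simulation blocks plus experimental dispersion into one global network. The
network is parametrised by stationary populations (softmax) and symmetric
exchange fluxes S_ij = π_i k_ij, so detailed balance holds by construction
and every parameter is unconstrained. The objective is

$$\sum_{r,f,\nu}\Big(\frac{R_{2,eff}^{obs}-R_{2,eff}^{calc}}{\sigma}\Big)^2
 + \lambda \sum_{(i,j)\in\text{sim}}
   \big(\log k_{ij} - \log k_{ij}^{sim}\big)^2,$$

a least-squares form (the penalty enters as extra residuals) minimised by
seeded multistart Levenberg–Marquardt; inter-block rates start log-uniform
over 10¹–10⁴ rad/s. λ = 1 by default — with no published guidance, the
kinetic prior and the data misfit are weighted equally. Per-state shift
offsets can be fitted jointly (bounded ±6 ppm), but when they are free the
two closed states become label-exchangeable and only the sorted populations
are identifiable; the recommended path, used by the analysis scripts, is to
supply offsets from the per-residue dispersion fits. The returned
diagnostics include the experimental χ² and the RMS log-space perturbation
of the intra-block rates.

### Structures and ensemble observables

Superposition is a least-squares rigid fit (Kabsch SVD construction,
reflections excluded) over a named atom selection matched by chain, residue
and atom name. All printed Å quantities — per-residue Cα deviations, loop
RMSDs, atom displacements between states — are measured after fitting on
the β-barrel frame. The 58-residue barrel Cα selection shipped in
`inst/extdata/barrel_selection.json` is constructed from the scaffold
topology (eight strands flanking the loops L1 38–51, L2 70–76, L3 95–105,
L4 125–132); the strand assignment is not enumerated in the experimental
reports, so the file is a documented approximation and every function
accepts an alternative selection. Altloc 'A' is kept, insertion codes are
rejected, and atom names follow PDB v3 (CD1, CG1, CG2).

S² order parameters use
$S^2 = \tfrac32\sum_{ab}\langle e_a e_b\rangle^2 - \tfrac12$ over
normalised bond vectors, assumed expressed in a molecule-fixed frame; the
documented preprocessing path is a superposition pass with
`superpose()`/`apply_superposition()` to remove global tumbling, and no
time-windowing is applied. NOE distances use
$\langle r^{-6}\rangle^{-1/6}$ with an inclusive 10 Å visibility cutoff
(methyl–methyl NOEs are observable over roughly 4–10 Å).

## The synthetic study

Because the raw spectrometer output, the microsecond MD trajectories and
the deposited dispersion tables are not distributable inputs, the package
generates a two-arm synthetic study (`make_study_bundle()`) that emulates
the *structure* of the real data, with every planted truth recorded in a
manifest:

* an "apo" arm with a planted three-state network — a binding-competent
  state at 3% population exchanging with two binding-incompetent states at
  57% / 40%, inter-state exchange in the 10²–10³ rad/s range — driving
  two-field (600/950 MHz) dispersion at four loop-L3 reporter residues with
  σ = 0.3 s⁻¹ Gaussian noise;
* a "bound" arm generated from a single-state (flat) model;
* relaxation tables for 150 residues at the planted tumbling times
  13.24 ns (apo) and 13.06 ns (bound) with 2% noise, a structured core at
  S² = 0.86 with 20 ps internal motion (hetNOE ≈ 0.8) and flexible termini
  and loops at S² = 0.45;
* a jump trajectory (0.1 ms frames) covering only the two closed states,
  so the competent state is a disconnected singleton block — the situation
  the augmentation step exists to resolve.

The generators are pure functions of (parameters, seed); a study-level seed
fans out to fixed per-table substreams. What passing tests on this study
show is that the estimators recover planted truths under honest noise of
the right magnitude and data layout; what they cannot show is robustness to
real-data pathologies — peak overlap, field-dependent intrinsic R₂,
anisotropic tumbling, force-field error — which are all out of scope.

## Numerical choices

* τc inversion: bisection on [0.1, 100] ns, tolerance 10⁻¹⁵ s; the R₂/R₁
  ratio is strictly increasing in τc so the root is unique.
* Matrix exponentials: complex eigendecomposition with a scaled
  Taylor-series fallback when the eigenvector basis is ill-conditioned
  (rcond < 10⁻¹²); an independent series implementation serves as the
  oracle in tests.
* Multistart fitting: Levenberg–Marquardt (`minpack.lm`), 20 starts for
  per-residue dispersion fits, 6–8 for the augmentation; non-convergence of
  every start is a flagged result, never silent.
* Degenerate inputs: zero-length vectors, empty distance series, absorbing
  states, non-integer pulse counts (snapped to the nearest valid grid with
  a warning) and non-positive transition-matrix spectra (no real generator;
  error with diagnosis) are all handled explicitly.
* AICc uses the χ² form appropriate for known σ, with the small-sample
  correction; an exact tie selects the simpler model.

## Problem sizes

The default test and acceptance runs use 150-residue relaxation tables,
12–20-point CPMG grids at two fields, 2 × 10⁴-frame trajectories, 10⁵-frame
wobble series and 3-state networks. These sizes were chosen so every
planted-truth recovery sits well inside its tolerance while the full suite
completes in minutes; all of them are arguments, and scaling any of them up
changes no code path.

## Known limitations

* The experimental dispersion data of the original study are not deposited,
  so its fitted kex/pA/Δω values, the 97%/3% populations and the MD-derived
  8.6/14 Å r⁻⁶ distances are covered only qualitatively, by construction of
  the synthetic study; the quantitative surface is planted-truth recovery.
* The real-coordinate measurements (loop RMSDs, atom displacements) require
  the deposited PDB entries 6Z6Z, 5NKN and 3CMP, fetched at run time or
  supplied locally; the shipped barrel selection is an approximation with
  ±0.3 Å-scale selection sensitivity.
* No multiple-quantum CPMG, CEST or R1ρ; no anisotropic diffusion; no
  Bayesian MSM uncertainty; no TICA/clustering of raw coordinates into
  microstates (discrete labels are inputs).
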