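---
title: "Models and methods behind gluflux"
author: "gluflux maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gluflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gluflux)
```

gluflux bundles two pipelines that meet in the same scientific question —
how glutamate finds, and gates, an AMPA-type receptor:

1. a **kinetic pipeline**: a 12-state Markov gating model of the receptor,
   integrated under realistic agonist concentration jumps, plus the
   trace-analysis fitters used on patch-clamp-style currents;
2. a **trajectory pipeline**: 3D potentials of mean force (PMFs) from
   ligand-coordinate time series, metastable-site extraction,
   cleft-closure order parameters, binding-event detection and an
   association-rate (k~on~) estimator.

Both are backed by seeded synthetic-data generators with known ground
truth, so every analysis stage can be validated end to end.

## The gating model

The receptor carries four glutamate binding sites. Closed states R, AR,
A2R, A3R, A4R are connected by sequential binding steps with association
rate `k_plus` (per site, scaled by the agonist concentration) and
dissociation rate `k_minus`; openings A3R ⇌ A3R\* and A4R ⇌ A4R\* use
`beta`/`alpha`; each closed state has a dead-end desensitized partner
(d~0~ rates for the unliganded pair, d rates for liganded ones). The
default rate set is `beta` 5000, `alpha` 3000 s^-1^, `k_plus` 5×10^6^
M^-1^s^-1^, `k_minus` 10^4^ s^-1^, `d_plus` 250, `d_minus` 60,
`d0_plus` 1, `d0_minus` 9 s^-1^. Unitary conductances are 0 except
A3R\* (1) and A4R\* (2); the normalized current is the
conductance-weighted occupancy divided by the maximum conductance. A
common factor *f* (`scale_binding()`) multiplies `k_plus` and `k_minus`
together, slowing the binding pathway without changing affinity — the
model's handle on binding-pathway mutants.

Because desensitized states are dead ends and no binding occurs along
them, the transition graph is a tree: detailed balance at stationarity is
automatic, and the resting state at zero agonist is
P(R) = d0~minus~/(d0~plus~+d0~minus~) = 0.9, P(D0) = 0.1. All protocols
start from this resting equilibrium.

**Statistical factors.** Association steps carry the multiplicities
4, 3, 2, 1 of four identical independent sites. Whether dissociation
steps carry the reverse factors 1, 2, 3, 4 is a convention the model's
description leaves open, so `build_default_scheme()` exposes both. The
default omits them, a choice made on the model's published behaviour
rather than taste: with dissociation factors the simulated
deactivation-versus-rise-time relation across the *f* sweep has slope
≈ 3 and the model's apparent glutamate EC~50~ is ≈ 1 mM; without them
the slope is ≈ 7–8 — the steep relation the simulations are known to
produce — and the EC~50~ falls to a few hundred µM, in line with the
measured 330 µM. Pass `dissociation_factors = TRUE` for the fully
factored convention.

**Generator convention.** `generator_matrix()` uses the column
convention: `Q[j, i]` is the rate from state i to state j and every
column sums to zero, so the master equation is dP/dt = Q P. The matrix
is affine in concentration, Q = Q0 + \[A\]·Q1, which the integrator
exploits.

**Integration.** The default path is the stiff solver
`deSolve::lsoda` (rtol 10^-8^); a piecewise matrix-exponential
propagator (`method = "expm"`, midpoint concentration per interval,
i.e. second-order Magnus) is provided as an independent cross-check.
On smooth 300 µs exchange edges the two agree to ~2×10^-5^ at one
substep and to < 10^-6^ with `expm_substeps = 8`; the test suite pins
that agreement. Probability is conserved to ~10^-14^ because the
generator's columns sum to zero exactly.

## Concentration jumps

`make_jump()` builds the agonist waveform of a piezo-driven fast
perfusion system: complementary Gaussian-CDF edges with
σ = exchange/2.5631 (2.5631 σ is the 10–90% width of a normal CDF) and a
pulse duration interpreted as the waveform's full width at half maximum.
The functional form of real perfusion edges is not uniquely defined by a
10–90% time, so the edge shape is pluggable (`shape = "logistic"` is the
alternative); rise-time comparisons at the ~10% level can depend on it.
`measure_exchange()` reads the realized 10–90% width back off any
profile by linear interpolation, and round-trips `make_jump()` within
1%.

## What the simulated rise time can and cannot be

With the printed rates, the current's intrinsic step response relaxes at
β+α = 8000 s^-1^ (τ = 125 µs), which floors the sigmoid-fitted 10–90%
rise near 240 µs for an instantaneous jump; the binding cascade only
sharpens this mildly. Driving the model with the standard 10 mM, 800 µs,
300 µs-exchange jump yields ≈ 315 µs. A measured wild-type rise time of
≈ 200 µs therefore cannot be reproduced by this rate set under any edge
shape — a genuine property of the model as printed, not an integration
artifact (the stiff and exponential integrators agree, and the rise-time
fitter is exact on analytic test curves). The package reports what the
model computes.

**Two-pulse recovery.** The two-pulse protocol reports test/conditioning
peak fractions. Because the conditioning pulse also drains the slowly
re-equilibrating resting desensitized pool (d~0~ rates, τ ≈ 0.1 s), the
fraction can transiently overshoot 1 at intermediate interpulse
intervals before settling back — a property of the scheme, not a bug in
the bookkeeping.

## Trace analysis

- **Rise times** (`rise_time_10_90()`): a Richards (generalized
  logistic) sigmoid, y = base + amp·(1+ν e^-(t-t50)/k^)^-1/ν^, is fitted
  from the baseline to the peak and the 10% and 90% crossings are read
  off the fitted curve. The shape parameter ν nests the symmetric
  logistic (ν = 1) and the saturating exponential 1−e^-t/τ^ (ν = −1,
  with the ν < 0 branch clipped to the baseline), so first-order
  onsets are fitted without shape bias — on a pure saturating
  exponential the procedure returns τ·ln 9 to machine precision.
- **Decay constants** (`fit_monoexp()`): least squares of
  A e^-t/τ^ + C over a window; the deactivation window runs from the
  post-peak sample to the end of the record, the desensitization window
  from the peak to the end of the pulse; both are arguments.
  `effective_tau_from_90_10()` back-calculates τ = Δt/ln 9 from a
  90→10% decay time.
- **Dose–response** (`fit_hill()`): I/I~max~ = \[A\]^n^/(\[A\]^n^+EC~50~^n^),
  with the fit flagged when the EC~50~ leaves the tested range by more
  than 100-fold.
- **Recovery from desensitization** (`fit_recovery()`): the
  Hodgkin–Huxley-type form N(t) = N~0~+(1−N~0~)(1−e^-k~rec~t^)^n^, with
  a degeneracy flag when the data carry no recovery signal.
- **Deactivation vs activation** (`fit_line_eiv()`): a straight line
  fitted with uncertainties in both axes by the exact York iteration
  (orthogonal-distance regression with per-point σ~x~, σ~y~), returning
  slope, intercept, reduced χ², parameter covariance and a confidence
  band. It reduces to ordinary least squares as σ~x~ → 0.

Noise for peak detection is estimated robustly from first differences
(MAD), which is insensitive to the trend.

## PMF pipeline

Ligand heavy-atom coordinates (in a protein-aligned frame;
`align_frames()` performs the Kabsch superposition when raw protein
coordinates are supplied) are binned on a regular grid (default 0.5 Å)
with a hard-sphere rule: a voxel is occupied in a frame when its center
lies within the van der Waals radius of any ligand heavy atom (element
radii C 1.7, O 1.52, N 1.55 Å are typical; radii are per-atom inputs).
Occupancy is binary per frame by default; an atom-count-weighted variant
sits behind `weighted = TRUE`. Boltzmann inversion gives
W(r) = −k~B~T ln ρ(r) with k~B~ = 1.9872×10^-3^ kcal mol^-1^ K^-1^
(T defaults to 300 K; pass 310 K for runs thermostatted there),
referenced so the mapped minimum is exactly zero. Zero-density voxels
are masked rather than capped: −ln 0 is undefined and capping would
bias site volumes.

Uncertainty comes from block averaging: contiguous equal-length blocks
(10 by default; 5–15 give qualitatively similar pictures), a PMF per
block, and the per-voxel population standard deviation across blocks.
Metastable sites are 26-connected components of voxels under a contour
(presets 0.32, 1.16, 1.89, 2.62 kcal/mol), sorted by their minimum free
energy so the global minimum is site 0. `flatten_1d()` produces the
canonical 1D representation (z fastest, then y, then x, from the
minimum corner), and grids export to OpenDX for molecular viewers.

The (ξ1, ξ2) cleft-closure order parameters are center-of-mass
distances between user-configured atom clusters (`cluster_spec()`,
`xi_values()`); the cluster membership must be supplied because it is a
structure-specific definition.

## Binding events and k~on~

`detect_events()` opens an event when the ligand's reference-atom
distance to the pocket stays below `bound_cutoff` (default 6 Å) for at
least `min_dwell` (default 1 ns) and closes it symmetrically —
hysteresis that rejects sub-dwell flicker. Poses are classified by
anchor contacts (α-carboxylate to Lobe 1 and γ-carboxylate to Lobe 2 =
crystallographic; swapped = inverted; both or neither = undetermined;
4 Å heavy-atom cutoff). Bulk time is the frame-weighted time with the
minimum ligand–protein distance above 8 Å, mirroring the placement
criterion of unbiased binding simulations; the alternative "bulk = not
bound" bookkeeping is available because the definition is a convention.
The estimator is

k~on~ = Σ~i~ N~b,i~ / Σ~i~ t~i~ \[L~i~\] s~i~,

summed over systems, and is invariant to how rows are split.

## Synthetic ground truth

`bd_simulate()` integrates overdamped Langevin dynamics
(Euler–Maruyama, Δr = −(D/k~B~T)∇U dt + √(2D dt) η) for point ligands
over Gaussian-well potentials in a periodic box; D defaults to 76
Å²/ns (small-molecule scale), dt to 10^-3^ ns with a stability guard
D·dt ≤ 0.1·w²~min~. Every generator is bit-reproducible from its seed.
`truth_pmf()` evaluates the potential at voxel centers — the exact
answer the density pipeline should recover.

Validation choices worth knowing:

- **Resolution condition.** The hard-sphere probe (1.7 Å pseudo-atom)
  convolves the sampled density, so recovery tests use wells of width
  5 Å — wide relative to the probe. With 3 Å wells the smoothing bias
  exceeds the statistical block error and the comparison fails for the
  right reason: the probe cannot resolve features at its own scale.
  Real heavy atoms binned at 0.5 Å face the same resolution limit.
- **Recovery test.** A two-well landscape (depths 2.5 and 1.5 kcal/mol,
  referenced difference 1 kcal/mol, box 40×24×24 Å, 1 Å grid, 10
  walkers × 60 000 steps, frames every 0.03 ns) is pushed through
  bin→invert; ≈ 99% of well-region voxels agree with the analytic truth
  within twice the 10-block error, and the point-density ratio at the
  two minima reproduces the Boltzmann factor e^-ΔU/kBT^ ≈ 0.187.
- **k~on~ oracle.** Absorbing-sphere runs at U ≡ 0 (R = 5 Å, box edge
  120 Å, dt 10^-3^ ns, nine walkers × 2×10^7^ steps ≈ 550 events)
  reproduce the Smoluchowski closed form 4πDR ≈ 2.9×10^9^ M^-1^s^-1^
  within ~9%. Two small systematic effects partially cancel and are
  deliberately left visible: periodic images raise the steady-state
  rate by ≈ 2.84·R/L (+13% here), and the finite timestep lowers the
  effective absorbing radius by ≈ 0.58·√(2D dt) (−5%). Bulk time in
  these runs is all unabsorbed time: the zero-potential world has no
  surface-associated state to exclude.
- **What the generators do not emulate:** protein geometry and
  flexibility, explicit solvent, electrostatic steering, correlated
  multi-ligand effects, and recording artifacts beyond additive
  Gaussian noise. Passing tests demonstrate the estimators' correctness
  on data that match their assumptions, not performance on real
  recordings or trajectories.

## Problem sizes and defaults

Simulated protocols default to 10 kHz output sampling (the usual
acquisition rate); rise-time work uses 5 µs sampling internally because
a 200–300 µs rise cannot be interpolated from 100 µs samples. The
f-sweep uses a 20 ms activation pulse — the rise completes within ~2 ms
even at f = 0.05 — and a 1 ms deactivation pulse with a 50 ms tail.
Brownian-dynamics problem sizes above were chosen so each well voxel
collects enough counts per block for a meaningful standard deviation
and each association run collects ≥ 500 events.

## Known limitations

- The gating scheme's desensitized-state attachment (one dead-end
  partner per closed state) is one reading of a model whose topology is
  described only in outline; the builder isolates it so alternatives
  can be plugged in.
- The rise-time floor discussed above means the kinetic model, as
  printed, rises more slowly than the ~200 µs wild-type measurement.
- Site extraction is exact on mapped voxels but silent about unmapped
  (never-visited) space between sites; contour choices matter near the
  masking threshold.
- The York fit assumes independent Gaussian errors per point; reduced
  χ² well above 1 (as for the published mutant panel, ~6) signals model
  misfit, which the fit reports rather than hides.
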