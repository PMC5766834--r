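# gluflux

Kinetic modelling and trajectory analysis of glutamate binding to
AMPA-type ionotropic receptors.

Fast excitatory neurotransmission depends on how quickly glutamate can
reach, bind and gate its receptor. Two complementary kinds of data speak
to that process: macroscopic receptor currents evoked by sub-millisecond
agonist applications, and molecular-dynamics trajectories in which
ligands diffuse onto the receptor's clamshell-shaped ligand-binding
domain (LBD). gluflux implements the computational machinery for both,
for people who study ligand-gated ion channel kinetics or ligand-binding
pathways:

- **Gating-model simulation.** A 12-state Markov scheme of a four-site
  receptor (closed chain R…A4R, open states A3R\*/A4R\*, five dead-end
  desensitized states) with the master equation dP/dt = Q([A](t)) P
  integrated under "realistic concentration jumps" — smooth agonist
  waveforms with a parameterized 10–90 % solution-exchange time. A
  common factor *f* on the association and dissociation rates models
  mutations that disrupt the binding pathway without changing affinity.
- **Trace analysis.** Sigmoid-interpolated 10–90 % rise times,
  monoexponential deactivation/desensitization fits, the effective
  τ = Δt(90→10)/ln 9 back-calculation, Hill dose–response fits
  (I/I\_max = [A]^n / ([A]^n + EC50^n)), Hodgkin–Huxley-type recovery
  fits (N = N0 + (1−N0)(1−e^(−k\_rec t))^n), and errors-in-variables
  (York/ODR) straight-line fits with per-point uncertainties on both
  axes.
- **3D ligand-density PMFs.** Hard-sphere occupancy of ligand heavy
  atoms on a 0.5 Å grid, Boltzmann inversion W(r) = −k\_B T ln ρ(r),
  10-block statistical errors, metastable-site extraction by
  contouring, the canonical 1D flattening, (ξ1, ξ2) cleft-closure
  order parameters, and OpenDX export.
- **Binding events and k\_on.** Dwell-time–hysteretic event detection,
  crystallographic/inverted pose classification, bulk-time bookkeeping,
  and the pooled estimator k\_on = Σ N\_b / Σ t\_i [L\_i] s\_i.
- **Synthetic ground truth.** Seeded Brownian-dynamics over known
  Gaussian-well landscapes (with analytic truth PMFs and a
  Smoluchowski 4πDR association oracle) and noisy synthetic current
  traces with known kinetics, so every estimator is validated end to
  end.

## Worked example

Simulate a wild-type receptor current evoked by a 1 ms pulse of 10 mM
glutamate with a 300 µs solution exchange, then measure its
deactivation:

```r
library(gluflux)

rates <- rate_constants()          # printed wild-type set, f = 1
trace <- run_protocol("brief_pulse", rates = rates, dt = 5e-6)
peak  <- max(trace$response)
tau   <- fit_monoexp(trace)$tau    # post-peak monoexponential fit
cat(sprintf("peak = %.3f of max response, tau_deact = %.2f ms\n",
            peak, tau * 1e3))
#> peak = 0.451 of max response, tau_deact = 0.90 ms
```

The peak reaches about 45 % of the maximal (all-channels-open) response
— the scheme's efficacy and desensitization cap it — and deactivation
relaxes with τ ≈ 0.9 ms, set mainly by glutamate unbinding. Slowing the
binding pathway tenfold (f = 0.1) slows deactivation roughly in
proportion:

```r
slow <- run_protocol("brief_pulse", rates = rates, f = 0.1, dt = 5e-6)
cat(sprintf("tau_deact(f = 0.1) = %.2f ms\n",
            fit_monoexp(slow)$tau * 1e3))
#> tau_deact(f = 0.1) = 3.26 ms
```

The association-rate estimator works on per-system event tables:

```r
inp <- kon_input(data.frame(system = "mon1", Nb = 3, t_s = 1e-5,
                            conc_M = 0.01, subunits = 1))
estimate_kon(inp)                  # 3 binding events in 10 us at 10 mM
#> [1] 3e+07
```

See `vignette("gluflux-methods")` for the models, conventions and
validation design.

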