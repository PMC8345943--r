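# dnatwist

Torsional dynamics of double-stranded DNA, modelled as two coupled chains
of base "pendulums" on an elastic sugar–phosphate backbone — a simulator
and analysis toolkit for studying how a DNA molecule responds to a
periodic external torque, and how that response depends on its nucleotide
sequence. It is aimed at researchers in molecular biophysics and
structural bioinformatics who want a reproducible, scriptable
implementation of this class of mechanical DNA models.

## The model

Base *i* of chain *j* is a pendulum with moment of inertia *I*ⱼⁱ rotating
about the backbone; its angle φⱼⁱ(*t*) obeys Newton's equation with three
torques:

* backbone torsion *K*ⱼⁱ·[φⱼⁱ⁻¹ − 2φⱼⁱ + φⱼⁱ⁺¹] (one-neighbour form at the
  chain ends),
* elastic hydrogen-bond pairing with the complementary base,
  −*k*₁₂ⁱ*R*₁ⁱ(*R*₁ⁱ+*R*₂ⁱ)·sin φ₁ⁱ − *k*₁₂ⁱ*R*₁ⁱ*R*₂ⁱ·sin(φ₁ⁱ−φ₂ⁱ) on
  chain 1, with two selectable sign conventions for chain 2 (the
  `as_printed` form and a `potential_consistent` form that derives from an
  explicit pair potential — see the vignette),
* external action −βⱼⁱ·dφⱼⁱ/dt + *F*₀cos ω*t*: viscous drag from the
  surrounding liquid plus a uniform periodic drive.

Chain 1 carries the input sequence (FASTA or a seeded synthetic
generator), chain 2 its Watson–Crick complement; every coefficient is
looked up per base from a built-in SI parameter table (moments of inertia
~10⁻⁴⁴ kg m², pair stiffnesses 6.2×10⁻² N/m for A·T and 9.6×10⁻² N/m for
G·C, etc.). The 2*n* equations are integrated from the equilibrium state
(φ₁ = 0, φ₂ = π, at rest) with a compiled fixed-step classical RK4 solver,
and trajectories are summarized by the chain-1 mean angular deviation
φ̄₁(*t*) = (1/*n*)Σᵢφ₁ⁱ(*t*), its post-transient amplitude, and its
dominant frequency (Hann-windowed periodogram).

## Worked example: the oscillation frequency is the molecule's, not the drive's

```r
library(dnatwist)

s <- random_sequence(100, gc_fraction = 0.5, seed = 1)   # synthetic duplex
for (om in c(1e10, 5e9, 0)) {
  sys  <- build_system(s, force = force_spec(F0 = 0.5e-22, omega = om),
                       variant = "potential_consistent")
  traj <- integrate_duplex(sys, integration_settings(t_end = 5e-9))
  sm   <- run_summary(traj, transient_cutoff = 0.5e-9)
  cat(sprintf("omega = %5.0e s^-1  ->  dominant frequency %.4g Hz\n",
              om, sm$dominant_frequency))
}
#> omega = 1e+10 s^-1  ->  dominant frequency 1.376e+11 Hz
#> omega = 5e+09 s^-1  ->  dominant frequency 1.35e+11 Hz
#> omega = 0e+00 s^-1  ->  dominant frequency 1.35e+11 Hz
```

All three runs oscillate at ≈1.35×10¹¹ Hz — within 2% of the
constant-force (ω = 0) reference and two orders of magnitude away from
the drive frequencies ω/2π themselves. The molecule responds at its own
intrinsic frequency; the drive only sets how hard it is shaken. Each run
integrates 5×10⁵ RK4 steps (dt = 10⁻¹⁴ s) and takes ~15 s.

Block-substitution experiments (`run_substitution_experiment()`) replace
a centered stretch of chain 1 with a homopolymer (40A/40T/40G/40C/100A;
positions 471–510 and 441–540 in a 980-mer) and compare amplitudes across
variants, including an estimator-sensitivity report. A thin command-line
front end with `gen-seq` / `simulate` / `sweep` / `substitute` verbs is
installed under `inst/scripts/dnatwist.R`.

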