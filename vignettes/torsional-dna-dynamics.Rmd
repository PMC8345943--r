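---
title: "Torsional dynamics of a DNA duplex as coupled base pendulums"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsional dynamics of a DNA duplex as coupled base pendulums}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnatwist)
```

## The model

`dnatwist` simulates the rotational motion of nitrogenous bases around the
sugar–phosphate backbone of a double-stranded DNA molecule. The molecule is
idealized as two chains of $n$ pendulums: base $i$ of chain $j$ is a rigid
body with moment of inertia $I_j^i$ rotating about the backbone axis, its
center of mass a distance $R_j^i$ from the axis. Three torques act on it:

* **backbone torsion** — adjacent bases on the same chain are coupled by a
  torsional spring of constant $K_j^i$, giving
  $K_j^i\,[\varphi_j^{i-1} - 2\varphi_j^i + \varphi_j^{i+1}]$ in the
  interior and the one-neighbour forms
  $K_j^1[\varphi_j^2 - \varphi_j^1]$, $K_j^n[\varphi_j^{n-1}-\varphi_j^n]$
  at the ends;
* **hydrogen-bond pairing** — complementary bases are linked by an elastic
  bond of stiffness $k_{12}^i$ (one value for A·T, a larger one for G·C),
  producing the nonlinear on-site and cross terms
  $-k_{12}^i R_1^i (R_1^i{+}R_2^i)\sin\varphi_1^i
   - k_{12}^i R_1^i R_2^i \sin(\varphi_1^i-\varphi_2^i)$ on chain 1 and the
  variant-dependent analogue on chain 2 (below);
* **environment** — linear viscous drag $-\beta_j^i \dot\varphi_j^i$ from
  the surrounding liquid, plus a spatially uniform periodic driving torque
  $F_0\cos\omega t$ applied to every pendulum of both chains ($\omega = 0$
  is a constant torque).

Chain 1 carries the user's nucleotide sequence; chain 2 is its Watson–Crick
complement, and each base looks up its own row of the parameter table.
The rest configuration is $\varphi_1^i = 0$, $\varphi_2^i = \pi$, all
angular velocities zero, and the Cauchy problem is started there. Angles
are *not* wrapped to $(-\pi,\pi]$: the chain-mean observable and the
trajectory plots need accumulated angles.

The model deliberately keeps the hydrogen-bond coupling elastic at all
amplitudes: it cannot produce open states (locally broken base pairs), and
no stacking, helicoidal, or hydrodynamic refinements are included.

## The two sign conventions for chain 2

The chain-2 pairing torque is shipped in two variants because the two
natural formulations disagree and neither can be preferred on fidelity
*and* consistency grounds at once:

* `as_printed` (default): chain 2 feels
  $+k_{12}R_1(R_1{+}R_2)\sin\varphi_2 - k_{12}R_1R_2\sin(\varphi_1-\varphi_2)$.
  The boundary rows are taken as the one-neighbour specialization of the
  interior rows (the boundary rows of the original formulation are
  internally inconsistent; this is the minimal repair). These torques do
  **not** derive from any potential: the cross terms of the two chains carry the *same* sign, which
  makes the coupling circulatory. Small systems (a single pair, short
  chains, homopolymers) are nevertheless linearly stable around the rest
  state, but long heterogeneous duplexes are flutter-unstable: any
  perturbation grows at $\sim 10^{10}\,\mathrm{s^{-1}}$ until the bounded
  sine torques saturate against the damping, after which the chain-mean
  angle wanders over tens to hundreds of radians with a red, broadband
  spectrum. This is the faithful behavior of the original sign convention.
* `potential_consistent`: chain 2 feels the negative gradient of the pair
  potential
  $k_{12}[R_1(R_1{+}R_2)(1-\cos\varphi_1) + R_2(R_1{+}R_2)(1-\cos\varphi_2)
   + R_1R_2(1-\cos(\varphi_1-\varphi_2))]$, i.e.
  $-k_{12}R_2(R_1{+}R_2)\sin\varphi_2 + k_{12}R_1R_2\sin(\varphi_1-\varphi_2)$.
  The undriven, undamped system is then conservative, which is what makes
  quantitative validation (energy conservation, gradient checks) possible.
  In this variant the rest state $\varphi_2 = \pi$ sits on a saddle of the
  pair potential, so the duplex promptly rolls into the
  $(\varphi_1,\varphi_2) \approx (0,0)$ well and performs bounded, damped
  oscillations about it with an intrinsic frequency near
  $10^{11}\,\mathrm{Hz}$.

The frequency-independence and substitution experiments below use
`potential_consistent`: it is the variant in which "the dominant frequency
of the mean angular deviation" is a well-posed quantity (bounded
oscillations with a resolvable spectral peak), and its phenomenology —
a transient of a few tenths of a nanosecond during which all drive
frequencies look alike, then decaying periodic components whose frequency
is set by the molecule rather than the drive — is the phenomenology the
experiments are designed to probe. `build_system()` defaults to
`as_printed` for fidelity; every experiment takes the variant as a
configuration field.

## Parameters

The built-in table (`default_param_table()`), in SI units after scaling:

| base | $I$ (kg m²) | $R$ (m) | $K$ (J) | $\beta$ (J s) |
|------|-------------|---------|---------|----------------|
| A | 7.61e-44 | 5.80e-10 | 2.35e-18 | 4.25e-34 |
| T | 4.86e-44 | 4.80e-10 | 1.61e-18 | 2.91e-34 |
| G | 8.22e-44 | 5.70e-10 | 2.27e-18 | 4.10e-34 |
| C | 4.11e-44 | 4.70e-10 | 1.54e-18 | 2.79e-34 |

with pair stiffnesses $k_{12}$(A·T) = 6.20e-2 N/m and
$k_{12}$(G·C) = 9.60e-2 N/m (three hydrogen bonds for G·C, hence stiffer).
Dissipation is assigned per pendulum from its own base's row on both
chains. The drive defaults to $F_0 = 0.5\times10^{-22}$ J. A custom table
can be loaded from YAML with `read_param_table()`.

## Numerics

The $4n$-component first-order system is integrated with classical
fixed-step RK4 in compiled code. Numerical choices that matter:

* **Step size.** The fastest linearized modes are the torsion modes,
  $\omega_{\max}\approx\sqrt{4K/I}\approx 1.1\times10^{13}\,\mathrm{s^{-1}}$
  for Table values; the default $dt = 10^{-14}$ s resolves them with
  $\omega\,dt \approx 0.1$. `check_dt()` verifies a given system by step
  halving until the post-transient amplitude moves by less than 0.1%.
  Measured accuracy at the default step (against both an adaptive
  reference integrator and Richardson extrapolation): the global
  trajectory error over 1 ns stays below $10^{-5}$ of the angular
  excursion (typically $\approx 3\times10^{-6}$); users needing
  $10^{-6}$-level trajectories should use $dt \lesssim 2.5\times10^{-15}$ s.
* **Exact equilibrium.** Chain-2 sines are evaluated through the deviation
  $\psi_2 = \varphi_2 - \pi$ (an exact identity), so the rest state is an
  exact floating-point fixed point of the undriven system rather than
  drifting at the $\sin(\pi)\sim10^{-16}$ level.
* **Energy.** `total_energy()` is defined for the conservative variant on
  homopolymers only: with site-varying $K$ the model's torsion force is
  not the gradient of a symmetric spring energy, so no exact invariant
  exists for heterogeneous chains. Each chain uses its own (constant) $K$
  in the spring terms. Drift over 1 ns at the default step is
  $\lesssim 10^{-7}$ relative.
* **Recording.** The chain-mean series of both chains is always recorded;
  full per-site states only on request (`record_full`), since they cost
  $n\times$ the memory. The stride defaults to whatever keeps at most
  $10^5$ snapshots.
* **Blow-up.** A non-finite state aborts with the step index and the
  largest angle reached — with the default step this only happens for
  deliberately absurd settings.

## Observables

The primary observable is the unweighted site mean of the chain-1 angles,
$\bar\varphi_1(t) = \tfrac1n\sum_i \varphi_1^i(t)$. Summaries exclude an
initial transient (default cutoff $0.5\times10^{-9}$ s, the interval over
which runs at all drive frequencies look alike before their periodic
components separate; configurable).

* `amplitude()` defaults to half the peak-to-trough range of the
  mean-subtracted post-cutoff segment. The signals are non-sinusoidal and
  their periodic components decay, so half-range tracks what a trajectory
  plot shows; `rms` ($\sqrt2\,\mathrm{sd}$, exact for a sinusoid) and
  `max_abs` are provided because the choice is not innocent — the
  substitution report therefore tabulates all three.
* `dominant_frequency()` is the largest non-zero-frequency peak of the
  Hann-windowed periodogram of that segment, refined by parabolic
  interpolation, reported as ordinary frequency (cycles/s; compare a drive
  via $f = \omega/2\pi$). Its raw resolution, 1/(segment duration), is
  attached as an attribute, and segments too short to resolve anything are
  rejected rather than summarized.
* `time_resolved_frequency()` slides a fixed window over the segment. It
  is a descriptive tool only: the drift of the intrinsic frequency with
  time is displayed, not modelled.

## The experiments

`run_frequency_sweep()` simulates one sequence under a ladder of drive
frequencies (default $10^{11}$ down to $10^8\,\mathrm{s^{-1}}$ plus
$\omega=0$) and reports each run's post-transient amplitude and dominant
frequency together with the relative deviation of that frequency from the
constant-force ($\omega = 0$) run, which is always included as the
internal reference. On a seeded synthetic heterogeneous 100-mer in the
conservative variant, the driven runs' dominant frequencies sit within a
few percent of the $\omega=0$ reference — about $1.35\times10^{11}$ Hz —
while differing from the drive frequencies themselves by two orders of
magnitude: the oscillation frequency is a property of the molecule, not
of the drive. This comparison is scale- and window-sensitive: the
intrinsic component decays at $\beta/2I \approx 3\times10^9\,\mathrm{s^{-1}}$
and partially cancels in the site mean of long duplexes, so at $n = 980$
with a multi-nanosecond window the persistent driven steady state wins
the periodogram and the dominant frequency locks to $\omega/2\pi$, as
linear response requires once transients die. The drive-independent
intrinsic oscillation is a property of the post-transient *decaying*
component, which is why the documented preset for this experiment is
$n = 100$ over 5 ns.

`run_substitution_experiment()` replaces a centered block of chain 1 with
a homopolymer (40A/40T/40G/40C and 100A by default; for $n = 980$ the
40-base block spans positions 471–510 and the 100-base block 441–540,
preserving the stated block lengths) and compares amplitudes at a fixed
drive (default $\omega = 10^8\,\mathrm{s^{-1}}$), reporting the pairwise
ratio matrix, the amplitude ordering, and the estimator-sensitivity
columns. Which variant ends up largest depends on the base sequence
surrounding the block: published per-gene orderings and ratios are
reproduced by supplying that gene's FASTA, not by the synthetic stand-in.

## What the synthetic generator does and does not emulate

`random_sequence()` draws i.i.d. bases with a target GC fraction under a
fixed seed. It reproduces the *composition* and length of a natural
heterogeneous sequence (and hence the distribution of local stiffness and
inertia along the duplex), but none of its correlation structure — codon
bias, repeats, isochores. Passing tests on synthetic sequences therefore
validate the machinery and the sequence-independent physics
(equilibrium exactness, conservation, order of accuracy, drive
independence of the intrinsic frequency); they do not certify any claim
tied to one specific natural gene. The 980-base default mirrors the length
of the interferon-alpha-17 gene used as the standard test case, whose
sequence must be supplied by the user as a FASTA file to reproduce
per-gene numbers.

## Problem sizes used by the test suite and acceptance script

Desk-scale checks run at $n \le 20$ and $t \le 1$ ns; the
drive-independence check runs the $n = 100$ preset of the 980-base
experiment at $t_{\mathrm{end}} = 5$ ns; the substitution battery runs at
full $n = 980$ with $t_{\mathrm{end}} = 1.5$ ns (post-transient window
1 ns, i.e. $\sim$135 periods of the intrinsic oscillation). The
acceptance script runs the sweep at full scale ($n = 980$,
$t_{\mathrm{end}} = 5$ ns). These sizes are the package's documented
presets; all are configurable.

## Known limitations

* The original (`as_printed`) sign structure admits no energy functional,
  so no quantitative accuracy statement beyond oracle agreement is
  possible for it; on long heterogeneous duplexes it is flutter-unstable
  and its "amplitude" measures a saturated chaotic wander.
* `total_energy()` is homopolymer-only (see above).
* The RK4 integrator is fixed-step by design; the adaptive method is used
  only as a test oracle. Production runs needing guaranteed local error
  control should halve `dt` and compare, or use `check_dt()`.
* Frequency estimates inherit periodogram resolution: a post-transient
  window of $T$ seconds cannot distinguish frequencies closer than
  $1/T$. `dominant_frequency()` refuses windows that cannot resolve
  anything, and `run_summary()` records `NA` in that case.
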