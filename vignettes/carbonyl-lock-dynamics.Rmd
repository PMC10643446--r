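---
title: "Surface hopping, relaxation coordinates, and the carbonyl-lock mechanism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface hopping, relaxation coordinates, and the carbonyl-lock mechanism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(CoInPath)
```

## The problem

Non-aromatic biomolecular assemblies (amide crystals, amyloid fibrils) can
fluoresce even though their isolated chromophores decay non-radiatively
within tens of femtoseconds. The decisive quantity is access to a conical
intersection (CoIn): a nuclear geometry where the S1 and S0 adiabatic
surfaces touch and the excited state drains into the ground state without
emitting. Whether a system is dark or emissive then hinges on whether its
environment lets the gap-closing nuclear motion - typically a large CO
elongation, often concerted with a proton transfer - run free or stiffens
it. CoInPath packages this diagnostic chain at model scale: surface-hopping
dynamics on analytic two-state surfaces, data-driven extraction of the
relaxation coordinate from trajectory swarms, and the ensemble statistics
that distinguish a freely decaying system from a "locked", trapped one.

## Dynamics: decoherence-corrected fewest-switches surface hopping

Nuclei move classically (velocity Verlet) on one adiabatic surface of a
two-state diabatic model; the electronic amplitudes $c_j$ follow the
time-dependent Schrödinger equation in the adiabatic basis,

$$ i\,\dot c_j = c_j E_j - i \sum_i c_i\, \dot{\mathbf R}\cdot\mathbf d_{ij}, $$

with the nonadiabatic coupling vector obtained from the diabatic model in
Hellmann-Feynman form, $\mathbf d_{01} = \mathbf u_0^{\!\top}
(\partial V/\partial \mathbf R)\, \mathbf u_1 / (E_1 - E_0)$. Per nuclear
step the hop probability from the occupied state $i$ is the accumulated
fewest-switches integrand

$$ P_{i\to j} = -2\int_t^{t+\Delta t}
  \mathrm{Re}\!\left[\frac{c_i^* c_j\, \dot{\mathbf R}\cdot\mathbf d_{ij}}
  {|c_i|^2}\right]\mathrm dt , $$

clamped to $[0,1]$ (the real part is the only reading under which the
expression is a probability). Accepted hops rescale velocities along
$\mathbf d_{01}$ so total energy is conserved; energetically frustrated
upward hops are rejected with velocities unchanged (no velocity reversal; a
flag is not offered because the models here never produced a case where it
matters). Inactive amplitudes are damped by the energy-based decoherence
factor $e^{-\Delta t/\tau}$ with $\tau = \hbar/|E_j - E_i|\,(1 +
C/E_\mathrm{kin})$ and the working value $C = 0.1$; the active amplitude is
rescaled to restore the total norm, the standard companion step without
which population leaks.

Numerical choices that matter:

* **Electronic sub-stepping.** The amplitudes advance by fourth-order
  Runge-Kutta over 20 substeps per nuclear step, with energies and the
  scalar coupling interpolated linearly and the mean energy removed as a
  global phase. On scattering benchmarks the pre-renormalization norm
  deviation is at rounding level ($<10^{-15}$ per step); across narrow
  crossings of the lock model it stays below $10^{-4}$ and is logged.
* **Hop granularity.** One stochastic decision per nuclear step, using the
  substep-accumulated integral, matching the integral form above.
* **Near-degeneracy.** The NACV denominator is floored at $10^{-8}$
  hartree (occurrences counted in the trajectory metadata); below the
  0.1 eV stop criterion no hop is forced - the hopping integrand remains
  in charge of every transition.
* **Eigenvectors.** The 2x2 adiabatic eigenvectors use the closed form
  whose norm is bounded below by the level splitting (branching on the
  sign of the diabatic asymmetry), and their phase is made continuous
  between frames by sign flips; this is what keeps $\mathbf d_{01}$ smooth
  through the avoided crossing.
* **Units.** All dynamics is in Hartree atomic units; file and function
  interfaces use fs, eV and Angstrom with fixed conversions
  (`unitConstants()`).
* **Energy-drift bookkeeping.** Velocity Verlet has a bounded oscillatory
  energy error (the shadow Hamiltonian); `energyDrift()` therefore reports
  the secular trend - the difference between mean total energy over the
  final and initial 10% of frames - which is the quantity bounded at
  $10^{-5}$ hartree in the checks.

## The exact benchmark

`propagateWavepacket()` integrates the same two-state problem exactly on a
1D grid (split-operator: spectral kinetic steps, closed-form 2x2 matrix
exponentials for the potential half-steps) in the *diabatic* picture,
which has no coupling-vector singularity at the crossing; adiabatic
populations are projected only at analysis time. On the standard single
avoided crossing (`buildTullyModel()`, incoming momentum 20 a.u., Gaussian
width 1 bohr), 2000 hopping trajectories with Wigner-sampled initial
conditions reproduce the exact final lower-state population to better than
0.01 - well inside the 0.05 band the package asserts. This benchmark runs
with the decoherence correction disabled: it validates the hopping core
(TDSE, couplings, stochastic algorithm, velocity rescaling). The
energy-based damping is designed for repeated-crossing intramolecular
dynamics; applied to a single ballistic passage it re-inflates the active
amplitude between consecutive integration steps of one crossing event and
biases the branching by about 0.07 - a documented limitation of the
correction, not of its implementation, and the reason the dynamics of
interest (the lock models, many vibrational periods per crossing) runs
with it enabled.

## The carbonyl-lock model family

`buildCarbonylLockModel()` is a two-coordinate caricature of the mechanism:
a stretch $r$ (CO-elongation-like: reduced mass 12500 a.u., force constant
0.40 hartree/bohr$^2$, a ~1240 cm$^{-1}$ oscillator) whose elongation
closes the vertical gap linearly, a proton-transfer-like spectator $q$
(proton mass, 0.35 hartree/bohr$^2$) with a weak gap modulation, a constant
diabatic coupling $v_{12}$ (a Gaussian-damped variant sits behind
`couplingDecay`), and a harmonic lock $\tfrac12 k_\mathrm{lock}(r-r_0)^2$
added to *both* states - the model analogue of a hydrogen bond stiffening
the carbonyl. Defaults place the vertical gap at 4 eV, the diabatic seam at
an elongation of 0.44 A, and the minimum adiabatic gap $2v_{12}$ at
0.082 eV, below the 0.1 eV crossing criterion. The seam's position does not
move with the lock; what the lock changes is whether the excited-state
oscillation *reaches* it: `criticalLockStiffness()` gives the closed-form
threshold $2\,\mathrm{slope}_r^2/\mathrm{gap}_0 - k_r$ (0.020
hartree/bohr$^2$ at defaults) beyond which the seam is energetically out of
reach from equilibrium, and thermal initial conditions smear the decay
fraction around it. The margin is deliberately soft so that a constraint of
100 kcal/mol/A$^2$ - the package reads the constraint constant as *per
squared Angstrom*, the only reading with harmonic-energy units, and
documents that the source convention is printed ambiguously as
"kcal/mol A" - is enough to flip the system from decaying to trapped, while
the same constraint on the spectator changes nothing: the specificity
experiment that identifies which degree of freedom carries the decay.

Model experiments use a 0.1 fs step rather than the 0.5 fs interface
default: with $v_{12}$ held below the crossing criterion the avoided
crossing is only a few hundredths of a bohr wide, and the step must resolve
the coupling peak for the hop integral to see it. Ground-state sampling at
300 K runs one independent Langevin (BAOAB) chain per trajectory, seeded
from the harmonic Boltzmann distribution at the minimum with a 1 ps burn-in
at friction 1 ps$^{-1}$ - unbiased starts, mutually independent members,
and fully reproducible from the base seed (member $i$ hops with seed
$\mathrm{base}+i-1$, so swarms sharing a base seed are paired).

## The relaxation coordinate

Given a swarm, the decay direction is estimated per coordinate as

$$ c_i = \frac{\left\langle (x_i - \bar x_i)\,
  \mathrm{Sign}[-\Delta E^D]\, e^{-|\Delta E^D|/\alpha k T}\right\rangle}
  {\sqrt{\langle (x_i-\bar x_i)^2\rangle\,
   \langle e^{-2|\Delta E^D|/\alpha k T}\rangle}} , $$

with $\alpha = 100$, $T = 300$ K, and the diabatic gap $\Delta E^D$
reconstructed from the adiabatic one by swapping state identities from the
first crossing frame on (the exact-crossing frame belongs to the
post-crossing side - a tie-break, made explicit). The Arrhenius-like factor
concentrates weight on near-crossing frames; the sign term orients the
vector from excited-state toward ground-state configurations; the
normalization bounds every component by 1 (Cauchy-Schwarz), with the 0/0
case of a frozen coordinate mapped to 0. Decaying trajectories contribute
all their frames (both sides of the crossing - the sign term needs both);
non-decaying ones are excluded unless requested, and an optional window
around the crossing is exposed because the averaging span is a genuine
free choice. Kabsch alignment to the pooled mean (one fixed-point
iteration: mean, align, re-mean) is on by default for Cartesian input;
positionally restrained source data make it nearly moot, but generic input
drifts. Mass weighting is off by default - the estimator is written in bare
Cartesian fluctuations - and available as a flag.

## What the synthetic generator emulates - and what it does not

`generateMockDimerTrajectories()` fabricates Cartesian trajectories of a
12-atom two-fragment amide toy with a *known* decay direction: one planted
mode (the first CO distance, along a coordinate axis so the planted
Cartesian direction has equal-magnitude components) ramps up and closes a
linear gap function, spectator modes fluctuate as stationary Gaussian noise
with coordinate variance `noiseSigma`^2, and every atom carries isotropic
jitter (0.3 x `noiseSigma` per component; the planted-mode series absorb
the difference so spectator coordinate variances come out exactly on
target). Displacements run along coordinate-conjugate directions
($\nabla g/|\nabla g|^2$), so planted modes are translation- and
torque-free and the ground truth survives superposition. Defaults - 0.3 A
decay amplitude, 0.05 A noise, 500 frames at 0.5 fs, 4 eV vertical gap
closing at 0.24 A of elongation - put the crossing mid-trajectory with
noise large enough that the estimator works in its intended
correlation-dominated regime. The generator emulates the *statistical*
structure of excited-state swarms (thermal spectators, a gap-closing drift,
state flips at a 0.1 eV threshold); it does not emulate anharmonicity,
mode coupling, multiple competing crossings, or post-crossing vibrational
relaxation - so a passing planted-truth test certifies the estimator's
algebra and sign conventions, not its behavior on strongly mixed real
spectra.

## Ensemble statistics

`summarizeSwarm()` counts ground-state arrivals (no recrossing is allowed
once a trajectory reaches S0, matching the simulation protocol);
`detectCoinFrames()` takes the first below-threshold passage as the
crossing geometry and falls back, flagged, to the hop frame when coarse
stepping jumps the dip. Histograms over S0/S1/CoIn ensembles share one
binning, and excited-state ensembles exclude post-decay frames throughout.
The separation statistic $D = (\bar x_\mathrm{CoIn} - \bar x_{S1}) /
\sigma_{S1}$ uses the population standard deviation (switchable); it is 0
for identical distributions, 1 for a one-sigma shift, and invariant under
joint affine rescaling. The variance hierarchy of constrained swarms
reports *both* printed conventions - the fractional reduction
$(V_0 - V_j)/V_0$ and the normalized-variance form
$1 - [V_j - V_0]/V_0 = 1 + \mathrm{reduction}$, which reads 1 for no
effect and 2 for full suppression - because the two appear interchangeably
in the field and differ by a constant; neither is silently "corrected"
into the other.

One design point deserves emphasis: the $D$-ordering experiment (weak vs
strong lock) runs with a mild Langevin thermostat (5 ps$^{-1}$) on the
excited state. In strictly conservative dynamics a trajectory that can
reach the seam at all oscillates with an amplitude comparable to the
seam distance, so $\sigma_{S1}$ scales with the distance and $D$ is nearly
lock-independent. The thermostat stands in for vibrational cooling by the
crystal environment: survivors relax toward the excited-state minimum,
their fluctuations narrow, and reaching the seam becomes the rare,
large-$D$ excursion that distinguishes the trapped (emissive) regime from
the freely decaying one. Problem sizes throughout the tests - 200
trajectories per condition, 2000 for the scattering benchmark, $10^5$
pooled frames for the null-component check - are the sizes at which the
asserted properties are statistically unambiguous at model scale.

## Configuration and files

Swarm runs and analyses are driven either programmatically or from a YAML
configuration (`readRunConfig()`: sections `model`, `sampling`, `dynamics`,
`constraints` - with an explicit `index_base` key, since XYZ files carry no
native indexing convention - `analysis`, `output`, `seed`; unknown keys are
rejected by location). Cartesian trajectories interchange as extended XYZ
with per-frame `time_fs`/`E0_eV`/`E1_eV`/`state` comment fields, model
trajectories as TSV sidecars; JSON summaries and manifests embed the seed
and a configuration hash so any stochastic result can be audited. Exported
functions map one-to-one onto pipeline stages (generate, sample, run-swarm,
pathway, constrain-scan, stats, oracle), which is the package's command
surface; externally produced trajectories enter through the documented
XYZ+TSV schema.

## Known limitations

Two electronic states only; analytic model surfaces only (no electronic
structure); 1D exact benchmarking (the 2D lock model is validated by
properties - seam identities, lock monotonicity, constraint specificity -
not by exact dynamics); the decoherence correction is inappropriate for
single-passage scattering, as quantified above; and the amide-plane
degree of freedom is deliberately configuration, not code - which atom
quadruplet defines it in a given system is the user's call
(`improperDihedralCoordinate()`, reported as deviation from 180 degrees
when `planarity = TRUE`).
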