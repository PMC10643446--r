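# CoInPath

Surface-hopping dynamics and relaxation-pathway analysis for non-radiative
excited-state decay through conical intersections.

## The scientific problem

Isolated amide chromophores are dark: after photoexcitation to S1, a large
CO elongation (often concerted with a proton transfer) drives the system to
a conical intersection (CoIn) with the ground state within tens of
femtoseconds, and the energy is dissipated without emission. Yet amide
crystals and amyloid-like assemblies fluoresce. The proposed mechanism is a
*carbonyl lock*: a strong local interaction - typically a short hydrogen
bond of ~2.45 Å donor-acceptor length - stiffens the CO stretch, puts the
intersection seam out of thermal reach, and traps the emissive excited
state. CoInPath implements the computational chain used to diagnose this
mechanism at model scale, for photochemists and computational biophysicists
who want the analysis machinery without an electronic-structure code
attached.

## What the package computes

* **DC-TSH engine** - decoherence-corrected fewest-switches trajectory
  surface hopping on analytic two-state diabatic models (compiled core).
  Per nuclear step: classical nuclei on the active adiabat, TDSE
  propagation of the amplitudes
  $i\dot c_j = c_j E_j - i\sum_i c_i \dot R\, d_{ij}$, hop probability
  $P_{i\to j} = -2\int \mathrm{Re}[c_i^* c_j \dot R\, d_{ij}/|c_i|^2]\,dt$,
  energy-conserving velocity rescaling along the coupling vector, and
  energy-based decoherence
  $\tau_{ji} = \hbar/|E_j-E_i| \,(1 + C/E_\mathrm{kin})$ with $C = 0.1$.
  Harmonic bias constraints on chosen coordinates implement the trapping
  experiments.
* **Exact benchmark** - split-operator two-state wavepacket propagation in
  1D, the independent yardstick for the hopping populations.
* **Model systems** - a Tully-style single avoided crossing, a tunable
  carbonyl-lock family (gap-closing stretch + proton-transfer spectator +
  lock stiffness), thermal ground-state sampling at 300 K, and a mock
  amide-dimer generator that plants a known Cartesian decay direction in
  noisy 12-atom trajectories.
* **Relaxation coordinate** - the gap-weighted fluctuation estimator
  $c_i = \langle (x_i-\bar x_i)\,\mathrm{Sign}[-\Delta E^D]\,
  e^{-|\Delta E^D|/\alpha kT}\rangle / \sqrt{\langle (x_i-\bar x_i)^2
  \rangle \langle e^{-2|\Delta E^D|/\alpha kT}\rangle}$ with $\alpha=100$,
  the diabatic gap reconstructed by swapping state identities after the
  crossing, plus projection onto named internal coordinates.
* **Ensemble statistics** - decay fractions and times, CoIn-frame
  extraction (gap < 0.1 eV), S0/S1/CoIn histograms, the standardized
  separation $D = (\bar x_\mathrm{CoIn} - \bar x_{S1})/\sigma_{S1}$, and
  constrained-dynamics variance hierarchies.
* **I/O** - extended XYZ + TSV trajectory interchange, JSON
  summaries/manifests with embedded seeds, YAML run configuration.

## Worked example

```r
library(CoInPath)

free   <- buildCarbonylLockModel(carbonylLockParams(k_lock = 0))
locked <- buildCarbonylLockModel(carbonylLockParams(k_lock = 0.12))
cfg <- integratorConfig(dt = 0.1, tMax = 250)

summarizeSwarm(runSwarm(free,   200, cfg, baseSeed = 1))
#> SwarmSummary: 184/200 trajectories decayed (92.0%)
#>   median decay time 11.7 fs
summarizeSwarm(runSwarm(locked, 200, cfg, baseSeed = 1))
#> SwarmSummary: 2/200 trajectories decayed (1.0%)
#>   median decay time 62.0 fs
```

The unlocked model funnels almost every trajectory through the
intersection within a few CO vibrational periods; a lock of
0.12 hartree/bohr² traps the excited state for the whole 250 fs window.
Constraining the gap-closing stretch with a soft 100 kcal/mol/Å² harmonic
has the same signature, while the identical constraint on the spectator
coordinate changes nothing - the specificity that identifies the decay
mode:

```r
conS <- runSwarm(free, 200, cfg, list(constraintSpec(1)), baseSeed = 1)
conQ <- runSwarm(free, 200, cfg, list(constraintSpec(2)), baseSeed = 1)
#> decay: free 0.92 | stretch-constrained 0.38 | spectator-constrained 0.94
```

The relaxation-coordinate estimator recovers a planted decay direction
from noisy Cartesian swarms:

```r
spec  <- mockDimerSpec(seed = 42)
trajs <- generateMockDimerTrajectories(spec, 50)
vec   <- relaxationVector(poolEnsemble(trajs, pathwayConfig()),
                          pathwayConfig())
#> RelaxationVector: 36 components, |c| = 0.969, max |c_i| = 0.686
#> cosine to planted direction: 0.999

projectVector(vec, list(distanceCoordinate(1, 2, label = "CO"),
                        distanceCoordinate(3, 4, label = "NH")),
              mockDimerReference())
#>   label  projection       cosine       share
#> 1    CO  0.96850763  0.999321187 0.996958832
#> 2    NH -0.00295438 -0.003048375 0.003041168
```

The CO mode carries essentially the whole decay direction; the N-H
spectator's share is at the noise level.

## Further reading

The methods vignette (`vignettes/carbonyl-lock-dynamics.Rmd`) documents the
model assumptions, parameter meanings and defaults, numerical tolerances,
the design choices behind the synthetic generator, and known limitations.
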