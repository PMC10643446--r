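#' Integrator configuration for surface-hopping runs
#'
#' @param dt nuclear time step (fs).
#' @param nSubsteps electronic substeps per nuclear step (RK4 with linear
#'   interpolation of energies and couplings).
#' @param tMax maximum simulation time (fs).
#' @param gapStop adiabatic gap (eV) below which a ground-state trajectory is
#'   terminated (the crossing-region stop criterion).
#' @param stopAtGap whether to apply the gap stop criterion.
#' @param forbidRecrossing if `TRUE`, upward hop probabilities are forced to
#'   zero once the trajectory is on the ground state (no recrossing).
#' @param decoherenceC energy-based decoherence parameter C (dimensionless
#'   factor on 1/E_kin); the working value is 0.1.
#' @param decoherence enable the decoherence correction.
#' @param thermostat `"none"` (NVE) or `"langevin"`.
#' @param temperature thermostat temperature (K).
#' @param friction thermostat friction (1/ps).
#' @param xStop optional |x| bound on the first coordinate at which to stop
#'   (bohr); used for scattering runs on 1D models. `NA` disables it.
#' @return a named list.
#' @export
integratorConfig <- function(dt = 0.5, nSubsteps = 20, tMax = 250,
                             gapStop = 0.1, stopAtGap = TRUE,
                             forbidRecrossing = TRUE, decoherenceC = 0.1,
                             decoherence = TRUE, thermostat = "none",
                             temperature = 300, friction = 1,
                             xStop = NA_real_) {
  stopifnot(dt > 0, nSubsteps >= 1, tMax > 0, gapStop > 0,
            decoherenceC > 0, thermostat %in% c("none", "langevin"))
  list(dt = dt, nSubsteps = as.integer(nSubsteps), tMax = tMax,
       gapStop = gapStop, stopAtGap = stopAtGap,
       forbidRecrossing = forbidRecrossing, decoherenceC = decoherenceC,
       decoherence = decoherence, thermostat = thermostat,
       temperature = temperature, friction = friction, xStop = xStop)
}

#' Harmonic bias constraint on a generalized coordinate
#'
#' Used for the trapping experiments: a soft harmonic potential
#' `1/2 k (y - target)^2` added to both surfaces along an internal
#' coordinate. For model-space dynamics the coordinate must be a `"dof"`
#' coordinate (see [dofCoordinate()]).
#'
#' @param coordinate a [CoordinateDefinition-class] (or a bare 1-based dof
#'   index, taken as a `"dof"` coordinate).
#' @param k force constant in kcal/mol/A^2 (default 100). Note the source
#'   convention is printed as "kcal/mol A"; it is interpreted here as per
#'   squared Angstrom, the only reading with harmonic-energy units.
#' @param target reference value in Angstrom; `NA` means "value at
#'   excitation" (the trajectory's initial value).
#' @return a named list with the force constant converted to atomic units.
#' @export
constraintSpec <- function(coordinate, k = 100, target = NA_real_) {
  if (is.numeric(coordinate) && length(coordinate) == 1)
    coordinate <- dofCoordinate(as.integer(coordinate))
  stopifnot(is(coordinate, "CoordinateDefinition"), k >= 0)
  list(coordinate = coordinate, k = k, target = target,
       k_au = k * KFORCE2AU,
       target_au = if (is.na(target)) NA_real_ else target / BOHR2ANG)
}

.constraintMatrix <- function(constraints) {
  if (length(constraints) == 0) return(matrix(0, 0, 3))
  rows <- lapply(constraints, function(cs) {
    if (cs$coordinate@kind != "dof")
      stop("model-space dynamics supports constraints on 'dof' coordinates only")
    c(cs$coordinate@atoms[[1]], cs$k_au, cs$target_au)
  })
  do.call(rbind, rows)
}

#' Adiabatize a diabatic model at a geometry
#'
#' Diagonalizes the 2x2 diabatic matrix and returns sorted adiabatic
#' energies, analytic adiabatic gradients, the antisymmetric nonadiabatic
#' coupling vector `d01` (Hellmann-Feynman form
#' `u0' dV/dR u1 / (E1 - E0)`, magnitude capped when the gap falls below
#' 1e-8 hartree) and the diabatic-to-adiabatic eigenvector matrix. With a
#' previous frame's eigenvectors, phase continuity is enforced by sign flips.
#'
#' @param model a [DiabaticModel-class].
#' @param R coordinates (bohr).
#' @param prev optional previous 2x2 eigenvector matrix for phase continuity.
#' @return list: `energies` (hartree, sorted), `grad0`, `grad1`
#'   (hartree/bohr), `nacv` (1/bohr), `eigvec` (columns are eigenvectors),
#'   `capped`.
#' @export
adiabatize <- function(model, R, prev = NULL) {
  cpp_adiabatize(model@kindCode, .modelParams(model), as.numeric(R),
                 if (is.null(prev)) NULL else prev)
}

#' One velocity-Verlet step on the active surface
#'
#' Advances nuclei classically on the active adiabatic surface plus any
#' harmonic bias constraints (forces by chain rule through the coordinate).
#'
#' @param model a [DiabaticModel-class].
#' @param R,V coordinates (bohr) and velocities (a.u.).
#' @param active active surface (0 or 1).
#' @param dt time step (fs).
#' @param constraints list of [constraintSpec()] entries on dof coordinates.
#' @return list with advanced `R`, `V`, and the new frame's `adiabatic` data.
#' @export
propagateNuclei <- function(model, R, V, active = 1L, dt = 0.5,
                            constraints = list()) {
  dtau <- dt * FS2AU
  cmat <- .constraintMatrix(constraints)
  force <- function(ad, R) {
    f <- -(if (active == 0) ad$grad0 else ad$grad1)
    if (nrow(cmat) > 0) for (i in seq_len(nrow(cmat))) {
      j <- cmat[i, 1]
      tgt <- if (is.na(cmat[i, 3])) R[j] else cmat[i, 3]
      f[j] <- f[j] - cmat[i, 2] * (R[j] - tgt)
    }
    f
  }
  ad0 <- adiabatize(model, R)
  f0 <- force(ad0, R)
  if (!all(is.finite(f0))) stop("non-finite force; aborting trajectory")
  V1 <- V + 0.5 * dtau * f0 / model@masses
  R1 <- R + dtau * V1
  ad1 <- adiabatize(model, R1, prev = ad0$eigvec)
  f1 <- force(ad1, R1)
  if (!all(is.finite(f1))) stop("non-finite force; aborting trajectory")
  V1 <- V1 + 0.5 * dtau * f1 / model@masses
  list(R = R1, V = V1, adiabatic = ad1)
}

#' Propagate electronic amplitudes across one nuclear step
#'
#' Fourth-order Runge-Kutta over `nSubsteps` substeps of the adiabatic
#' time-dependent Schroedinger equation, with energies and the scalar
#' coupling `Rdot . d01` interpolated linearly between the bracketing
#' frames. The returned amplitudes are renormalized once; the pre-renormal-
#' ization deviation is reported.
#'
#' @param c complex length-2 amplitude vector (ground, excited).
#' @param Eprev,Ecur adiabatic energies at the step ends (hartree).
#' @param sigmaPrev,sigmaCur `Rdot . d01` at the step ends (1/a.u. time).
#' @param dt nuclear step (a.u. of time).
#' @param nSubsteps electronic substeps.
#' @param active active surface (0/1), used to accumulate the
#'   fewest-switches integrand.
#' @return list: `c` (renormalized amplitudes), `pHop` (accumulated hop
#'   probability active -> other, clamped to `[0, 1]`), `normDev`.
#' @export
propagateCoefficients <- function(c, Eprev, Ecur, sigmaPrev, sigmaCur,
                                  dt, nSubsteps = 20L, active = 1L) {
  out <- cpp_propagate_coeff(as.complex(c), Eprev, Ecur, sigmaPrev,
                             sigmaCur, dt, as.integer(nSubsteps),
                             as.integer(active))
  list(c = out$c, pHop = out$p_hop, normDev = out$norm_dev)
}

#' Fewest-switches hop probability for one interval
#'
#' Direct evaluation of the hopping integrand
#' `P = -2 Re(c_i* c_j sigma_ij) dt / |c_i|^2` (rectangle rule), clamped to
#' `[0, 1]`; negative values are truncated to zero. The real part is taken:
#' the only reading under which the expression is a probability.
#'
#' @param c complex amplitudes (ground, excited).
#' @param sigma scalar coupling `Rdot . d_ij` from the active state i to the
#'   target j (1/a.u. time).
#' @param dt interval (a.u. of time).
#' @param active index of the occupied surface (0/1).
#' @return hop probability in `[0, 1]`.
#' @examples
#' # occupied amplitude sqrt(0.8), target sqrt(0.2), 0.5 fs interval
#' hopProbability(c(sqrt(0.2), sqrt(0.8)), sigma = -0.01, dt = 20.67,
#'                active = 1)
#' @export
hopProbability <- function(c, sigma, dt, active = 1L) {
  ci <- c[active + 1L]
  cj <- c[2L - active]
  pa <- Mod(ci)^2
  if (pa < 1e-12) {
    warning("occupied-state population below 1e-12; probability set to 0")
    return(0)
  }
  p <- -2 * Re(Conj(ci) * cj * sigma) * dt / pa
  min(max(p, 0), 1)
}

#' Stochastic hop decision with velocity rescaling
#'
#' Draws a uniform number against the hop probability; on an accepted hop
#' velocities are rescaled along the nonadiabatic coupling direction so that
#' total energy is conserved. If the kinetic energy along the coupling
#' direction cannot pay an upward gap the hop is frustrated: rejected with
#' velocities unchanged.
#'
#' @param p hop probability (active -> other).
#' @param V velocities (a.u.).
#' @param masses per-dof masses (a.u.).
#' @param nacv coupling vector d01 (1/bohr).
#' @param energies adiabatic energies (hartree).
#' @param active occupied surface (0/1).
#' @param forbidRecrossing force upward probability to zero from the ground
#'   state.
#' @return list: `active`, `V`, `hopped`, `frustrated`.
#' @export
attemptHop <- function(p, V, masses, nacv, energies, active = 1L,
                       forbidRecrossing = TRUE) {
  target <- 1L - active
  if (forbidRecrossing && active == 0L) p <- 0
  if (p <= 0 || runif(1) >= p)
    return(list(active = active, V = V, hopped = FALSE, frustrated = FALSE))
  dE <- energies[active + 1L] - energies[target + 1L]
  rs <- cpp_rescale_velocities(V, masses, nacv, dE)
  if (!rs$ok)
    return(list(active = active, V = V, hopped = FALSE, frustrated = TRUE))
  list(active = target, V = rs$v, hopped = TRUE, frustrated = FALSE)
}

#' Energy-based decoherence damping
#'
#' Damps the inactive amplitude by `exp(-dt/tau)` with
#' `tau = hbar/|Ej - Ei| (1 + C/E_kin)` (atomic units, hbar = 1) and restores
#' the total norm through the active amplitude. At vanishing kinetic energy
#' the damping is skipped (the infinite-tau limit); at vanishing gap the
#' damping factor tends to 1, so there is no decoherence at the crossing.
#'
#' @param c complex amplitudes (ground, excited).
#' @param active occupied surface (0/1).
#' @param gap adiabatic gap (hartree).
#' @param ekin nuclear kinetic energy (hartree).
#' @param C decoherence parameter (default 0.1).
#' @param dt interval (a.u. of time).
#' @param enabled set `FALSE` to bypass.
#' @return damped, renormalized amplitudes.
#' @export
applyDecoherence <- function(c, active, gap, ekin, C = 0.1, dt,
                             enabled = TRUE) {
  if (!enabled) return(as.complex(c))
  cpp_apply_decoherence(as.complex(c), as.integer(active), gap, ekin, C, dt)
}

.trajectoryFromCpp <- function(out, model, config, seed, constraints) {
  n <- nrow(out$positions)
  hops <- if (nrow(out$hops) > 0)
    data.frame(frame = out$hops[, 1], from = out$hops[, 2],
               to = out$hops[, 3])
  else data.frame(frame = integer(), from = integer(), to = integer())
  fc <- if (out$first_crossing > 0) as.integer(out$first_crossing)
        else NA_integer_
  new("Trajectory",
      positions = out$positions, velocities = out$velocities,
      energies = out$energies * HA2EV, state = as.integer(out$state),
      coeffs = out$coeffs, nacv = out$nacv,
      time = out$time * AU2FS, hops = hops, firstCrossing = fc,
      cartesian = FALSE, elements = character(),
      metadata = list(model = model@label, config = config, seed = seed,
                      constraints = constraints,
                      etot = out$etot, ekin = out$ekin, sigma = out$sigma,
                      maxNormDev = out$max_norm_dev,
                      normWarnings = out$norm_warnings,
                      frustrated = out$frustrated,
                      nacvCapped = out$nacv_capped,
                      terminated = c("t_max", "gap_stop",
                                     "left_region")[out$terminated + 1L]))
}

#' Run one decoherence-corrected surface-hopping trajectory
#'
#' NVE (or Langevin-thermostatted) evolution with per-step order: nuclei ->
#' adiabatize -> electronic coefficients -> decoherence -> hop attempt.
#' The trajectory starts on the excited surface with amplitudes (0, 1)
#' unless stated otherwise and terminates at `tMax` or, if configured, when
#' the gap drops below `gapStop` on the ground state.
#'
#' @param model a [DiabaticModel-class].
#' @param R0,V0 initial coordinates (bohr) and velocities (a.u.).
#' @param config an [integratorConfig()] list.
#' @param constraints list of [constraintSpec()] entries.
#' @param seed integer seed controlling every stochastic element of the run.
#' @param active0 initial surface (default excited, 1).
#' @param c0 initial complex amplitudes.
#' @return a [Trajectory-class].
#' @export
runTrajectory <- function(model, R0, V0, config = integratorConfig(),
                          constraints = list(), seed = 1, active0 = 1L,
                          c0 = c(0 + 0i, 1 + 0i)) {
  stopifnot(is(model, "DiabaticModel"))
  set.seed(seed)
  nsteps <- as.integer(round(config$tMax / config$dt))
  gamma_au <- if (config$thermostat == "langevin")
    config$friction / 1000 / FS2AU else 0
  out <- cpp_run_trajectory(model@kindCode, .modelParams(model),
                            model@masses, as.numeric(R0), as.numeric(V0),
                            as.complex(c0), as.integer(active0),
                            config$dt * FS2AU, nsteps, config$nSubsteps,
                            config$gapStop / HA2EV, config$stopAtGap,
                            config$forbidRecrossing,
                            config$decoherenceC, config$decoherence,
                            .constraintMatrix(constraints),
                            gamma_au, KB_HA * config$temperature,
                            if (is.na(config$xStop)) NaN else config$xStop)
  .trajectoryFromCpp(out, model, config, seed, constraints)
}

#' Run a swarm of independent surface-hopping trajectories
#'
#' Initial conditions come from thermal ground-state sampling followed by
#' vertical excitation (positions and velocities kept, electronic state set
#' to the excited surface). Member i runs with seed `baseSeed + i - 1`, so
#' two swarms sharing `baseSeed` are seed-paired; results do not depend on
#' evaluation order.
#'
#' @param model a [DiabaticModel-class].
#' @param nTraj number of trajectories.
#' @param config an [integratorConfig()] list.
#' @param constraints list of [constraintSpec()] entries.
#' @param baseSeed base seed.
#' @param initialConditions optional list with `positions`/`velocities`
#'   matrices (rows recycled across the swarm); defaults to
#'   [sampleGroundState()] at the model temperature.
#' @param temperature,friction,burnin ground-state sampling settings.
#' @return list of [Trajectory-class] objects.
#' @export
runSwarm <- function(model, nTraj, config = integratorConfig(),
                     constraints = list(), baseSeed = 1,
                     initialConditions = NULL, temperature = NULL,
                     friction = 1, burnin = 1000) {
  stopifnot(nTraj >= 1)
  if (is.null(temperature))
    temperature <- if ("temperature" %in% names(model@params))
      unname(model@params["temperature"]) else 300
  if (is.null(initialConditions))
    initialConditions <- sampleGroundState(model, nTraj,
                                           temperature = temperature,
                                           friction = friction,
                                           burnin = burnin,
                                           seed = baseSeed + 1000000L)
  np <- nrow(initialConditions$positions)
  lapply(seq_len(nTraj), function(i) {
    j <- (i - 1L) %% np + 1L
    runTrajectory(model, initialConditions$positions[j, ],
                  initialConditions$velocities[j, ], config, constraints,
                  seed = baseSeed + i - 1L)
  })
}

#' Linear-trend total-energy drift of a trajectory
#'
#' Difference between the mean total energy over the final and initial
#' fractions of the run. Averaging over windows much longer than a
#' vibrational period isolates secular drift from the bounded oscillatory
#' energy error of the velocity-Verlet shadow Hamiltonian.
#'
#' @param traj a [Trajectory-class] from [runTrajectory()].
#' @param window fraction of frames in each window.
#' @return drift in hartree.
#' @export
energyDrift <- function(traj, window = 0.1) {
  e <- traj@metadata$etot
  n <- length(e)
  w <- max(1L, as.integer(round(window * n)))
  abs(mean(e[(n - w + 1L):n]) - mean(e[1:w]))
}

#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(object) nrow(object@positions))
#' @rdname accessors
#' @export
setMethod("activeState", "Trajectory", function(object) object@state)
#' @rdname accessors
#' @export
setMethod("energies", "Trajectory", function(object) object@energies)
#' @rdname accessors
#' @export
setMethod("positions", "Trajectory", function(object) object@positions)
#' @rdname accessors
#' @export
setMethod("hops", "Trajectory", function(object) object@hops)
#' @rdname accessors
#' @export
setMethod("firstCrossing", "Trajectory", function(object) object@firstCrossing)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames, %s coordinates, %d hop(s)\n",
              nrow(object@positions),
              if (object@cartesian) "Cartesian" else "model-space",
              nrow(object@hops)))
  if (!is.na(object@firstCrossing))
    cat(sprintf("  decayed at frame %d (t = %.1f fs)\n",
                object@firstCrossing, object@time[object@firstCrossing]))
  else cat("  stayed on the excited surface\n")
})
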