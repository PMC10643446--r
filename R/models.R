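#' Tully-style single avoided crossing model
#'
#' One-dimensional two-state diabatic model with
#' `V11(x) = A(1 - exp(-Bx))` for `x >= 0`, `-A(1 - exp(Bx))` for `x < 0`,
#' `V22 = -V11` and a Gaussian coupling `V12 = C exp(-D x^2)`. This is the
#' standard benchmark surface for validating hopping engines against exact
#' wavepacket dynamics.
#'
#' @param A,B,C,D model parameters (atomic units).
#' @param mass nuclear mass (atomic units).
#' @return a [DiabaticModel-class].
#' @examples
#' m <- buildTullyModel()
#' potential(m, 0)                 # V11 = V22 = 0, V12 = C at the crossing
#' @export
buildTullyModel <- function(A = 0.01, B = 1.6, C = 0.005, D = 1.0,
                            mass = 2000) {
  new("DiabaticModel", kind = "tully", kindCode = 1L, nDof = 1L,
      masses = mass, params = c(A = A, B = B, C = C, D = D),
      label = "tully-single-crossing")
}

#' Parameters of the carbonyl-lock model family
#'
#' Two-dimensional two-state model of an excited-state decay channel driven
#' by a gap-closing stretch (a CO-elongation-like coordinate `r`) next to a
#' proton-transfer-like spectator coordinate `q`:
#' `V11 = 1/2 k_r (r-r0)^2 + 1/2 k_q (q-q0)^2`,
#' `V22 = V11 + gap0 - slope_r (r-r0) - couple_q (q0-q)`, with a constant
#' diabatic coupling `v12` (optionally Gaussian-damped along `r` via
#' `couplingDecay`) and a harmonic "lock" `1/2 k_lock (r-r0)^2` added to both
#' states. Stiffening the lock narrows the thermally accessible `r` range and
#' eventually puts the diabatic seam out of energetic reach, trapping the
#' excited state - the mechanism by which a strong local interaction (e.g. a
#' short hydrogen bond) suppresses non-radiative decay.
#'
#' Defaults are chosen so that the unlocked model decays within a few CO
#' vibrational periods after vertical excitation at ~4 eV, while a lock of a
#' few hundredths of a hartree/bohr^2 traps it: `r0` 2.3 bohr (a 1.22 A CO
#' bond), `k_r` 0.40 hartree/bohr^2 with the CO reduced mass (a ~1240 cm^-1
#' stretch), seam elongation `gap0/slope_r` of 0.84 bohr (0.44 A) and a
#' minimum adiabatic gap `2 v12` of 0.082 eV, below the 0.1 eV crossing
#' criterion.
#'
#' @param r0,q0 equilibria of the stretch and spectator coordinates (bohr).
#' @param gap0 vertical gap at equilibrium (hartree); must be positive.
#' @param slope_r gap-closing rate along r (hartree/bohr).
#' @param couple_q gap modulation by q (hartree/bohr).
#' @param v12 diabatic coupling amplitude (hartree).
#' @param k_lock lock stiffness added to both states along r (hartree/bohr^2).
#' @param k_r,k_q harmonic force constants (hartree/bohr^2).
#' @param couplingDecay Gaussian damping rate of the coupling along r
#'   (1/bohr^2); 0 keeps the coupling constant.
#' @param temperature sampling temperature (K).
#' @param mass_r,mass_q coordinate masses (atomic units); defaults are the
#'   CO reduced mass and the proton mass.
#' @return named list of validated parameters.
#' @export
carbonylLockParams <- function(r0 = 2.3, q0 = 0, gap0 = 0.147,
                               slope_r = 0.1757, couple_q = 0.02,
                               v12 = 0.0015, k_lock = 0, k_r = 0.40,
                               k_q = 0.35, couplingDecay = 0,
                               temperature = 300,
                               mass_r = 12500, mass_q = 1836) {
  if (gap0 <= 0) stop("gap0 must be positive")
  if (k_lock < 0) stop("k_lock must be non-negative")
  if (temperature <= 0) stop("temperature must be positive")
  list(r0 = r0, q0 = q0, gap0 = gap0, slope_r = slope_r,
       couple_q = couple_q, v12 = v12, k_lock = k_lock, k_r = k_r,
       k_q = k_q, couplingDecay = couplingDecay, temperature = temperature,
       mass_r = mass_r, mass_q = mass_q)
}

#' Build a carbonyl-lock model
#'
#' @param p parameter list from [carbonylLockParams()].
#' @return a [DiabaticModel-class] with the temperature recorded in `params`.
#' @seealso [carbonylLockParams()] for the functional form,
#'   [criticalLockStiffness()] for the stiffness above which the seam is
#'   energetically unreachable from equilibrium.
#' @examples
#' m <- buildCarbonylLockModel(carbonylLockParams())
#' p <- carbonylLockParams()
#' V <- potential(m, c(p$r0 + p$gap0 / p$slope_r, p$q0))
#' V[2, 2] - V[1, 1]   # diabatic seam: 0
#' @export
buildCarbonylLockModel <- function(p = carbonylLockParams()) {
  if (p$gap0 <= 0) stop("gap0 must be positive")
  new("DiabaticModel", kind = "carbonyl_lock", kindCode = 2L, nDof = 2L,
      masses = c(p$mass_r, p$mass_q),
      params = c(r0 = p$r0, q0 = p$q0, gap0 = p$gap0, slope_r = p$slope_r,
                 couple_q = p$couple_q, v12 = p$v12, k_lock = p$k_lock,
                 k_r = p$k_r, k_q = p$k_q, couplingDecay = p$couplingDecay,
                 temperature = p$temperature),
      label = sprintf("carbonyl-lock (k_lock=%g)", p$k_lock))
}

#' Critical lock stiffness of a carbonyl-lock model
#'
#' The lock stiffness above which a classical trajectory started at the
#' ground-state equilibrium with zero kinetic energy can no longer reach the
#' diabatic seam on the upper surface: `k_lock* = 2 slope_r^2 / gap0 - k_r`.
#' Thermal initial conditions smear the decay fraction around this value.
#'
#' @param p parameter list from [carbonylLockParams()].
#' @return critical stiffness (hartree/bohr^2; can be negative if the bare
#'   model is already trapped).
#' @export
criticalLockStiffness <- function(p = carbonylLockParams()) {
  2 * p$slope_r^2 / p$gap0 - p$k_r
}

.modelParams <- function(object) {
  if (object@kindCode == 1L) unname(object@params[c("A", "B", "C", "D")])
  else unname(object@params[c("r0", "q0", "gap0", "slope_r", "couple_q",
                              "v12", "k_lock", "k_r", "k_q",
                              "couplingDecay")])
}

#' @rdname potential
#' @export
setMethod("potential", "DiabaticModel", function(object, R) {
  cpp_model_eval(object@kindCode, .modelParams(object), as.numeric(R))$V
})

#' @rdname modelGradient
#' @export
setMethod("modelGradient", "DiabaticModel", function(object, R) {
  g <- cpp_model_eval(object@kindCode, .modelParams(object), as.numeric(R))$dV
  rownames(g) <- c("dV11", "dV22", "dV12")
  g
})

#' @rdname accessors
#' @export
setMethod("nDof", "DiabaticModel", function(object) object@nDof)
#' @rdname accessors
#' @export
setMethod("masses", "DiabaticModel", function(object) object@masses)

setMethod("show", "DiabaticModel", function(object) {
  cat(sprintf("DiabaticModel '%s' (%s): %d state pair, %d dof\n",
              object@label, object@kind, 1L, object@nDof))
  cat("  params:", paste(sprintf("%s=%g", names(object@params),
                                 object@params), collapse = ", "), "\n")
})

#' Thermal ground-state sampling of a diabatic model
#'
#' Draws initial conditions for vertical excitation by running, per sample,
#' an independent Langevin (BAOAB) chain on the adiabatic ground surface.
#' Chains start from the harmonic Boltzmann draw at the ground-state minimum
#' and are decorrelated by a burn-in, so samples are unbiased and mutually
#' independent.
#'
#' @param model a [DiabaticModel-class].
#' @param n number of samples.
#' @param temperature temperature (K).
#' @param friction Langevin friction (1/ps).
#' @param burnin burn-in time per chain (fs).
#' @param dt Langevin time step (fs).
#' @param seed integer seed; sample i uses seed + i - 1.
#' @return list with matrices `positions` (bohr) and `velocities` (a.u.),
#'   one row per sample.
#' @export
sampleGroundState <- function(model, n, temperature = 300, friction = 1,
                              burnin = 1000, dt = 0.5, seed = 1) {
  stopifnot(is(model, "DiabaticModel"), n >= 1)
  ndof <- model@nDof
  kT <- KB_HA * temperature
  # harmonic frequencies at the ground-state minimum for the analytic seed
  Rmin <- if (model@kindCode == 1L) 0 else
    unname(model@params[c("r0", "q0")])
  h <- 1e-3
  kdiag <- vapply(seq_len(ndof), function(k) {
    e <- function(x) {
      Rk <- Rmin; Rk[k] <- Rk[k] + x
      a <- cpp_adiabatize(model@kindCode, .modelParams(model), Rk, NULL)
      a$energies[1]
    }
    (e(h) - 2 * e(0) + e(-h)) / h^2
  }, numeric(1))
  kdiag <- pmax(kdiag, 1e-6)
  gamma_au <- friction / 1000 / FS2AU     # 1/ps -> 1/a.u.
  nburn <- max(1L, as.integer(round(burnin / dt)))
  pos <- matrix(0, n, ndof)
  vel <- matrix(0, n, ndof)
  for (i in seq_len(n)) {
    set.seed(seed + i - 1L)
    R0 <- Rmin + rnorm(ndof) * sqrt(kT / kdiag)
    V0 <- rnorm(ndof) * sqrt(kT / model@masses)
    ch <- cpp_langevin_chain(model@kindCode, .modelParams(model),
                             model@masses, R0, V0, dt * FS2AU, nburn,
                             gamma_au, kT)
    pos[i, ] <- ch$R
    vel[i, ] <- ch$V
  }
  list(positions = pos, velocities = vel)
}
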