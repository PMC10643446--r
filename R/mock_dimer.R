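# Mock Cartesian trajectory fabrication: a small amide-dimer toy with a
# planted decay mode whose elongation closes the S1-S0 gap, spectator modes
# fluctuating as stationary noise, and per-atom thermal jitter. Serves as a
# planted-truth fixture for the relaxation-coordinate estimator.

#' Reference geometry of the mock amide dimer
#'
#' Twelve atoms arranged as two stacked N-C=O fragments. The first CO bond
#' (atoms 1-2) lies along the x axis, so displacing it produces a Cartesian
#' direction with components of equal magnitude - the planted decay
#' direction is then known exactly.
#'
#' @return a [Structure-class].
#' @export
mockDimerReference <- function() {
  xyz <- rbind(
    c( 0.00, 0.00, 0.00),  # C1  (decay CO carbon)
    c( 1.22, 0.00, 0.00),  # O2  (decay CO oxygen)
    c(-0.70, 1.10, 0.00),  # N3
    c(-0.30, 1.95, 0.00),  # H4
    c(-2.10, 1.20, 0.30),  # C5
    c(-2.50, 0.40, 0.90),  # H6
    c( 0.20, 0.30, 3.00),  # C7
    c( 1.35, 0.60, 3.10),  # O8
    c(-0.60, 1.30, 3.20),  # N9
    c(-0.20, 2.10, 3.30),  # H10
    c(-2.00, 1.30, 3.40),  # C11
    c(-2.60, 0.50, 3.60))  # H12
  makeStructure(c("C", "O", "N", "H", "C", "H",
                  "C", "O", "N", "H", "C", "H"), xyz)
}

#' Specification of the mock-dimer generator
#'
#' The planted modes are internal coordinates displaced along their
#' coordinate-conjugate Cartesian directions (`grad / |grad|^2`, so a mode
#' value change of s moves the coordinate by s to first order). Exactly one
#' mode has the `decay` role: its value ramps up linearly over
#' `rampFraction` of the run and then plateaus, closing the electronic gap
#' through `gapFunction`; spectator modes fluctuate as stationary Gaussian
#' noise with total coordinate variance `noiseSigma^2` (shared between the
#' mode series and isotropic per-atom jitter). The electronic state flips to
#' the ground state at the first frame whose gap falls below `threshold`.
#'
#' @param nAtoms atom count (fixed by the reference geometry, 12).
#' @param plantedModes list of `list(coord =, amplitude =, role =)` entries;
#'   role is `"decay"` or `"spectator"`. Defaults: the first CO distance as
#'   decay mode (amplitude 0.3 A), the N-H and second CO distances as
#'   spectators.
#' @param noiseSigma stationary noise scale (Angstrom).
#' @param nFrames frames per trajectory (>= 10).
#' @param dt frame spacing (fs).
#' @param gap0 vertical gap at the reference geometry (eV).
#' @param gapScale decay-coordinate displacement (Angstrom) at which the gap
#'   extrapolates to zero; the gap function is
#'   `gap(s) = gap0 (1 - s / gapScale)`, monotone decreasing.
#' @param gapFunction optional override, a monotone decreasing function of
#'   the decay-coordinate displacement (Angstrom) returning eV.
#' @param rampFraction fraction of the run over which the decay mode ramps.
#' @param threshold state-flip gap threshold (eV).
#' @param seed base seed; trajectory i uses `seed + i - 1`.
#' @return validated spec (list).
#' @export
mockDimerSpec <- function(nAtoms = 12,
                          plantedModes = NULL,
                          noiseSigma = 0.05, nFrames = 500, dt = 0.5,
                          gap0 = 4, gapScale = 0.25, gapFunction = NULL,
                          rampFraction = 0.6, threshold = 0.1, seed = 1) {
  if (nFrames < 10) stop("nFrames must be at least 10")
  if (is.null(plantedModes))
    plantedModes <- list(
      list(coord = distanceCoordinate(1, 2, label = "CO"),
           amplitude = 0.3, role = "decay"),
      list(coord = distanceCoordinate(3, 4, label = "NH"),
           amplitude = NA_real_, role = "spectator"),
      list(coord = distanceCoordinate(7, 8, label = "CO2"),
           amplitude = NA_real_, role = "spectator"))
  roles <- vapply(plantedModes, `[[`, character(1), "role")
  if (sum(roles == "decay") != 1)
    stop("exactly one planted mode must have role 'decay'")
  if (is.null(gapFunction))
    gapFunction <- function(s) gap0 * (1 - s / gapScale)
  sgrid <- seq(0, 1, length.out = 41)
  if (any(diff(gapFunction(sgrid)) >= 0))
    stop("gapFunction must be monotone decreasing in the decay coordinate")
  list(nAtoms = nAtoms, plantedModes = plantedModes,
       noiseSigma = noiseSigma, nFrames = as.integer(nFrames), dt = dt,
       gapFunction = gapFunction, rampFraction = rampFraction,
       threshold = threshold, seed = seed)
}

#' Planted Cartesian decay direction of a mock-dimer spec
#'
#' The unit 3N-vector along which the decay mode displaces the reference
#' geometry - the ground truth against which a recovered relaxation vector
#' is scored.
#'
#' @param spec a [mockDimerSpec()].
#' @return unit numeric vector of length 3N.
#' @export
plantedDirection <- function(spec) {
  ref <- mockDimerReference()
  dm <- spec$plantedModes[[which(vapply(spec$plantedModes, `[[`,
                                        character(1), "role") == "decay")]]
  g <- coordinateGradient(dm$coord, ref)
  v <- as.numeric(t(g))
  v / sqrt(sum(v^2))
}

#' Generate mock dimer trajectories with a planted decay mode
#'
#' @param spec a [mockDimerSpec()].
#' @param nTraj number of trajectories.
#' @return list of Cartesian [Trajectory-class] objects (positions in
#'   Angstrom, energies in eV).
#' @examples
#' trajs <- generateMockDimerTrajectories(mockDimerSpec(nFrames = 50), 2)
#' firstCrossing(trajs[[1]])
#' @export
generateMockDimerTrajectories <- function(spec, nTraj) {
  ref <- mockDimerReference()
  nat <- nrow(ref@xyz)
  x0 <- as.numeric(t(ref@xyz))            # frame layout: x1 y1 z1 x2 ...
  modes <- spec$plantedModes
  gvecs <- lapply(modes, function(m) {
    g <- as.numeric(t(coordinateGradient(m$coord, ref)))
    list(conj = g / sum(g^2), norm2 = sum(g^2))
  })
  decayIdx <- which(vapply(modes, `[[`, character(1), "role") == "decay")
  jitterSigma <- 0.3 * spec$noiseSigma
  n <- spec$nFrames
  tgrid <- (seq_len(n) - 1) * spec$dt
  ramp <- pmin(tgrid / (spec$rampFraction * tgrid[n]), 1)
  refVal <- evaluateCoordinate(modes[[decayIdx]]$coord, ref)

  lapply(seq_len(nTraj), function(i) {
    set.seed(spec$seed + i - 1L)
    X <- matrix(rep(x0, each = n), nrow = n)
    for (m in seq_along(modes)) {
      if (m == decayIdx) {
        sm <- modes[[m]]$amplitude * ramp
      } else {
        v <- spec$noiseSigma^2 - gvecs[[m]]$norm2 * jitterSigma^2
        sm <- rnorm(n, 0, sqrt(max(v, 0)))
      }
      X <- X + outer(sm, gvecs[[m]]$conj)
    }
    if (jitterSigma > 0)
      X <- X + matrix(rnorm(n * 3 * nat, 0, jitterSigma), n)
    sval <- vapply(seq_len(n), function(f)
      evaluateCoordinate(modes[[decayIdx]]$coord,
                         matrix(X[f, ], ncol = 3, byrow = TRUE)),
      numeric(1)) - refVal
    gap <- spec$gapFunction(sval)
    cross <- which(gap < spec$threshold)
    fc <- if (length(cross)) cross[1] else NA_integer_
    state <- rep(1L, n)
    if (!is.na(fc)) state[fc:n] <- 0L
    ener <- cbind(rep(0, n), abs(gap))
    hops <- if (!is.na(fc))
      data.frame(frame = fc, from = 1L, to = 0L)
    else data.frame(frame = integer(), from = integer(), to = integer())
    new("Trajectory", positions = X,
        velocities = matrix(0, 0, 0), energies = ener, state = state,
        coeffs = matrix(complex(0), 0, 0), nacv = matrix(0, 0, 0),
        time = tgrid, hops = hops, firstCrossing = fc, cartesian = TRUE,
        elements = ref@elements,
        metadata = list(model = "mock-amide-dimer", seed = spec$seed + i - 1L,
                        noiseSigma = spec$noiseSigma))
  })
}
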