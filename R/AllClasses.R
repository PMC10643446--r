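#' Two-state diabatic model Hamiltonian
#'
#' An analytic two-state diabatic potential matrix V(R) over `nDof` nuclear
#' degrees of freedom, standing in for an ab initio excited-state surface.
#' Build instances with [buildTullyModel()] or [buildCarbonylLockModel()].
#'
#' @slot kind model family, `"tully"` or `"carbonyl_lock"`.
#' @slot kindCode integer code used by the compiled kernels.
#' @slot nDof number of nuclear degrees of freedom.
#' @slot masses per-dof masses (atomic units).
#' @slot params named numeric parameter vector (atomic units).
#' @slot label free-text label.
#' @export
setClass("DiabaticModel",
  representation(kind = "character", kindCode = "integer", nDof = "integer",
                 masses = "numeric", params = "numeric", label = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@masses) != object@nDof)
      msg <- c(msg, "masses must have one entry per degree of freedom")
    if (any(object@masses <= 0)) msg <- c(msg, "masses must be positive")
    if (length(msg)) msg else TRUE
  })

#' Generalized internal coordinate definition
#'
#' A named internal coordinate evaluated on Cartesian structures (distance,
#' difference of two distances, improper dihedral) or directly on a model
#' degree of freedom (`"dof"`). Atom indices are 1-based.
#'
#' @slot kind one of `"distance"`, `"distance_difference"`,
#'   `"improper_dihedral"`, `"dof"`.
#' @slot atoms list of integer index tuples; for `"dof"` a single index into
#'   the model coordinate vector.
#' @slot label coordinate label used in output tables and error messages.
#' @export
setClass("CoordinateDefinition",
  representation(kind = "character", atoms = "list", label = "character"),
  validity = function(object) {
    kinds <- c("distance", "distance_difference", "improper_dihedral", "dof")
    if (!object@kind %in% kinds)
      return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
    n <- switch(object@kind, distance = list(2L), dof = list(1L),
                distance_difference = list(2L, 2L),
                improper_dihedral = list(4L))
    if (length(object@atoms) != length(n))
      return("wrong number of atom tuples for this coordinate kind")
    for (i in seq_along(n)) {
      tup <- object@atoms[[i]]
      if (length(tup) != n[[i]]) return("atom tuple has wrong length")
      if (anyDuplicated(tup)) return("atom indices within a tuple must be distinct")
      if (any(tup < 1)) return("atom indices are 1-based and must be >= 1")
    }
    TRUE
  })

#' Molecular structure (elements + Cartesian coordinates)
#'
#' @slot elements element symbols.
#' @slot xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @slot masses optional per-atom masses (may be empty).
#' @export
setClass("Structure",
  representation(elements = "character", xyz = "matrix", masses = "numeric"),
  validity = function(object) {
    if (ncol(object@xyz) != 3) return("xyz must have 3 columns")
    if (nrow(object@xyz) != length(object@elements))
      return("element list length must match coordinate rows")
    if (!all(is.finite(object@xyz))) return("coordinates must be finite")
    TRUE
  })

#' Surface-hopping / mock trajectory record
#'
#' The universal per-trajectory record produced by [runTrajectory()] and
#' [generateMockDimerTrajectories()] and consumed by all analyses. Positions
#' are in bohr for model-space trajectories (`cartesian = FALSE`) and in
#' Angstrom for Cartesian ones; energies are adiabatic and in eV; time in fs.
#'
#' @slot positions frames x nDof (or frames x 3N) coordinate matrix.
#' @slot velocities matching velocity matrix (atomic units; may be empty).
#' @slot energies frames x 2 adiabatic energies (eV).
#' @slot state per-frame active surface (0 or 1).
#' @slot coeffs frames x 2 complex electronic amplitudes (may be empty).
#' @slot nacv frames x nDof nonadiabatic coupling vector (1/bohr; may be empty).
#' @slot time per-frame time (fs).
#' @slot hops data.frame with columns frame/from/to.
#' @slot firstCrossing 1-based index of the first frame on the ground state,
#'   or `NA_integer_`.
#' @slot cartesian whether positions are Cartesian (Angstrom).
#' @slot elements element symbols for Cartesian trajectories.
#' @slot metadata list: model label, configuration, seed, counters.
#' @export
setClass("Trajectory",
  representation(positions = "matrix", velocities = "matrix",
                 energies = "matrix", state = "integer", coeffs = "matrix",
                 nacv = "matrix", time = "numeric", hops = "data.frame",
                 firstCrossing = "integer", cartesian = "logical",
                 elements = "character", metadata = "list"),
  validity = function(object) {
    n <- nrow(object@positions)
    msg <- character()
    if (nrow(object@energies) != n || length(object@state) != n ||
        length(object@time) != n)
      msg <- c(msg, "frame counts of positions/energies/state/time disagree")
    if (ncol(object@energies) != 2)
      msg <- c(msg, "energies must have two columns (S0, S1)")
    if (!is.na(object@firstCrossing)) {
      fc <- object@firstCrossing
      if (fc < 1 || fc > n) msg <- c(msg, "firstCrossing out of range")
      else if (object@state[fc] != 0L)
        msg <- c(msg, "firstCrossing must index a ground-state frame")
    }
    if (length(msg)) msg else TRUE
  })

#' Swarm-level decay summary
#'
#' @slot nTraj number of trajectories.
#' @slot nDecayed number that reached the ground state.
#' @slot decayTimes first-crossing times (fs) of the decayed members.
#' @slot coinFrames data.frame (traj, frame, time_fs, gap_eV, flagged).
#' @slot metadata list.
#' @export
setClass("SwarmSummary",
  representation(nTraj = "integer", nDecayed = "integer",
                 decayTimes = "numeric", coinFrames = "data.frame",
                 metadata = "list"),
  validity = function(object) {
    if (object@nDecayed > object@nTraj)
      return("nDecayed cannot exceed nTraj")
    TRUE
  })

#' Pooled fluctuation ensemble for relaxation-coordinate extraction
#'
#' Frames pooled across decaying trajectories, centered per coordinate, with
#' the per-frame signed diabatic gap.
#'
#' @slot fluct frames x K centered coordinate fluctuation matrix.
#' @slot deltaED per-frame signed diabatic gap (eV).
#' @slot means per-coordinate time averages removed during centering.
#' @slot reference mean structure/coordinates used for alignment/projection.
#' @slot provenance data.frame (traj, frame) covering every pooled row.
#' @slot cartesian whether coordinates are Cartesian.
#' @export
setClass("PooledEnsemble",
  representation(fluct = "matrix", deltaED = "numeric", means = "numeric",
                 reference = "numeric", provenance = "data.frame",
                 cartesian = "logical"),
  validity = function(object) {
    if (nrow(object@fluct) != length(object@deltaED))
      return("fluctuation rows and deltaED length disagree")
    if (!all(is.finite(object@deltaED)))
      return("every frame needs a finite diabatic gap")
    if (nrow(object@fluct) > 0 &&
        max(abs(colMeans(object@fluct))) > 1e-10)
      return("fluctuations must be centered per coordinate")
    TRUE
  })

#' S1 -> S0 relaxation pathway vector
#'
#' The gap-weighted, per-coordinate-normalized linear estimator of the decay
#' direction; every component is bounded by 1 in magnitude (Cauchy-Schwarz).
#'
#' @slot c component vector (dimensionless).
#' @slot config the configuration used (list).
#' @slot provenance pooled-frame provenance.
#' @export
setClass("RelaxationVector",
  representation(c = "numeric", config = "list", provenance = "data.frame"),
  validity = function(object) {
    if (any(abs(object@c) > 1 + 1e-9))
      return("components must satisfy |c_i| <= 1")
    TRUE
  })
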