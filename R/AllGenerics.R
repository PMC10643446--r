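#' Evaluate the diabatic potential matrix
#'
#' @param object a [DiabaticModel-class].
#' @param R numeric coordinate vector (bohr).
#' @return symmetric 2x2 matrix of diabatic energies (hartree).
#' @examples
#' m <- buildTullyModel()
#' potential(m, 0)[1, 2]   # = C parameter at the crossing
#' @export
setGeneric("potential", function(object, R) standardGeneric("potential"))

#' Evaluate the gradient of the diabatic potential matrix
#'
#' @param object a [DiabaticModel-class].
#' @param R numeric coordinate vector (bohr).
#' @return 3 x nDof matrix; rows are dV11, dV22, dV12 (hartree/bohr).
#' @export
setGeneric("modelGradient", function(object, R) standardGeneric("modelGradient"))

#' @rdname accessors
#' @export
setGeneric("nDof", function(object) standardGeneric("nDof"))
#' @rdname accessors
#' @export
setGeneric("masses", function(object) standardGeneric("masses"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("activeState", function(object) standardGeneric("activeState"))
#' @rdname accessors
#' @export
setGeneric("energies", function(object) standardGeneric("energies"))
#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("hops", function(object) standardGeneric("hops"))
#' @rdname accessors
#' @export
setGeneric("firstCrossing", function(object) standardGeneric("firstCrossing"))
#' @rdname accessors
#' @export
setGeneric("decayFraction", function(object) standardGeneric("decayFraction"))
#' @rdname accessors
#' @export
setGeneric("decayTimes", function(object) standardGeneric("decayTimes"))
#' @rdname accessors
#' @export
setGeneric("coinFrames", function(object) standardGeneric("coinFrames"))
#' @rdname accessors
#' @export
setGeneric("pathwayVector", function(object) standardGeneric("pathwayVector"))

#' Accessors for CoInPath objects
#'
#' Small read-only accessors: `nDof()`/`masses()` on models, `nFrames()`,
#' `activeState()`, `energies()`, `positions()`, `hops()`, `firstCrossing()`
#' on trajectories, `decayFraction()`, `decayTimes()`, `coinFrames()` on
#' swarm summaries and `pathwayVector()` on relaxation vectors.
#'
#' @param object the object to query.
#' @return the corresponding slot value (see the class documentation).
#' @name accessors
NULL
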