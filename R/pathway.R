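# Data-driven extraction of the S1 -> S0 relaxation coordinate: pooled
# coordinate fluctuations weighted by a signed, gap-dependent Arrhenius-like
# factor. Frames close to the crossing (small diabatic gap) dominate the
# average; the sign term orients the vector from excited-state toward
# ground-state configurations.

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

#' Configuration for relaxation-coordinate extraction
#'
#' @param alpha dimensionless width parameter of the Arrhenius-like gap
#'   weight `exp(-|dE|/(alpha k T))`; the working value is 100.
#' @param temperature temperature entering the weight (K).
#' @param align Kabsch-align Cartesian frames onto the pooled mean before
#'   computing fluctuations (one fixed-point iteration: mean, align,
#'   re-mean).
#' @param massWeight weight Cartesian fluctuations by sqrt(atomic mass).
#' @param includeNonDecaying admit trajectories that never reach the ground
#'   state (their diabatic gap is the adiabatic gap throughout).
#' @param window optional half-window (fs) around the crossing outside of
#'   which frames are dropped; `NULL` admits every frame.
#' @return named list.
#' @export
pathwayConfig <- function(alpha = 100, temperature = 300, align = TRUE,
                          massWeight = FALSE, includeNonDecaying = FALSE,
                          window = NULL) {
  stopifnot(alpha > 0, temperature > 0)
  list(alpha = alpha, temperature = temperature, align = align,
       massWeight = massWeight, includeNonDecaying = includeNonDecaying,
       window = window)
}

#' Reconstruct the signed diabatic gap of a trajectory
#'
#' Approximates the diabatic S1-S0 energy difference by the adiabatic gap
#' with the state identities swapped after the crossing: `+(E1-E0)` before
#' `firstCrossing`, `-(E1-E0)` from the crossing frame on (the exact-
#' crossing frame belongs to the post-crossing side). `Sign(-dE^D)` hence
#' flips from -1 to +1 at the crossing, orienting the relaxation vector from
#' excited- toward ground-state configurations. Trajectories without a
#' crossing keep the adiabatic gap (all positive).
#'
#' @param traj a [Trajectory-class].
#' @return numeric vector of signed gaps (eV), one per frame.
#' @export
reconstructDiabaticGap <- function(traj) {
  gap <- traj@energies[, 2] - traj@energies[, 1]
  fc <- traj@firstCrossing
  if (!is.na(fc)) {
    sgn <- rep(1, length(gap))
    sgn[seq(fc, length(gap))] <- -1
    gap <- gap * sgn
  }
  gap
}

.frameStructure <- function(row) matrix(row, ncol = 3, byrow = TRUE)

#' Pool trajectory frames into a centered fluctuation ensemble
#'
#' Admits decaying trajectories (all of them when `includeNonDecaying`),
#' optionally restricts to a time window around each crossing, optionally
#' Kabsch-aligns Cartesian frames onto the pooled mean, and centers every
#' coordinate. Provenance records each pooled frame exactly once.
#'
#' @param trajs list of [Trajectory-class] objects over the same
#'   coordinates.
#' @param config a [pathwayConfig()].
#' @return a [PooledEnsemble-class].
#' @export
poolEnsemble <- function(trajs, config = pathwayConfig()) {
  keep <- if (config$includeNonDecaying) seq_along(trajs)
          else which(!vapply(trajs, function(t) is.na(t@firstCrossing),
                             logical(1)))
  if (length(keep) == 0)
    stop("no admitted trajectories (none decayed and includeNonDecaying is FALSE)")
  rows <- list(); dEs <- list(); prov <- list()
  for (ti in keep) {
    tr <- trajs[[ti]]
    dE <- reconstructDiabaticGap(tr)
    idx <- seq_len(nrow(tr@positions))
    if (!is.null(config$window) && !is.na(tr@firstCrossing)) {
      tc <- tr@time[tr@firstCrossing]
      idx <- idx[abs(tr@time - tc) <= config$window]
    }
    if (length(idx) == 0) next
    rows[[length(rows) + 1]] <- tr@positions[idx, , drop = FALSE]
    dEs[[length(dEs) + 1]] <- dE[idx]
    prov[[length(prov) + 1]] <- data.frame(traj = ti, frame = idx)
  }
  X <- do.call(rbind, rows)
  if (is.null(X) || nrow(X) == 0) stop("zero admitted frames")
  dE <- unlist(dEs)
  cartesian <- trajs[[keep[1]]]@cartesian
  if (cartesian && config$align) {
    mean0 <- colMeans(X)
    for (f in seq_len(nrow(X)))
      X[f, ] <- as.numeric(t(
        kabschRmsd(.frameStructure(mean0),
                   .frameStructure(X[f, ]))$aligned))
  }
  mu <- colMeans(X)
  fl <- sweep(X, 2, mu)
  if (config$massWeight && cartesian) {
    el <- trajs[[keep[1]]]@elements
    m <- .ELEMENT_MASS[el]
    m[is.na(m)] <- 12
    fl <- sweep(fl, 2, rep(sqrt(m), each = 3), `*`)
    fl <- sweep(fl, 2, colMeans(fl))   # re-center exactly
  }
  new("PooledEnsemble", fluct = fl, deltaED = dE, means = mu,
      reference = mu, provenance = do.call(rbind, prov),
      cartesian = cartesian)
}

#' Compute the S1 -> S0 relaxation pathway vector
#'
#' Componentwise evaluation of the gap-weighted fluctuation estimator: for
#' coordinate i with centered fluctuations `dx_i(t)` and signed diabatic gap
#' `dE(t)`,
#' `c_i = < dx_i Sign(-dE) w > / sqrt(< dx_i^2 > < w^2 >)` with
#' `w = exp(-|dE| / (alpha k T))`. Every component is bounded by 1 in
#' magnitude (Cauchy-Schwarz); coordinates with vanishing fluctuation
#' (variance below 1e-12) get `c_i = 0`.
#'
#' @param ens a [PooledEnsemble-class].
#' @param config a [pathwayConfig()].
#' @return a [RelaxationVector-class].
#' @export
relaxationVector <- function(ens, config = pathwayConfig()) {
  if (nrow(ens@fluct) == 0) stop("empty ensemble")
  kT <- KB_EV * config$temperature
  w <- exp(-abs(ens@deltaED) / (config$alpha * kT))
  if (all(w < 1e-300))
    warning("all gap weights are numerically zero; vector returned as computed")
  sw <- sign(-ens@deltaED) * w
  num <- colMeans(ens@fluct * sw)
  v2 <- colMeans(ens@fluct^2)
  den <- sqrt(v2 * mean(w^2))
  cc <- ifelse(v2 < 1e-12, 0, num / ifelse(den > 0, den, 1))
  new("RelaxationVector", c = as.numeric(cc),
      config = config, provenance = ens@provenance)
}

#' @rdname accessors
#' @export
setMethod("pathwayVector", "RelaxationVector", function(object) object@c)

setMethod("show", "RelaxationVector", function(object) {
  cat(sprintf("RelaxationVector: %d components, |c| = %.3f, max |c_i| = %.3f\n",
              length(object@c), sqrt(sum(object@c^2)), max(abs(object@c))))
})

#' Project a relaxation vector onto named internal coordinates
#'
#' The contribution of each coordinate is the inner product between the
#' relaxation vector and the coordinate's normalized Cartesian gradient at a
#' reference structure; relative shares are reported over the requested set.
#'
#' @param vec a [RelaxationVector-class] over 3N Cartesian coordinates.
#' @param coords list of [CoordinateDefinition-class] objects.
#' @param reference a [Structure-class] consistent with the vector length.
#' @return data.frame: label, projection (signed inner product), cosine
#'   (projection / |c|), share (|projection| normalized over the set).
#' @export
projectVector <- function(vec, coords, reference) {
  cc <- vec@c
  if (length(cc) != 3 * nrow(reference@xyz))
    stop("vector length does not match 3N of the reference structure")
  proj <- vapply(coords, function(co) {
    g <- as.numeric(t(coordinateGradient(co, reference)))
    g <- g / sqrt(sum(g^2))
    sum(cc * g)
  }, numeric(1))
  labs <- vapply(coords, function(co) co@label, character(1))
  nv <- sqrt(sum(cc^2))
  tot <- sum(abs(proj))
  data.frame(label = labs, projection = proj,
             cosine = if (nv > 0) proj / nv else proj * 0,
             share = if (tot > 0) abs(proj) / tot else proj * 0)
}
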