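# Swarm-level statistics: decay fractions, crossing-frame extraction,
# ensemble histograms over internal coordinates, the standardized
# excited-state/crossing separation statistic, and the constrained-dynamics
# variance hierarchy.

#' Detect the conical-intersection frame of a trajectory
#'
#' Returns the frame at the first passage where the adiabatic gap drops
#' below the threshold (operationally, the crossing geometry). If the
#' trajectory hopped to the ground state without the gap ever dipping below
#' the threshold (coarse stepping), the hop frame is returned flagged.
#'
#' @param traj a [Trajectory-class].
#' @param threshold gap threshold (eV); must be smaller than the vertical
#'   gap at the first frame.
#' @return data.frame with zero or one row: `frame`, `time_fs`, `gap_eV`,
#'   `flagged`.
#' @export
detectCoinFrames <- function(traj, threshold = 0.1) {
  stopifnot(threshold > 0)
  gap <- traj@energies[, 2] - traj@energies[, 1]
  if (threshold >= gap[1])
    stop("threshold must be below the vertical gap at the first frame")
  below <- which(gap < threshold)
  empty <- data.frame(frame = integer(), time_fs = numeric(),
                      gap_eV = numeric(), flagged = logical())
  if (length(below) > 0) {
    f <- below[1]
    return(data.frame(frame = f, time_fs = traj@time[f], gap_eV = gap[f],
                      flagged = FALSE))
  }
  fc <- traj@firstCrossing
  if (!is.na(fc))
    return(data.frame(frame = fc, time_fs = traj@time[fc], gap_eV = gap[fc],
                      flagged = TRUE))
  empty
}

#' Summarize decay statistics of a trajectory swarm
#'
#' Counts trajectories whose active state reaches the ground state within
#' the run; decay times are the first-crossing times. Crossing frames are
#' collected with [detectCoinFrames()].
#'
#' @param trajs non-empty list of [Trajectory-class] objects.
#' @param threshold crossing gap threshold (eV).
#' @return a [SwarmSummary-class].
#' @export
summarizeSwarm <- function(trajs, threshold = 0.1) {
  if (length(trajs) == 0) stop("empty swarm")
  decayed <- which(!vapply(trajs, function(t) is.na(t@firstCrossing),
                           logical(1)))
  dt <- vapply(decayed, function(i)
    trajs[[i]]@time[trajs[[i]]@firstCrossing], numeric(1))
  cf <- lapply(decayed, function(i) {
    d <- detectCoinFrames(trajs[[i]], threshold)
    if (nrow(d)) cbind(traj = i, d) else NULL
  })
  cf <- do.call(rbind, cf)
  if (is.null(cf))
    cf <- data.frame(traj = integer(), frame = integer(),
                     time_fs = numeric(), gap_eV = numeric(),
                     flagged = logical())
  new("SwarmSummary", nTraj = length(trajs), nDecayed = length(decayed),
      decayTimes = as.numeric(dt), coinFrames = cf,
      metadata = list(threshold = threshold))
}

#' @rdname accessors
#' @export
setMethod("decayFraction", "SwarmSummary", function(object)
  object@nDecayed / object@nTraj)
#' @rdname accessors
#' @export
setMethod("decayTimes", "SwarmSummary", function(object) object@decayTimes)
#' @rdname accessors
#' @export
setMethod("coinFrames", "SwarmSummary", function(object) object@coinFrames)

setMethod("show", "SwarmSummary", function(object) {
  cat(sprintf("SwarmSummary: %d/%d trajectories decayed (%.1f%%)\n",
              object@nDecayed, object@nTraj,
              100 * object@nDecayed / object@nTraj))
  if (length(object@decayTimes))
    cat(sprintf("  median decay time %.1f fs\n", median(object@decayTimes)))
})

#' Standardized separation between excited-state and crossing distributions
#'
#' `D = (mean(coin) - mean(s1)) / sd(s1)`: the distance between the
#' coordinate distribution at the crossing and in the excited state, in
#' units of the excited-state spread. Large values mean the crossing
#' requires a rare distortion (the fluorescent, trapped regime); values
#' around 1 mean the crossing lies within ordinary excited-state
#' fluctuations. Invariant under jointly rescaling both samples.
#'
#' @param s1Values coordinate values over excited-state frames.
#' @param coinValues coordinate values at crossing frames.
#' @param coordinate label.
#' @param populationSD use the population standard deviation (default) or
#'   the sample one.
#' @return list: `coordinate`, `meanS1`, `meanCoIn`, `sdS1`, `D`.
#' @export
coinDistanceStat <- function(s1Values, coinValues, coordinate = "coord",
                             populationSD = TRUE) {
  if (length(s1Values) == 0 || length(coinValues) == 0)
    stop("both samples must be non-empty")
  s <- sd(s1Values)
  if (populationSD) s <- s * sqrt((length(s1Values) - 1) / length(s1Values))
  if (!is.finite(s) || s <= 0)
    stop("excited-state sample has zero spread")
  list(coordinate = coordinate, meanS1 = mean(s1Values),
       meanCoIn = mean(coinValues), sdS1 = s,
       D = (mean(coinValues) - mean(s1Values)) / s)
}

.excitedFrames <- function(traj) which(traj@state == 1L)

#' Coordinate histograms over the S0 / S1 / CoIn ensembles
#'
#' Excited-state frames exclude everything from the first crossing on; the
#' crossing ensemble comes from [detectCoinFrames()]; the ground-state
#' ensemble is either user-supplied sampling values or the post-decay
#' frames. All ensembles share one binning.
#'
#' @param trajs list of [Trajectory-class] objects.
#' @param coordinate a [CoordinateDefinition-class].
#' @param threshold crossing gap threshold (eV).
#' @param nBins bin count.
#' @param s0Values optional ground-state sampling values (same units);
#'   `NULL` uses post-decay frames.
#' @return list: `values` (named list of numeric vectors), `table`
#'   (long-format data.frame: coordinate, ensemble, bin_lo, bin_hi, count),
#'   `summary` (per-ensemble n/mean/sd, with empty ensembles flagged).
#' @export
ensembleHistograms <- function(trajs, coordinate, threshold = 0.1,
                               nBins = 30, s0Values = NULL) {
  s1 <- unlist(lapply(trajs, function(t) {
    v <- evaluateOnTrajectory(coordinate, t)
    v[.excitedFrames(t)]
  }))
  coin <- unlist(lapply(trajs, function(t) {
    d <- detectCoinFrames(t, threshold)
    if (nrow(d) == 0) return(numeric())
    evaluateOnTrajectory(coordinate, t)[d$frame]
  }))
  s0 <- if (!is.null(s0Values)) as.numeric(s0Values)
  else unlist(lapply(trajs, function(t) {
    v <- evaluateOnTrajectory(coordinate, t)
    v[t@state == 0L]
  }))
  vals <- list(S0 = s0, S1 = s1, CoIn = coin)
  allv <- unlist(vals)
  if (length(allv) == 0) stop("no frames in any ensemble")
  breaks <- seq(min(allv), max(allv), length.out = nBins + 1)
  breaks[1] <- breaks[1] - 1e-9
  breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
  tab <- do.call(rbind, lapply(names(vals), function(ens) {
    cnt <- if (length(vals[[ens]]))
      hist(vals[[ens]], breaks = breaks, plot = FALSE)$counts
    else rep(0L, nBins)
    data.frame(coordinate = coordinate@label, ensemble = ens,
               bin_lo = head(breaks, -1), bin_hi = tail(breaks, -1),
               count = cnt)
  }))
  summ <- do.call(rbind, lapply(names(vals), function(ens) {
    v <- vals[[ens]]
    data.frame(ensemble = ens, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               empty = length(v) == 0)
  }))
  list(values = vals, table = tab, summary = summ)
}

#' Constrained-dynamics variance hierarchy
#'
#' For every measured degree of freedom i and every constrained swarm j,
#' the variance `Var(Y_i^j)` over pooled excited-state frames is compared
#' with the unconstrained baseline `Var(Y_i^0)`. Both conventions are
#' reported: the fractional reduction `(V_0 - V_j)/V_0` and the printed
#' normalized-variance form `1 - [Var(Y_i^j) - Var(Y_i^0)]/Var(Y_i^0)`,
#' which equals 1 + reduction (no-effect cells read 1, full suppression 2).
#'
#' @param unconstrained list of [Trajectory-class] (baseline swarm).
#' @param constrained named list of swarms; names identify the constrained
#'   degree of freedom.
#' @param dofList named list of [CoordinateDefinition-class] objects to
#'   measure.
#' @return list: `var` (measured x constrained matrix), `baseline`,
#'   `reduction`, `printed`.
#' @export
varianceHierarchy <- function(unconstrained, constrained, dofList) {
  if (is.null(names(constrained)) || any(names(constrained) == ""))
    stop("constrained swarms must be named by their constrained DoF")
  poolVar <- function(trajs, coord) {
    v <- unlist(lapply(trajs, function(t)
      evaluateOnTrajectory(coord, t)[.excitedFrames(t)]))
    if (length(v) < 2) stop("too few excited-state frames for a variance")
    mean((v - mean(v))^2)
  }
  v0 <- vapply(dofList, function(co) poolVar(unconstrained, co), numeric(1))
  vm <- sapply(constrained, function(sw)
    vapply(dofList, function(co) poolVar(sw, co), numeric(1)))
  vm <- matrix(vm, nrow = length(dofList),
               dimnames = list(names(dofList), names(constrained)))
  red <- sweep(-vm, 1, v0, `+`) / v0
  list(var = vm, baseline = v0, reduction = red, printed = 1 + red)
}
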