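#' Create a Structure
#'
#' @param elements element symbols.
#' @param xyz numeric matrix (n x 3), Angstrom.
#' @param masses optional per-atom masses.
#' @return a [Structure-class].
#' @export
makeStructure <- function(elements, xyz, masses = numeric()) {
  new("Structure", elements = as.character(elements),
      xyz = as.matrix(xyz), masses = masses)
}

setMethod("show", "Structure", function(object) {
  cat(sprintf("Structure: %d atoms (%s)\n", nrow(object@xyz),
              paste(unique(object@elements), collapse = ", ")))
})

#' Coordinate definition constructors
#'
#' `distanceCoordinate(a, b)` is the distance d(a,b);
#' `distanceDifferenceCoordinate(a, b, c, d)` is d(a,b) - d(c,d) (e.g. a
#' proton-transfer coordinate d(O-H) - d(N-H));
#' `improperDihedralCoordinate(a, b, c, d)` is the improper dihedral over an
#' atom quadruplet in degrees, used to quantify amide deplanarization;
#' `dofCoordinate(i)` addresses the i-th model degree of freedom directly
#' (reported in Angstrom).
#'
#' @param a,b,c,d 1-based atom indices.
#' @param i 1-based model dof index.
#' @param label coordinate label.
#' @return a [CoordinateDefinition-class].
#' @export
distanceCoordinate <- function(a, b, label = sprintf("d(%d,%d)", a, b)) {
  new("CoordinateDefinition", kind = "distance",
      atoms = list(as.integer(c(a, b))), label = label)
}

#' @rdname distanceCoordinate
#' @export
distanceDifferenceCoordinate <- function(a, b, c, d,
                                         label = sprintf("d(%d,%d)-d(%d,%d)",
                                                         a, b, c, d)) {
  new("CoordinateDefinition", kind = "distance_difference",
      atoms = list(as.integer(c(a, b)), as.integer(c(c, d))), label = label)
}

#' @rdname distanceCoordinate
#' @export
improperDihedralCoordinate <- function(a, b, c, d,
                                       label = sprintf("impdih(%d,%d,%d,%d)",
                                                       a, b, c, d)) {
  new("CoordinateDefinition", kind = "improper_dihedral",
      atoms = list(as.integer(c(a, b, c, d))), label = label)
}

#' @rdname distanceCoordinate
#' @export
dofCoordinate <- function(i, label = sprintf("dof%d", i)) {
  new("CoordinateDefinition", kind = "dof", atoms = list(as.integer(i)),
      label = label)
}

.coordXYZ <- function(s) {
  if (is(s, "Structure")) return(s@xyz)
  if (is.matrix(s)) {
    if (ncol(s) != 3) stop("coordinate matrix must have 3 columns")
    return(s)
  }
  # flat frame vector in x1 y1 z1 x2 ... order
  matrix(as.numeric(s), ncol = 3, byrow = TRUE)
}

.checkIndices <- function(coord, natoms) {
  idx <- unlist(coord@atoms)
  if (any(idx > natoms))
    stop(sprintf("coordinate '%s' references atom %d but the structure has %d atoms",
                 coord@label, max(idx), natoms))
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
         n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Evaluate an internal coordinate on a structure
#'
#' Distances and distance differences are returned in Angstrom, improper
#' dihedrals in degrees in (-180, 180]. With `planarity = TRUE` an improper
#' dihedral is reported as its deviation from planarity,
#' `|180 - |dihedral||` degrees.
#'
#' @param coord a [CoordinateDefinition-class].
#' @param s a [Structure-class], an n x 3 coordinate matrix (Angstrom), or -
#'   for `"dof"` coordinates - a numeric model coordinate vector in bohr.
#' @param planarity report improper dihedrals as deviation from 180 degrees.
#' @return coordinate value.
#' @examples
#' s <- makeStructure(c("O", "H", "N"),
#'                    rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0)))
#' pt <- distanceDifferenceCoordinate(1, 2, 3, 2, label = "PT")
#' evaluateCoordinate(pt, s)   # d(O-H) - d(N-H) = 1.0 - 1.8 = -0.8
#' @export
evaluateCoordinate <- function(coord, s, planarity = FALSE) {
  if (coord@kind == "dof") {
    x <- if (is(s, "Structure")) stop("'dof' coordinates apply to model coordinate vectors")
         else as.numeric(s)
    i <- coord@atoms[[1]]
    if (i > length(x))
      stop(sprintf("coordinate '%s' addresses dof %d of %d", coord@label, i,
                   length(x)))
    return(x[i] * BOHR2ANG)
  }
  xyz <- .coordXYZ(s)
  .checkIndices(coord, nrow(xyz))
  switch(coord@kind,
    distance = {
      ab <- coord@atoms[[1]]
      sqrt(sum((xyz[ab[1], ] - xyz[ab[2], ])^2))
    },
    distance_difference = {
      ab <- coord@atoms[[1]]; cd <- coord@atoms[[2]]
      sqrt(sum((xyz[ab[1], ] - xyz[ab[2], ])^2)) -
        sqrt(sum((xyz[cd[1], ] - xyz[cd[2], ])^2))
    },
    improper_dihedral = {
      q <- coord@atoms[[1]]
      ang <- .dihedral(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
      if (planarity) abs(180 - abs(ang)) else ang
    })
}

#' Evaluate a coordinate on every frame of a trajectory
#'
#' @param coord a [CoordinateDefinition-class].
#' @param traj a [Trajectory-class].
#' @param planarity see [evaluateCoordinate()].
#' @return numeric vector, one value per frame.
#' @export
evaluateOnTrajectory <- function(coord, traj, planarity = FALSE) {
  if (coord@kind == "dof") {
    i <- coord@atoms[[1]]
    if (traj@cartesian || i > ncol(traj@positions))
      stop(sprintf("coordinate '%s': dof %d not available", coord@label, i))
    return(traj@positions[, i] * BOHR2ANG)
  }
  if (!traj@cartesian)
    stop("Cartesian coordinate requested on a model-space trajectory")
  vapply(seq_len(nrow(traj@positions)), function(f) {
    evaluateCoordinate(coord, matrix(traj@positions[f, ], ncol = 3,
                                     byrow = TRUE), planarity)
  }, numeric(1))
}

#' Cartesian gradient of an internal coordinate
#'
#' Analytic per-atom gradient; distances in (dimensionless) unit-vector
#' form, dihedrals in degrees per Angstrom. The gradient sums to zero over
#' atoms (translation invariance).
#'
#' @param coord a [CoordinateDefinition-class] (not `"dof"`).
#' @param s a [Structure-class] or n x 3 matrix.
#' @return n x 3 gradient matrix.
#' @export
coordinateGradient <- function(coord, s) {
  xyz <- .coordXYZ(s)
  .checkIndices(coord, nrow(xyz))
  g <- matrix(0, nrow(xyz), 3)
  addDist <- function(g, a, b, sign) {
    v <- xyz[a, ] - xyz[b, ]
    d <- sqrt(sum(v^2))
    if (d < 1e-10) stop("degenerate geometry: zero-length bond vector")
    g[a, ] <- g[a, ] + sign * v / d
    g[b, ] <- g[b, ] - sign * v / d
    g
  }
  if (coord@kind == "distance") {
    ab <- coord@atoms[[1]]
    g <- addDist(g, ab[1], ab[2], 1)
  } else if (coord@kind == "distance_difference") {
    ab <- coord@atoms[[1]]; cd <- coord@atoms[[2]]
    g <- addDist(g, ab[1], ab[2], 1)
    g <- addDist(g, cd[1], cd[2], -1)
  } else if (coord@kind == "improper_dihedral") {
    q <- coord@atoms[[1]]
    p1 <- xyz[q[1], ]; p2 <- xyz[q[2], ]; p3 <- xyz[q[3], ]; p4 <- xyz[q[4], ]
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                              u[3] * v[1] - u[1] * v[3],
                              u[1] * v[2] - u[2] * v[1])
    n1 <- cross(b1, b2); n2 <- cross(b2, b3)
    nb2 <- sqrt(sum(b2^2))
    if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
      stop("degenerate geometry: collinear atoms in dihedral")
    d1 <- nb2 / sum(n1^2) * n1
    d4 <- -nb2 / sum(n2^2) * n2
    f12 <- sum(b1 * b2) / nb2^2
    f32 <- sum(b3 * b2) / nb2^2
    d2 <- -(1 + f12) * d1 + f32 * d4
    d3 <- -(1 + f32) * d4 + f12 * d1
    g[q[1], ] <- d1; g[q[2], ] <- d2; g[q[3], ] <- d3; g[q[4], ] <- d4
    g <- g * 180 / pi
  } else {
    stop("no Cartesian gradient for 'dof' coordinates")
  }
  g
}

#' Optimal superposition and RMSD (Kabsch)
#'
#' Least-squares superposition of structure `b` onto structure `a` over an
#' optional atom selection, with the reflection excluded via the determinant
#' correction.
#'
#' @param a,b [Structure-class] objects (or n x 3 matrices) with matching
#'   element order.
#' @param selection optional 1-based atom indices used both for the fit and
#'   the RMSD.
#' @return list: `rmsd` (Angstrom), `rotation` (3 x 3), `translation`
#'   (length 3; the map is `x -> x R + t` applied to `b`), `aligned`
#'   (the transformed full coordinates of `b`).
#' @export
kabschRmsd <- function(a, b, selection = NULL) {
  ea <- if (is(a, "Structure")) a@elements else NULL
  eb <- if (is(b, "Structure")) b@elements else NULL
  xa <- .coordXYZ(a); xb <- .coordXYZ(b)
  if (nrow(xa) != nrow(xb)) stop("structures have different atom counts")
  if (!is.null(ea) && !is.null(eb) && !identical(ea, eb))
    stop("element order mismatch between structures")
  sel <- if (is.null(selection)) seq_len(nrow(xa)) else as.integer(selection)
  if (length(sel) < 3) stop("at least 3 atoms are needed for superposition")
  pa <- xa[sel, , drop = FALSE]; pb <- xb[sel, , drop = FALSE]
  ca <- colMeans(pa); cb <- colMeans(pb)
  A <- sweep(pa, 2, ca); B <- sweep(pb, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  # b is mapped by x -> (x - cb) R' ... build as x R + t acting on rows
  Rm <- t(R)
  tv <- ca - cb %*% Rm
  aligned <- xb %*% Rm + matrix(tv, nrow(xb), 3, byrow = TRUE)
  dev <- aligned[sel, , drop = FALSE] - pa
  list(rmsd = sqrt(mean(rowSums(dev^2))), rotation = Rm,
       translation = as.numeric(tv), aligned = aligned)
}

#' Donor-acceptor hydrogen-bond length
#'
#' Heavy-atom donor-acceptor distance, the standard geometric descriptor of
#' hydrogen-bond strength (around 2.45 A for a short/strong hydrogen bond,
#' 2.85 A for a conventional one).
#'
#' @param s a [Structure-class] or n x 3 matrix.
#' @param donor,acceptor 1-based heavy-atom indices.
#' @return distance in Angstrom.
#' @export
hydrogenBondLength <- function(s, donor, acceptor) {
  evaluateCoordinate(distanceCoordinate(donor, acceptor,
                                        label = "HB"), s)
}
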