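test_that("internal coordinates evaluate to their defining quantities", {
  s <- makeStructure(c("O", "H", "N"),
                     rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0)))
  expect_equal(evaluateCoordinate(distanceCoordinate(1, 2), s), 1.0)
  pt <- distanceDifferenceCoordinate(1, 2, 3, 2, label = "PT")
  expect_equal(evaluateCoordinate(pt, s), 1.0 - 1.8)
  # shared proton at the midpoint: PT coordinate vanishes
  smid <- makeStructure(c("O", "H", "N"),
                        rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.8, 0, 0)))
  expect_equal(evaluateCoordinate(pt, smid), 0)
  # four coplanar atoms in trans arrangement: dihedral 180, planarity 0
  sq <- makeStructure(rep("C", 4),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)))
  dih <- improperDihedralCoordinate(1, 2, 3, 4)
  expect_equal(abs(evaluateCoordinate(dih, sq)), 180)
  expect_equal(evaluateCoordinate(dih, sq, planarity = TRUE), 0)
  expect_error(evaluateCoordinate(distanceCoordinate(1, 9, label = "bad"), s),
               "bad")
})

test_that("coordinate gradients are analytic, translation-free and rotation-consistent", {
  set.seed(12)
  xyz <- matrix(rnorm(18, sd = 2), 6, 3)
  s <- makeStructure(rep("C", 6), xyz)
  coords <- list(distanceCoordinate(1, 2),
                 distanceDifferenceCoordinate(1, 2, 3, 4),
                 improperDihedralCoordinate(1, 2, 3, 4))
  h <- 1e-6
  for (co in coords) {
    g <- coordinateGradient(co, s)
    expect_lt(max(abs(colSums(g))), 1e-9)       # translation invariance
    fd <- matrix(0, 6, 3)
    for (a in 1:6) for (k in 1:3) {
      xp <- xyz; xp[a, k] <- xp[a, k] + h
      xm <- xyz; xm[a, k] <- xm[a, k] - h
      fd[a, k] <- (evaluateCoordinate(co, xp) -
                     evaluateCoordinate(co, xm)) / (2 * h)
    }
    expect_lt(max(abs(g - fd)), 1e-5)
    # distance gradient on atom a is the unit vector from b to a
    if (co@kind == "distance") {
      u <- (xyz[1, ] - xyz[2, ])
      expect_equal(g[1, ], u / sqrt(sum(u^2)), tolerance = 1e-12)
    }
  }
  # invariance of values under rigid motion
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xyz2 <- xyz %*% R + matrix(c(3, -1, 2), 6, 3, byrow = TRUE)
  for (co in coords)
    expect_equal(evaluateCoordinate(co, xyz2), evaluateCoordinate(co, xyz),
                 tolerance = 1e-9)
})

test_that("Kabsch superposition recovers rigid motions and the optimal RMSD", {
  set.seed(3)
  xyz <- matrix(rnorm(12, sd = 1.5), 4, 3)
  a <- makeStructure(rep("C", 4), xyz)
  expect_equal(kabschRmsd(a, a)$rmsd, 0, tolerance = 1e-12)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  b <- makeStructure(rep("C", 4),
                     xyz %*% R + matrix(c(1, 2, 3), 4, 3, byrow = TRUE))
  expect_lt(kabschRmsd(a, b)$rmsd, 1e-10)
  # one atom displaced by 1 A: compare against a brute-force oracle over
  # rotations x centroid shifts; naive (unaligned) RMSD 0.5 is the bound
  b2 <- xyz
  b2[1, ] <- b2[1, ] + c(1, 0, 0)
  got <- kabschRmsd(a, makeStructure(rep("C", 4), b2))$rmsd
  expect_lte(got, 0.5 + 1e-12)
  brute <- {
    ca <- sweep(xyz, 2, colMeans(xyz))
    cb <- sweep(b2, 2, colMeans(b2))
    best <- Inf
    ang <- seq(0, 2 * pi, length.out = 25)[-25]
    for (a1 in ang) for (a2 in seq(0, pi, length.out = 13)) for (a3 in ang) {
      R1 <- rbind(c(cos(a1), -sin(a1), 0), c(sin(a1), cos(a1), 0), c(0, 0, 1))
      R2 <- rbind(c(cos(a2), 0, sin(a2)), c(0, 1, 0), c(-sin(a2), 0, cos(a2)))
      R3 <- rbind(c(cos(a3), -sin(a3), 0), c(sin(a3), cos(a3), 0), c(0, 0, 1))
      d <- cb %*% (R1 %*% R2 %*% R3) - ca
      best <- min(best, sqrt(mean(rowSums(d^2))))
    }
    best
  }
  expect_lte(got, brute + 1e-6)        # analytic optimum beats the grid
  expect_gt(got, brute - 0.05)         # ... and the grid gets close to it
  expect_error(kabschRmsd(a, makeStructure(c("C", "C", "N", "C"), b2)),
               "element")
})

test_that("Kabsch agrees with an independent structural-biology implementation", {
  skip_if_not_installed("bio3d")
  set.seed(9)
  xa <- matrix(rnorm(30, sd = 2), 10, 3)
  xb <- xa + matrix(rnorm(30, sd = 0.3), 10, 3)
  ours <- kabschRmsd(makeStructure(rep("C", 10), xa),
                     makeStructure(rep("C", 10), xb))$rmsd
  ref <- bio3d::rmsd(as.numeric(t(xa)), as.numeric(t(xb)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("hydrogen-bond length is the donor-acceptor distance", {
  s <- makeStructure(c("O", "O"), rbind(c(0, 0, 0), c(0, 0, 2.45)))
  expect_equal(hydrogenBondLength(s, 1, 2), 2.45)
  expect_equal(hydrogenBondLength(s, 1, 2),
               evaluateCoordinate(distanceCoordinate(1, 2), s))
  s0 <- makeStructure(c("O", "O"), rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(hydrogenBondLength(s0, 1, 2), 0)
})
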