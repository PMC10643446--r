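test_that("diabatic gap reconstruction swaps identities at the crossing", {
  gap <- c(rep(1, 49), seq(1, 0.05, length.out = 2), rep(0.4, 49))
  state <- c(rep(1L, 50), rep(0L, 50))
  tr <- syntheticTrajectory(gap, state)
  dE <- reconstructDiabaticGap(tr)
  expect_equal(sign(-dE), c(rep(-1, 50), rep(1, 50)))
  expect_equal(abs(dE), gap)
  # the exact-crossing frame sits on the post-crossing (swapped) side
  expect_lt(dE[firstCrossing(tr)], 0)
  # no crossing: adiabatic gap everywhere, all positive
  tr2 <- syntheticTrajectory(rep(2, 20), rep(1L, 20))
  expect_true(all(reconstructDiabaticGap(tr2) > 0))
})

test_that("pooling centers fluctuations and accounts for every frame once", {
  trajs <- mockTrajectories()[1:5]
  ens <- poolEnsemble(trajs, pathwayConfig(align = FALSE))
  expect_lt(max(abs(colMeans(ens@fluct))), 1e-10)
  expect_equal(nrow(ens@provenance), nrow(ens@fluct))
  expect_false(any(duplicated(ens@provenance[c("traj", "frame")])))
  expect_equal(nrow(ens@fluct),
               sum(vapply(trajs, nFrames, integer(1))))
  # a static trajectory pools to zero fluctuations
  st <- syntheticTrajectory(c(rep(1, 5), rep(0.05, 5)),
                            c(rep(1L, 5), rep(0L, 5)),
                            positions = matrix(2.5, 10, 3))
  e2 <- poolEnsemble(list(st), pathwayConfig(align = FALSE))
  expect_true(all(e2@fluct == 0))
  # nothing admitted without decaying members
  nd <- syntheticTrajectory(rep(2, 10), rep(1L, 10))
  expect_error(poolEnsemble(list(nd)), "admitted")
  expect_equal(nrow(poolEnsemble(list(nd),
    pathwayConfig(includeNonDecaying = TRUE))@fluct), 10)
})

test_that("alignment is a no-op for drift-free fixtures", {
  trajs <- mockTrajectories()[1:10]
  cOn <- pathwayVector(relaxationVector(
    poolEnsemble(trajs, pathwayConfig(align = TRUE)), pathwayConfig()))
  cOff <- pathwayVector(relaxationVector(
    poolEnsemble(trajs, pathwayConfig(align = FALSE)), pathwayConfig()))
  # planted displacements are translation- and torque-free, so the Kabsch
  # fit only chases per-frame jitter; the vectors agree closely
  expect_gt(sum(cOn * cOff) / sqrt(sum(cOn^2) * sum(cOff^2)), 0.999)
})

test_that("constant coordinates get zero weight and components obey Cauchy-Schwarz", {
  gap <- c(seq(2, 0.05, length.out = 30), seq(0.1, 1, length.out = 30))
  state <- c(rep(1L, 30), rep(0L, 30))
  pos <- cbind(rnorm(60), rep(1.7, 60))   # second coordinate constant
  tr <- syntheticTrajectory(gap, state, positions = pos)
  vec <- relaxationVector(poolEnsemble(list(tr), pathwayConfig(align = FALSE)),
                          pathwayConfig())
  expect_equal(pathwayVector(vec)[2], 0)
  # property: |c_i| <= 1 on randomized ensembles
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(20:80, 1)
    k <- sample(2:5, 1)
    gap <- abs(rnorm(n, 1, 0.8)) + 1e-3
    cross <- sample(2:(n - 1), 1)
    state <- c(rep(1L, cross - 1), rep(0L, n - cross + 1))
    pos <- matrix(rnorm(n * k, sd = runif(1, 0.01, 2)), n, k)
    tr <- syntheticTrajectory(gap, state, positions = pos)
    vec <- relaxationVector(
      poolEnsemble(list(tr), pathwayConfig(align = FALSE)), pathwayConfig())
    expect_true(all(abs(pathwayVector(vec)) <= 1 + 1e-12))
  }
})

test_that("planted decay direction is recovered and spectators rank below it", {
  spec <- mockDimerSpec(seed = 42)
  vec <- fixture("mockVector", function()
    relaxationVector(poolEnsemble(mockTrajectories(), pathwayConfig()),
                     pathwayConfig()))
  u <- plantedDirection(spec)
  expect_gt(cosineTo(vec, u), 0.9)
  # orientation: the decay component points from the pre-crossing mean
  # toward the post-crossing (ground-state side) mean of the coordinate
  co <- distanceCoordinate(1, 2)
  pre <- unlist(lapply(mockTrajectories(), function(t)
    evaluateOnTrajectory(co, t)[t@state == 1L]))
  post <- unlist(lapply(mockTrajectories(), function(t)
    evaluateOnTrajectory(co, t)[t@state == 0L]))
  proj <- projectVector(vec, list(co), mockDimerReference())
  expect_equal(sign(proj$projection), sign(mean(post) - mean(pre)))
  # projection shares: decay mode dominates every spectator
  pr <- projectVector(vec, list(distanceCoordinate(1, 2, label = "CO"),
                                distanceCoordinate(3, 4, label = "NH"),
                                distanceCoordinate(7, 8, label = "CO2")),
                      mockDimerReference())
  expect_gt(pr$share[1], max(pr$share[-1]))
  expect_equal(sum(pr$share), 1)
  # doubling alpha barely moves the recovered direction
  vec2 <- relaxationVector(poolEnsemble(mockTrajectories(), pathwayConfig()),
                           pathwayConfig(alpha = 200))
  expect_lt(abs(cosineTo(vec, u) - cosineTo(vec2, u)), 0.05)
})

test_that("projection separates parallel and orthogonal directions", {
  ref <- mockDimerReference()
  co <- distanceCoordinate(1, 2, label = "CO")
  g <- as.numeric(t(coordinateGradient(co, ref)))
  g <- g / sqrt(sum(g^2))
  vec <- new("RelaxationVector", c = g * 0.8, config = list(),
             provenance = data.frame())
  pr <- projectVector(vec, list(co, distanceCoordinate(3, 4, label = "NH")),
                      ref)
  expect_equal(pr$share, c(1, 0), tolerance = 1e-12)
  expect_equal(pr$cosine[1], 1, tolerance = 1e-12)
  # orthogonal everywhere: all shares zero
  vperp <- rep(0, length(g)); vperp[3] <- 0.5   # z of atom 1: orthogonal
  vec2 <- new("RelaxationVector", c = vperp, config = list(),
              provenance = data.frame())
  pr2 <- projectVector(vec2, list(co), ref)
  expect_equal(pr2$projection, 0, tolerance = 1e-12)
  expect_error(projectVector(vec, list(co),
                             makeStructure("C", rbind(c(0, 0, 0)))),
               "3N")
})
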