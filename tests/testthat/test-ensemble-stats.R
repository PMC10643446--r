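test_that("crossing frames are detected at the first below-threshold passage", {
  tr <- syntheticTrajectory(c(0.5, 0.3, 0.08, 0.4), c(1L, 1L, 0L, 0L))
  d <- detectCoinFrames(tr, 0.1)
  expect_equal(d$frame, 3L)
  expect_false(d$flagged)
  # no frame below threshold and no hop: empty
  tr2 <- syntheticTrajectory(c(0.5, 0.4, 0.45), rep(1L, 3))
  expect_equal(nrow(detectCoinFrames(tr2, 0.1)), 0)
  # hop without a below-threshold frame: hop frame, flagged
  tr3 <- syntheticTrajectory(c(0.6, 0.3, 0.2, 0.5), c(1L, 1L, 0L, 0L))
  d3 <- detectCoinFrames(tr3, 0.1)
  expect_equal(d3$frame, 3L)
  expect_true(d3$flagged)
  # threshold at or above the vertical gap is refused
  expect_error(detectCoinFrames(tr, 0.5), "vertical gap")
})

test_that("decay fractions count ground-state arrivals", {
  mk <- function(decays) {
    if (decays) syntheticTrajectory(c(1, 0.5, 0.05, 0.3),
                                    c(1L, 1L, 0L, 0L))
    else syntheticTrajectory(rep(1, 4), rep(1L, 4))
  }
  sw <- c(lapply(1:7, function(i) mk(TRUE)), lapply(1:3, function(i) mk(FALSE)))
  ss <- summarizeSwarm(sw)
  expect_equal(decayFraction(ss), 0.7)
  expect_equal(length(decayTimes(ss)), 7)
  expect_equal(decayFraction(summarizeSwarm(lapply(1:4, function(i) mk(TRUE)))), 1)
  expect_equal(decayFraction(summarizeSwarm(lapply(1:4, function(i) mk(FALSE)))), 0)
  expect_error(summarizeSwarm(list()), "empty")
})

test_that("the standardized separation statistic obeys its identities", {
  set.seed(5)
  s1 <- rnorm(4000, 1.25, 0.05)
  st0 <- coinDistanceStat(s1, s1)
  expect_equal(st0$D, 0, tolerance = 1e-12)
  sdp <- sd(s1) * sqrt((length(s1) - 1) / length(s1))
  st1 <- coinDistanceStat(s1, s1 + sdp)
  expect_equal(st1$D, 1, tolerance = 1e-12)
  # direct evaluation at stated moments
  s1v <- 1.25 + c(-1, 0, 1) * 0.05 * sqrt(3 / 2)   # population sd 0.05
  st <- coinDistanceStat(s1v, c(1.35, 1.40, 1.45))
  expect_equal(st$sdS1, 0.05, tolerance = 1e-12)
  expect_equal(st$D, 3, tolerance = 1e-12)
  # invariance under joint affine rescaling
  st2 <- coinDistanceStat(10 * s1v + 2, 10 * c(1.35, 1.40, 1.45) + 2)
  expect_equal(st2$D, st$D, tolerance = 1e-10)
  expect_error(coinDistanceStat(numeric(), 1), "non-empty")
})

test_that("ensemble histograms share bins, conserve counts and show the elongation", {
  sw <- weakLockSwarm()
  co <- dofCoordinate(1, label = "CO")
  eh <- ensembleHistograms(sw, co, nBins = 25)
  for (ens in c("S0", "S1", "CoIn")) {
    n <- sum(eh$table$count[eh$table$ensemble == ens])
    expect_equal(n, length(eh$values[[ens]]))
  }
  # S1 frames exclude post-decay frames by construction
  expect_equal(length(eh$values$S1),
               sum(vapply(sw, function(t) sum(t@state == 1L), integer(1))))
  # weak lock: the crossing demands CO elongation beyond the S1 mean
  expect_gt(mean(eh$values$CoIn), mean(eh$values$S1))
  # single-frame ensembles produce delta histograms
  tr <- syntheticTrajectory(c(1, 0.05), c(1L, 0L),
                            positions = matrix(c(2.0, 2.6), 2, 1))
  eh1 <- ensembleHistograms(list(tr), dofCoordinate(1), nBins = 10)
  expect_equal(max(eh1$table$count[eh1$table$ensemble == "S1"]), 1)
  expect_equal(sum(eh1$table$count[eh1$table$ensemble == "S1"] > 0), 1)
})

test_that("locking the stretch pushes the crossing into the tail of the excited-state distribution", {
  # D compares the crossing-geometry distribution with the excited-state
  # one; under mild dissipation (vibrational cooling by the environment)
  # a locked stretch keeps S1 fluctuations narrow, so reaching the seam
  # becomes a rare, large-D excursion. Paired seeds across the two models.
  co <- dofCoordinate(1, label = "CO")
  Dof <- function(kl) {
    cfg <- lockConfig(thermostat = "langevin", friction = 5)
    sw <- runSwarm(buildCarbonylLockModel(carbonylLockParams(k_lock = kl)),
                   200, cfg, baseSeed = 211)
    s1 <- unlist(lapply(sw, function(t)
      evaluateOnTrajectory(co, t)[t@state == 1L]))
    coin <- unlist(lapply(sw, function(t) {
      d <- detectCoinFrames(t)
      if (nrow(d)) evaluateOnTrajectory(co, t)[d$frame] else numeric()
    }))
    coinDistanceStat(s1, coin, "CO")$D
  }
  dWeak <- Dof(0)
  dStrong <- Dof(0.05)
  expect_gt(dStrong, dWeak)
  expect_gt(dWeak, 0)   # crossing always needs some elongation
})

test_that("variance hierarchy reports both conventions and finds the diagonal", {
  sw <- weakLockSwarm()
  # identity cells: comparing a swarm against itself
  dofs <- list(CO = dofCoordinate(1), PT = dofCoordinate(2))
  vh0 <- varianceHierarchy(sw, list(CO = sw), dofs)
  expect_equal(unname(vh0$reduction[, "CO"]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(vh0$printed[, "CO"]), c(1, 1), tolerance = 1e-12)
  expect_equal(vh0$printed, 1 + vh0$reduction)
  # full suppression: a constant coordinate
  stat <- syntheticTrajectory(c(rep(1, 6), 0.05), c(rep(1L, 6), 0L),
                              positions = cbind(rep(2.5, 7), rnorm(7)))
  base <- syntheticTrajectory(c(rep(1, 6), 0.05), c(rep(1L, 6), 0L),
                              positions = cbind(rnorm(7, 2.5, 0.1), rnorm(7)))
  vh1 <- varianceHierarchy(list(base), list(CO = list(stat)),
                           list(CO = dofCoordinate(1)))
  expect_equal(unname(vh1$reduction["CO", "CO"]), 1)
  expect_equal(unname(vh1$printed["CO", "CO"]), 2)
  # simulated constraint experiment: each constraint suppresses its own
  # coordinate more than the other's
  mm <- buildCarbonylLockModel(carbonylLockParams())
  swR <- fixture("conR", function()
    runSwarm(mm, 60, lockConfig(), list(constraintSpec(1)), baseSeed = 11))
  swQ <- fixture("conQ", function()
    runSwarm(mm, 60, lockConfig(), list(constraintSpec(2)), baseSeed = 11))
  vh <- varianceHierarchy(weakLockSwarm()[1:60],
                          list(CO = swR, PT = swQ), dofs)
  expect_gt(vh$reduction["CO", "CO"], vh$reduction["CO", "PT"])
  expect_gt(vh$reduction["PT", "PT"], vh$reduction["PT", "CO"])
  expect_error(varianceHierarchy(sw, list(sw), dofs), "named")
})
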