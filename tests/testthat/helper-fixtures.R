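# Shared, lazily built simulation fixtures so expensive swarms are run once
# per test session.
.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureEnv))
    assign(name, builder(), envir = .fixtureEnv)
  get(name, envir = .fixtureEnv)
}

lockConfig <- function(...) integratorConfig(dt = 0.1, tMax = 250, ...)

weakLockSwarm <- function() fixture("weakLockSwarm", function()
  runSwarm(buildCarbonylLockModel(carbonylLockParams()), 100, lockConfig(),
           baseSeed = 11))

mockTrajectories <- function() fixture("mockTrajectories", function()
  generateMockDimerTrajectories(mockDimerSpec(seed = 42), 50))

# cosine between a relaxation vector and a unit direction
cosineTo <- function(vec, u) {
  cc <- pathwayVector(vec)
  sum(cc * u) / sqrt(sum(cc^2))
}

# build a minimal Cartesian-free trajectory object from raw series (test
# scaffolding for the analysis modules)
syntheticTrajectory <- function(gapSeries, state, positions = NULL,
                                dt = 0.5) {
  n <- length(gapSeries)
  if (is.null(positions)) positions <- matrix(seq_len(n), ncol = 1)
  fc <- which(state == 0L)
  fc <- if (length(fc)) fc[1] else NA_integer_
  hops <- if (!is.na(fc) && fc > 1)
    data.frame(frame = fc, from = 1L, to = 0L)
  else data.frame(frame = integer(), from = integer(), to = integer())
  new("Trajectory", positions = positions, velocities = matrix(0, 0, 0),
      energies = cbind(0, gapSeries), state = as.integer(state),
      coeffs = matrix(complex(0), 0, 0), nacv = matrix(0, 0, 0),
      time = (seq_len(n) - 1) * dt, hops = hops, firstCrossing = fc,
      cartesian = FALSE, elements = character(), metadata = list())
}
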