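# Trajectory interchange: extended XYZ (per-frame key=value comment line)
# for Cartesian trajectories, TSV time series for energies/state and for
# model-space coordinates, JSON for summaries and manifests, YAML for run
# configuration. Every writer embeds the seed so outputs are auditable.

.cheapHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Write a Cartesian trajectory as extended XYZ
#'
#' One block per frame: atom count, then a comment line holding
#' `time_fs=... E0_eV=... E1_eV=... state=...` (plus `seed=` on the first
#' frame), then element/x/y/z rows in Angstrom.
#'
#' @param traj a Cartesian [Trajectory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrajectoryXYZ <- function(traj, path) {
  if (!traj@cartesian) stop("extended XYZ output needs a Cartesian trajectory")
  nat <- length(traj@elements)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nrow(traj@positions))) {
    meta <- sprintf("time_fs=%.6f E0_eV=%.8f E1_eV=%.8f state=%d",
                    traj@time[f], traj@energies[f, 1], traj@energies[f, 2],
                    traj@state[f])
    if (f == 1 && !is.null(traj@metadata$seed))
      meta <- paste0(meta, sprintf(" seed=%d", traj@metadata$seed))
    writeLines(as.character(nat), con)
    writeLines(meta, con)
    xyz <- matrix(traj@positions[f, ], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%-2s %16.10f %16.10f %16.10f", traj@elements,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

.parseKV <- function(line) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  kv <- strsplit(toks, "=", fixed = TRUE)
  ok <- vapply(kv, length, integer(1)) == 2
  out <- vapply(kv[ok], `[`, character(1), 2)
  names(out) <- vapply(kv[ok], `[`, character(1), 1)
  out
}

#' Read an extended-XYZ trajectory
#'
#' Expects the schema written by [writeTrajectoryXYZ()]; frames must share
#' one atom count and carry `time_fs`, `E0_eV`, `E1_eV` and `state` fields.
#' Malformed frames are reported by frame index.
#'
#' @param path input file.
#' @return a Cartesian [Trajectory-class].
#' @export
readTrajectoryXYZ <- function(path) {
  lines <- readLines(path)
  pos <- list(); ener <- list(); state <- integer(); tm <- numeric()
  elements <- NULL; seed <- NULL
  i <- 1L; f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    f <- f + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop(sprintf("frame %d: bad atom count at line %d", f, i))
    if (!is.null(elements) && nat != length(elements))
      stop(sprintf("frame %d: atom count %d differs from first frame (%d)",
                   f, nat, length(elements)))
    kv <- .parseKV(lines[i + 1L])
    need <- c("time_fs", "E0_eV", "E1_eV", "state")
    if (!all(need %in% names(kv)))
      stop(sprintf("frame %d: missing energy/state fields (%s)", f,
                   paste(setdiff(need, names(kv)), collapse = ", ")))
    if (f == 1 && "seed" %in% names(kv)) seed <- as.integer(kv["seed"])
    rows <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(rows), "[[:space:]]+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad))
      stop(sprintf("frame %d: malformed atom row at line %d", f,
                   i + 1L + bad[1]))
    el <- vapply(parts, `[`, character(1), 1)
    if (is.null(elements)) elements <- el
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop(sprintf("frame %d: non-numeric coordinates", f))
    pos[[f]] <- as.numeric(t(xyz))
    ener[[f]] <- as.numeric(kv[c("E0_eV", "E1_eV")])
    state[f] <- as.integer(kv["state"])
    tm[f] <- as.numeric(kv["time_fs"])
    i <- i + 2L + nat
  }
  if (f == 0L) stop("no frames found")
  X <- do.call(rbind, pos)
  E <- do.call(rbind, ener)
  fc <- which(state == 0L)
  fc <- if (length(fc)) fc[1] else NA_integer_
  hops <- if (!is.na(fc) && fc > 1)
    data.frame(frame = fc, from = 1L, to = 0L)
  else data.frame(frame = integer(), from = integer(), to = integer())
  new("Trajectory", positions = X, velocities = matrix(0, 0, 0),
      energies = E, state = state, coeffs = matrix(complex(0), 0, 0),
      nacv = matrix(0, 0, 0), time = tm, hops = hops, firstCrossing = fc,
      cartesian = TRUE, elements = elements,
      metadata = list(source = path, seed = seed))
}

#' Write / read the TSV time-series sidecar of a trajectory
#'
#' Columns: frame, time_fs, E0, E1, state, gap_eV, then one column per
#' coordinate (`q1`, `q2`, ... in bohr for model-space trajectories).
#'
#' @param traj a [Trajectory-class].
#' @param path file path.
#' @return `path` invisibly for the writer; a [Trajectory-class] for the
#'   reader (model-space, without velocities or amplitudes).
#' @export
writeTrajectoryTSV <- function(traj, path) {
  n <- nrow(traj@positions)
  df <- data.frame(frame = seq_len(n), time_fs = traj@time,
                   E0 = traj@energies[, 1], E1 = traj@energies[, 2],
                   state = traj@state,
                   gap_eV = traj@energies[, 2] - traj@energies[, 1])
  qc <- as.data.frame(traj@positions)
  names(qc) <- paste0("q", seq_len(ncol(qc)))
  write.table(cbind(df, qc), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryTSV
#' @export
readTrajectoryTSV <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  need <- c("frame", "time_fs", "E0", "E1", "state")
  if (!all(need %in% names(df)))
    stop(sprintf("missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  qcols <- grep("^q[0-9]+$", names(df), value = TRUE)
  X <- as.matrix(df[, qcols, drop = FALSE])
  st <- as.integer(df$state)
  fc <- which(st == 0L)
  fc <- if (length(fc)) fc[1] else NA_integer_
  hops <- if (!is.na(fc) && fc > 1)
    data.frame(frame = fc, from = 1L, to = 0L)
  else data.frame(frame = integer(), from = integer(), to = integer())
  new("Trajectory", positions = X, velocities = matrix(0, 0, 0),
      energies = cbind(df$E0, df$E1), state = st,
      coeffs = matrix(complex(0), 0, 0), nacv = matrix(0, 0, 0),
      time = df$time_fs, hops = hops, firstCrossing = fc,
      cartesian = FALSE, elements = character(),
      metadata = list(source = path))
}

#' Write a swarm manifest (JSON)
#'
#' Records, per member: seed, decay status, first-crossing time and hop
#' count, plus the configuration hash - enough to audit a stochastic run.
#'
#' @param trajs list of [Trajectory-class] objects.
#' @param path output file.
#' @param config the configuration the swarm ran with.
#' @return `path`, invisibly.
#' @export
writeSwarmManifest <- function(trajs, path, config = NULL) {
  members <- lapply(trajs, function(t) {
    list(seed = t@metadata$seed,
         decayed = !is.na(t@firstCrossing),
         decay_time_fs = if (!is.na(t@firstCrossing))
           t@time[t@firstCrossing] else NULL,
         n_hops = nrow(t@hops), n_frames = nrow(t@positions))
  })
  out <- list(package = "CoInPath",
              config_hash = .cheapHash(config),
              n_traj = length(trajs), members = members)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write an analysis summary as JSON or TSV
#'
#' JSON output has stable key ordering and embeds the configuration hash;
#' TSV expects a data.frame.
#'
#' @param x a (nested) list or data.frame of results.
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @param config optional configuration to hash into the output (JSON only).
#' @return `path`, invisibly.
#' @export
writeResults <- function(x, path, format = c("json", "tsv"), config = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(x)) stop("TSV output expects a data.frame")
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    payload <- list(package = "CoInPath", config_hash = .cheapHash(config),
                    results = x)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a structure from a (plain or extended) XYZ file
#'
#' @param path file with one XYZ block.
#' @return a [Structure-class].
#' @export
readStructureXYZ <- function(path) {
  lines <- readLines(path)
  nat <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[3:(2 + nat)]), "[[:space:]]+")
  makeStructure(vapply(parts, `[`, character(1), 1),
                t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))))
}

#' Write a relaxation-mode file (reference + displacements)
#'
#' XYZ-style block with element, position and the per-atom displacement
#' components of the relaxation vector appended as three extra columns -
#' loadable by standard viewers as a vector field.
#'
#' @param vec a [RelaxationVector-class] over 3N coordinates.
#' @param reference a [Structure-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeModeXYZ <- function(vec, reference, path) {
  n <- nrow(reference@xyz)
  if (length(vec@c) != 3 * n) stop("vector length does not match structure")
  d <- matrix(vec@c, ncol = 3, byrow = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  writeLines("relaxation mode: columns are x y z cx cy cz", con)
  writeLines(sprintf("%-2s %14.8f %14.8f %14.8f %12.6f %12.6f %12.6f",
                     reference@elements, reference@xyz[, 1],
                     reference@xyz[, 2], reference@xyz[, 3],
                     d[, 1], d[, 2], d[, 3]), con)
  invisible(path)
}

#' Read and validate a run configuration (YAML)
#'
#' Schema: top-level keys `model` (name: `tully` or `carbonyl_lock`, plus
#' parameter overrides), `sampling` (temperature, friction, burnin),
#' `dynamics` ([integratorConfig()] fields), `constraints` (list of dof /
#' k / target entries; `index_base` 0 or 1, default 1), `analysis`
#' ([pathwayConfig()] fields plus `gap_threshold`), `output` (paths), and
#' `seed`. Unknown keys are rejected with their location.
#'
#' @param path YAML file.
#' @return list with the validated raw config plus constructed `model`,
#'   `dynamics` and `constraints` objects.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("model", "sampling", "dynamics", "constraints", "analysis",
             "output", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop(sprintf("unknown top-level config key(s): %s",
                 paste(bad, collapse = ", ")))
  checkKeys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in %s: %s", where,
                   paste(bad, collapse = ", ")))
  }
  model <- NULL
  if (!is.null(cfg$model)) {
    checkKeys(cfg$model, c("name", "params"), "model")
    nm <- cfg$model$name
    pars <- cfg$model$params
    model <- switch(nm,
      tully = do.call(buildTullyModel, as.list(pars)),
      carbonyl_lock = buildCarbonylLockModel(
        do.call(carbonylLockParams, as.list(pars))),
      stop(sprintf("unknown model name '%s' in model section", nm)))
  }
  dynamics <- NULL
  if (!is.null(cfg$dynamics)) {
    allowed <- names(formals(integratorConfig))
    checkKeys(cfg$dynamics, allowed, "dynamics")
    dynamics <- do.call(integratorConfig, cfg$dynamics)
  }
  constraints <- list()
  if (!is.null(cfg$constraints)) {
    base <- 1L
    cl <- cfg$constraints
    if (!is.null(cl$index_base)) { base <- as.integer(cl$index_base)
      cl$index_base <- NULL }
    constraints <- lapply(cl, function(e) {
      checkKeys(e, c("dof", "k", "target"), "constraints entry")
      constraintSpec(as.integer(e$dof) + (1L - base),
                     k = if (is.null(e$k)) 100 else e$k,
                     target = if (is.null(e$target)) NA_real_ else e$target)
    })
  }
  if (!is.null(cfg$sampling))
    checkKeys(cfg$sampling, c("temperature", "friction", "burnin",
                              "n_samples"), "sampling")
  if (!is.null(cfg$analysis))
    checkKeys(cfg$analysis, c(names(formals(pathwayConfig)),
                              "gap_threshold"), "analysis")
  list(raw = cfg, model = model, dynamics = dynamics,
       constraints = constraints, seed = cfg$seed)
}
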