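# Parsing SMD output into force traces: NAMD log `SMD` lines, GROMACS pull
# .xvg files, and multi-frame coordinate files (multi-model PDB, XYZ) for
# center-of-mass distance and hydrogen-bond analysis.

#' Construct a force trace
#'
#' The canonical analysis container: time in ps, force in pN (projected on
#' the pulling direction), optional per-sample pulled-group COM positions in
#' Angstrom.
#'
#' @param time numeric vector, ps, strictly increasing.
#' @param force numeric vector, pN, same length as `time`.
#' @param position optional n x 3 matrix of COM positions (Angstrom).
#' @param direction unit 3-vector or `NULL`.
#' @param source one of `"namd_log"`, `"gromacs_xvg"`, `"toysim"`.
#' @param replica_id integer replica identifier.
#' @return an object of class `force_trace`.
#' @export
force_trace <- function(time, force, position = NULL, direction = NULL,
                        source = c("namd_log", "gromacs_xvg", "toysim"),
                        replica_id = 1L) {
  source <- match.arg(source)
  if (length(time) != length(force)) pf_stop_input("time and force lengths differ")
  if (length(time) == 0L) pf_stop_input("empty force trace")
  if (any(diff(time) <= 0)) pf_stop_input("time must be strictly increasing")
  if (!is.null(position)) {
    position <- as.matrix(position)
    if (nrow(position) != length(time)) pf_stop_input("position length differs from time")
  }
  structure(list(time = as.numeric(time), force = as.numeric(force),
                 position = position, direction = direction, source = source,
                 replica_id = as.integer(replica_id)),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("force_trace [%s, replica %d]: %d samples, t %.4g..%.4g ps, Fmax %.4g pN\n",
              x$source, x$replica_id, length(x$time), min(x$time), max(x$time), max(x$force)))
  invisible(x)
}

#' @export
length.force_trace <- function(x) length(x$time)

#' Parse NAMD SMD log lines into a force trace
#'
#' NAMD writes one line per SMD output step:
#' `SMD <step> <x> <y> <z> <Fx> <Fy> <Fz>` with the pulled-group COM in
#' Angstrom and the applied force in kcal mol^-1 A^-1. Time is
#' `step * timestep` (converted to ps) and the force is projected on the
#' pulling direction and converted to pN (x 69.4786). Duplicate step numbers
#' (restart overlap) keep the last occurrence with a warning; decreasing
#' steps are an error.
#'
#' @param path NAMD log file.
#' @param timestep timestep in fs.
#' @param direction unit 3-vector the force is projected on.
#' @param replica_id integer tag for the trace.
#' @param kind `"projection"` (default) or `"magnitude"` of the force vector.
#' @return a [force_trace()] (`source = "namd_log"`).
#' @export
parse_namd_smd_log <- function(path, timestep, direction, replica_id = 1L,
                               kind = c("projection", "magnitude")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) pf_stop_input(sprintf("log file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  sel <- grep("^SMD\\s", lines)
  if (length(sel) == 0L) pf_stop_format(sprintf("no SMD lines in %s", path))
  fields <- strsplit(trimws(lines[sel]), "\\s+")
  bad <- which(lengths(fields) != 8L)
  if (length(bad) > 0L)
    pf_stop_format(sprintf("malformed SMD line %d in %s (expected 8 fields)", sel[bad[1]], path))
  m <- matrix(suppressWarnings(as.numeric(unlist(lapply(fields, `[`, 2:8)))),
              ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    i <- which(apply(m, 1, anyNA))[1]
    pf_stop_format(sprintf("non-numeric SMD field on line %d in %s", sel[i], path))
  }
  steps <- m[, 1]
  if (any(diff(steps) < 0)) {
    i <- which(diff(steps) < 0)[1] + 1L
    pf_stop_format(sprintf("SMD steps decrease at line %d in %s", sel[i], path))
  }
  if (anyDuplicated(steps)) {
    warning("duplicate SMD step numbers (restart overlap); keeping the last occurrence",
            call. = FALSE)
    keep <- !duplicated(steps, fromLast = TRUE)
    m <- m[keep, , drop = FALSE]
    steps <- m[, 1]
  }
  fvec <- m[, 5:7, drop = FALSE]
  f_engine <- if (kind == "projection") as.numeric(fvec %*% direction) else sqrt(rowSums(fvec^2))
  force_trace(time = steps * timestep * 1e-3,
              force = kcal_mol_A_to_pN(f_engine),
              position = m[, 2:4, drop = FALSE],
              direction = direction, source = "namd_log", replica_id = replica_id)
}

read_xvg_matrix <- function(path) {
  if (!file.exists(path)) pf_stop_input(sprintf(".xvg file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!startsWith(lines, "#") & !startsWith(lines, "@") & nzchar(trimws(lines)))
  if (length(keep) == 0L) pf_stop_format(sprintf("no numeric rows in %s", path))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  ncol_first <- length(fields[[1]])
  ragged <- which(lengths(fields) != ncol_first)
  if (length(ragged) > 0L)
    pf_stop_format(sprintf("ragged row on line %d in %s", keep[ragged[1]], path))
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = ncol_first, byrow = TRUE)
  if (anyNA(m)) {
    i <- which(apply(m, 1, anyNA))[1]
    pf_stop_format(sprintf("non-numeric row on line %d in %s", keep[i], path))
  }
  m
}

#' Parse a GROMACS pull .xvg file
#'
#' Skips `#` comments and `@` xmgrace directives. For `kind = "pullf"` the
#' columns are time (ps) and force (kJ mol^-1 nm^-1), converted to pN
#' (x 1.66054) and returned as a [force_trace()]. For `kind = "pullx"` the
#' columns are time and pull-coordinate position (nm), returned as a data
#' frame `time`/`value` with the position converted to Angstrom.
#'
#' @param path .xvg file.
#' @param kind `"pullf"` or `"pullx"`.
#' @param direction optional unit 3-vector recorded on the trace.
#' @param replica_id integer tag.
#' @return a `force_trace` (pullf) or data frame (pullx).
#' @export
parse_xvg <- function(path, kind = c("pullf", "pullx"), direction = NULL, replica_id = 1L) {
  kind <- match.arg(kind)
  m <- read_xvg_matrix(path)
  if (ncol(m) < 2L) pf_stop_format(sprintf("%s: expected at least 2 columns", path))
  if (kind == "pullf") {
    force_trace(time = m[, 1], force = kJ_mol_nm_to_pN(m[, 2]),
                direction = direction, source = "gromacs_xvg", replica_id = replica_id)
  } else {
    data.frame(time = m[, 1], value = m[, 2] * 10)  # nm -> Angstrom
  }
}

## ---- trajectories ---------------------------------------------------------

#' Read a multi-frame coordinate file
#'
#' Supports multi-model PDB (MODEL/ENDMDL blocks, or a single implicit
#' model) and plain XYZ trajectories. Every frame must contain the same
#' number of atoms.
#'
#' @param path trajectory file.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @return an object of class `trajectory`: list with `frames` (list of
#'   n x 3 coordinate matrices, Angstrom) and, for PDB input, `structure`
#'   (the first model as a `pdb_structure`).
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) pf_stop_input(sprintf("trajectory not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "xyz") "xyz" else "pdb"
  }
  if (format == "xyz") read_xyz_trajectory(path) else read_pdb_trajectory(path)
}

read_pdb_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  frames <- list()
  if (length(model_starts) == 0L) {
    idx <- which(is_atom)
    if (length(idx) == 0L) pf_stop_format(sprintf("no ATOM records in %s", path))
    a <- parse_pdb_atom_lines(lines[idx], idx)
    frames[[1]] <- as.matrix(a[, c("x", "y", "z")])
  } else {
    bounds <- c(model_starts, length(lines) + 1L)
    for (k in seq_along(model_starts)) {
      block <- seq(bounds[k], bounds[k + 1L] - 1L)
      idx <- block[is_atom[block]]
      if (length(idx) == 0L) next
      a <- parse_pdb_atom_lines(lines[idx], idx)
      frames[[length(frames) + 1L]] <- as.matrix(a[, c("x", "y", "z")])
    }
    if (length(frames) == 0L) pf_stop_format(sprintf("no ATOM records in %s", path))
  }
  n0 <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, integer(1)) != n0))
    pf_stop_format(sprintf("frames with differing atom counts in %s", path))
  structure(list(frames = frames, structure = read_pdb(path)), class = "trajectory")
}

read_xyz_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0L) pf_stop_format(sprintf("bad XYZ atom count on line %d in %s", i, path))
    if (i + 1L + n > length(lines)) pf_stop_format(sprintf("truncated XYZ frame at line %d in %s", i, path))
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(coords)) pf_stop_format(sprintf("non-numeric XYZ coordinates in frame starting line %d", i))
    frames[[length(frames) + 1L]] <- coords
    i <- i + 2L + n
  }
  if (length(frames) == 0L) pf_stop_format(sprintf("no frames in %s", path))
  structure(list(frames = frames, structure = NULL), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frame(s) of %d atoms\n",
              length(x$frames), nrow(x$frames[[1]])))
  invisible(x)
}

#' Write a multi-model PDB trajectory
#'
#' @param structure template `pdb_structure` (atom metadata).
#' @param frames list of n x 3 coordinate matrices.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_trajectory_pdb <- function(structure, frames, path) {
  stopifnot(inherits(structure, "pdb_structure"))
  con <- file(path, "w")
  on.exit(close(con))
  atoms <- structure$atoms
  for (k in seq_along(frames)) {
    atoms$x <- frames[[k]][, 1]; atoms$y <- frames[[k]][, 2]; atoms$z <- frames[[k]][, 3]
    writeLines(c(sprintf("MODEL     %4d", k), format_pdb_atom_lines(atoms), "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Center-of-mass distance series along a trajectory
#'
#' Per-frame distance between the mass-weighted centers of the fixed and
#' pulled selections - the abscissa of the force-versus-distance analysis.
#'
#' @param traj a `trajectory`.
#' @param fixed_idx,pulled_idx 1-based atom index vectors.
#' @param masses per-atom masses (amu), full length; defaults to the
#'   trajectory's structure masses or unit masses.
#' @return numeric vector, one distance (Angstrom) per frame.
#' @export
com_distance_series <- function(traj, fixed_idx, pulled_idx, masses = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj$frames[[1]])
  if (is.null(masses)) {
    masses <- if (!is.null(traj$structure)) traj$structure$atoms$mass else rep(1, n)
  }
  if (max(fixed_idx, pulled_idx) > n || min(fixed_idx, pulled_idx) < 1L)
    pf_stop_input("selection index out of range for trajectory frames")
  wf <- masses[fixed_idx] / sum(masses[fixed_idx])
  wp <- masses[pulled_idx] / sum(masses[pulled_idx])
  vapply(traj$frames, function(fr) {
    comf <- colSums(fr[fixed_idx, , drop = FALSE] * wf)
    comp <- colSums(fr[pulled_idx, , drop = FALSE] * wp)
    sqrt(sum((comp - comf)^2))
  }, numeric(1))
}
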