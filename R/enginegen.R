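# Per-direction, per-replica engine input rendering (NAMD configuration
# files, GROMACS .mdp/.ndx) and run-tree scaffolding with bash run scripts.
#
# Numbers are written with a period decimal separator regardless of locale:
# sprintf in C locale formatting via formatC/sprintf on doubles.

# Format a number so that re-parsing recovers it exactly: use the compact
# 6-decimal form when it is lossless (unit-vector components, round
# constants), otherwise fall back to 17 significant digits.
fmt_num <- function(x) {
  vapply(x, function(xi) {
    f <- sprintf("%.6f", xi)
    if (as.numeric(f) == xi) f else sprintf("%.17g", xi)
  }, character(1))
}

#' Construct a pulling plan
#'
#' Bundles everything needed to render one multidirectional constant-velocity
#' SMD campaign. Units are engine-native and never converted silently:
#' NAMD takes the spring constant in kcal mol^-1 A^-2 and the pulling
#' velocity in A per timestep; GROMACS takes kJ mol^-1 nm^-2 and nm ps^-1.
#'
#' @param engine `"namd"`, `"gromacs"` or `"toysim"`.
#' @param spring_k spring constant (> 0, engine units).
#' @param pull_velocity pulling velocity (> 0, engine units).
#' @param timestep integration timestep in fs.
#' @param n_steps number of MD steps (> 0).
#' @param n_replicas replicas per direction (>= 1); replicas differ only by
#'   the engine random seed, `base_seed + replica`.
#' @param fixed,pulled selection strings (see [atom_select()]).
#' @param output_root campaign root directory.
#' @param engine_passthrough named list of extra engine keywords copied
#'   verbatim, in order, into every rendered input.
#' @param base_seed integer base for per-replica seeds.
#' @return an object of class `pull_plan`.
#' @export
pull_plan <- function(engine = c("namd", "gromacs", "toysim"),
                      spring_k, pull_velocity, timestep = 2, n_steps = 1000,
                      n_replicas = 1, fixed = NULL, pulled = NULL,
                      output_root = "pullfan_run",
                      engine_passthrough = list(), base_seed = 1000) {
  engine <- match.arg(engine)
  if (!is.numeric(spring_k) || spring_k <= 0) pf_stop_config("spring_k must be > 0")
  if (!is.numeric(pull_velocity) || pull_velocity <= 0) pf_stop_config("pull_velocity must be > 0")
  if (n_steps <= 0) pf_stop_config("n_steps must be > 0")
  if (n_replicas < 1) pf_stop_config("n_replicas must be >= 1")
  structure(list(engine = engine, spring_k = spring_k, pull_velocity = pull_velocity,
                 timestep = timestep, n_steps = as.integer(n_steps),
                 n_replicas = as.integer(n_replicas), fixed = fixed, pulled = pulled,
                 output_root = output_root, engine_passthrough = engine_passthrough,
                 base_seed = as.integer(base_seed)),
            class = "pull_plan")
}

check_unit_direction <- function(direction) {
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    pf_stop("direction vector is not unit length", "pullfan_internal_error")
  direction
}

## ---- NAMD -----------------------------------------------------------------

#' Render a NAMD constant-velocity SMD configuration
#'
#' Fixed atoms are flagged through the B-factor column of the reference PDB
#' (`fixedAtomsCol B`), SMD-pulled atoms through its occupancy column - the
#' standard NAMD convention (see [render_namd_reference_pdb()]).
#'
#' @param plan a `pull_plan` with `engine = "namd"`.
#' @param direction unit 3-vector for this pulling direction.
#' @param ref_pdb file name of the annotated reference PDB.
#' @param output_name NAMD `outputname`.
#' @param seed optional engine random seed for this replica.
#' @return configuration text (single string).
#' @export
render_namd_config <- function(plan, direction, ref_pdb = "ref.pdb",
                               output_name = "smd_out", seed = NULL) {
  if (plan$engine != "namd") pf_stop_config("plan engine is not 'namd'")
  check_unit_direction(direction)
  pass <- vapply(seq_along(plan$engine_passthrough), function(i) {
    sprintf("%-18s %s", names(plan$engine_passthrough)[i],
            as.character(plan$engine_passthrough[[i]]))
  }, character(1))
  lines <- c(
    "# constant-velocity SMD (generated by pullfan)",
    sprintf("timestep           %s", fmt_num(plan$timestep)),
    sprintf("outputname         %s", output_name),
    if (!is.null(seed)) sprintf("seed               %d", as.integer(seed)),
    pass,
    "fixedAtoms         on",
    sprintf("fixedAtomsFile     %s", ref_pdb),
    "fixedAtomsCol      B",
    "SMD                on",
    sprintf("SMDFile            %s", ref_pdb),
    sprintf("SMDk               %s", fmt_num(plan$spring_k)),
    sprintf("SMDVel             %s", fmt_num(plan$pull_velocity)),
    sprintf("SMDDir             %s %s %s",
            fmt_num(direction[1]), fmt_num(direction[2]), fmt_num(direction[3])),
    "SMDOutputFreq      100",
    sprintf("run                %d", plan$n_steps)
  )
  paste(lines, collapse = "\n")
}

#' Parse a rendered NAMD SMD configuration
#'
#' Recovers the spring constant, pulling velocity and direction vector from
#' configuration text; used to verify that rendering is lossless.
#'
#' @param text configuration text.
#' @return list with `spring_k`, `pull_velocity`, `direction`.
#' @export
parse_namd_config <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  get1 <- function(key) {
    hit <- grep(sprintf("^%s\\s", key), lines, value = TRUE)
    if (length(hit) == 0L) pf_stop_format(sprintf("NAMD config: key '%s' not found", key))
    trimws(sub(sprintf("^%s\\s+", key), "", hit[1]))
  }
  list(
    spring_k = as.numeric(get1("SMDk")),
    pull_velocity = as.numeric(get1("SMDVel")),
    direction = as.numeric(strsplit(get1("SMDDir"), "\\s+")[[1]])
  )
}

#' Annotated NAMD reference PDB
#'
#' Copy of the structure with B-factor 1.00 on fixed atoms (read by
#' `fixedAtomsCol B`) and occupancy 1.00 on SMD-pulled atoms, 0.00 elsewhere
#' in both columns.
#'
#' @param structure a `pdb_structure`.
#' @param fixed_idx,pulled_idx disjoint non-empty 1-based index sets.
#' @return a `pdb_structure` copy with the flag columns set.
#' @export
render_namd_reference_pdb <- function(structure, fixed_idx, pulled_idx) {
  if (length(fixed_idx) == 0L || length(pulled_idx) == 0L)
    pf_stop_input("fixed and pulled selections must be non-empty")
  overlap <- intersect(fixed_idx, pulled_idx)
  if (length(overlap) > 0L)
    pf_stop_input(sprintf("fixed and pulled selections overlap (%d atoms, e.g. index %d)",
                          length(overlap), overlap[1]))
  out <- structure
  out$atoms$beta <- 0
  out$atoms$occupancy <- 0
  out$atoms$beta[fixed_idx] <- 1
  out$atoms$occupancy[pulled_idx] <- 1
  out
}

## ---- GROMACS --------------------------------------------------------------

#' Render a GROMACS pull-code .mdp fragment
#'
#' Constant-velocity pulling along an absolute direction
#' (`pull-coord1-geometry = direction`); the fixed group is immobilized with
#' freeze groups rather than position restraints so no topology edit is
#' needed (frozen atoms are excluded from pressure coupling - documented
#' trade-off).
#'
#' @param plan a `pull_plan` with `engine = "gromacs"`.
#' @param direction unit 3-vector.
#' @param seed optional `gen-seed` for this replica.
#' @return .mdp text (single string).
#' @export
render_gromacs_mdp <- function(plan, direction, seed = NULL) {
  if (plan$engine != "gromacs") pf_stop_config("plan engine is not 'gromacs'")
  check_unit_direction(direction)
  pass <- vapply(seq_along(plan$engine_passthrough), function(i) {
    sprintf("%-22s = %s", names(plan$engine_passthrough)[i],
            as.character(plan$engine_passthrough[[i]]))
  }, character(1))
  lines <- c(
    "; constant-velocity pull (generated by pullfan)",
    sprintf("dt                     = %s", fmt_num(plan$timestep / 1000)),
    sprintf("nsteps                 = %d", plan$n_steps),
    if (!is.null(seed)) sprintf("gen-seed               = %d", as.integer(seed)),
    pass,
    "freezegrps             = fixed",
    "freezedim              = Y Y Y",
    "pull                   = yes",
    "pull-ngroups           = 2",
    "pull-ncoords           = 1",
    "pull-group1-name       = fixed",
    "pull-group2-name       = pulled",
    "pull-coord1-type       = umbrella",
    "pull-coord1-geometry   = direction",
    "pull-coord1-groups     = 1 2",
    sprintf("pull-coord1-vec        = %s %s %s",
            fmt_num(direction[1]), fmt_num(direction[2]), fmt_num(direction[3])),
    sprintf("pull-coord1-rate       = %s", fmt_num(plan$pull_velocity)),
    sprintf("pull-coord1-k          = %s", fmt_num(plan$spring_k)),
    "pull-coord1-start      = yes"
  )
  paste(lines, collapse = "\n")
}

#' Parse a rendered GROMACS .mdp
#'
#' @param text .mdp text.
#' @return list with `spring_k`, `pull_velocity`, `direction`, `groups`.
#' @export
parse_gromacs_mdp <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!startsWith(trimws(lines), ";")]
  kv <- regmatches(lines, regexec("^[[:space:]]*([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.*)$", lines))
  kv <- kv[lengths(kv) == 3L]
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  get1 <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) pf_stop_format(sprintf(".mdp: key '%s' not found", key))
    vals[i]
  }
  list(
    spring_k = as.numeric(get1("pull-coord1-k")),
    pull_velocity = as.numeric(get1("pull-coord1-rate")),
    direction = as.numeric(strsplit(get1("pull-coord1-vec"), "\\s+")[[1]]),
    groups = c(get1("pull-group1-name"), get1("pull-group2-name"))
  )
}

#' Render a GROMACS index (.ndx) file
#'
#' @param groups named list of 1-based atom positions.
#' @return .ndx text: `[ name ]` headers and 1-based serials, at most 15 per
#'   line.
#' @export
render_ndx <- function(groups) {
  if (length(groups) == 0L) pf_stop_config("no index groups given")
  if (anyDuplicated(names(groups))) pf_stop_config("duplicate index group name")
  blocks <- lapply(names(groups), function(nm) {
    idx <- as.integer(groups[[nm]])
    rows <- split(idx, ceiling(seq_along(idx) / 15))
    c(sprintf("[ %s ]", nm),
      vapply(rows, function(r) paste(r, collapse = " "), character(1)))
  })
  paste(unlist(blocks), collapse = "\n")
}

#' Parse a GROMACS index file
#'
#' @param text .ndx text.
#' @return named list of integer vectors.
#' @export
parse_ndx <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  out <- list()
  current <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    m <- regexec("^\\[\\s*(.+?)\\s*\\]$", ln)[[1]]
    if (m[1] != -1L) {
      current <- regmatches(ln, regexec("^\\[\\s*(.+?)\\s*\\]$", ln))[[1]][2]
      out[[current]] <- integer(0)
    } else {
      if (is.null(current)) pf_stop_format(".ndx: indices before any [ group ] header")
      out[[current]] <- c(out[[current]], as.integer(strsplit(ln, "\\s+")[[1]]))
    }
  }
  out
}

## ---- scaffolding ----------------------------------------------------------

write_campaign_cfg <- function(plan, path, extra = list()) {
  kv <- c(list(engine = plan$engine, spring_k = plan$spring_k,
               pull_velocity = plan$pull_velocity, timestep_fs = plan$timestep,
               n_steps = plan$n_steps, n_replicas = plan$n_replicas,
               base_seed = plan$base_seed), extra)
  writeLines(sprintf("%s = %s", names(kv), vapply(kv, as.character, character(1))), path)
  invisible(path)
}

read_campaign_cfg <- function(path) {
  if (!file.exists(path)) pf_stop_input(sprintf("campaign config not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^[[:space:]]*([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.*)$", lines))
  kv <- kv[lengths(kv) == 3L]
  setNames(lapply(kv, function(p) trimws(p[3])), vapply(kv, `[`, character(1), 2))
}

render_run_script <- function(plan, direction_label) {
  body <- switch(plan$engine,
    namd = vapply(seq_len(plan$n_replicas), function(r)
      sprintf("namd3 +p${NPROC:-1} smd_r%d.conf > smd_r%d.log", r, r), character(1)),
    gromacs = unlist(lapply(seq_len(plan$n_replicas), function(r) c(
      sprintf("gmx grompp -f pull_r%d.mdp -c conf.gro -p topol.top -n index.ndx -o pull_r%d.tpr", r, r),
      sprintf("gmx mdrun -deffnm pull_r%d -pf pullf_r%d.xvg -px pullx_r%d.xvg", r, r, r)))),
    pf_stop_config("run scripts are rendered for namd or gromacs engines only"))
  paste(c("#!/bin/bash",
          "set -e",
          sprintf("# direction %s: %d replica(s)", direction_label, plan$n_replicas),
          body), collapse = "\n")
}

#' Scaffold a multidirectional SMD run tree
#'
#' Creates one subdirectory per pulling direction (named by its label), each
#' holding the per-replica engine inputs (NAMD `.conf` plus annotated
#' `ref.pdb`, or GROMACS `.mdp` plus `index.ndx`) and a single `run.sh`; a
#' top-level `manifest.tsv` lists every direction and a `campaign.cfg`
#' records the plan. Replicas differ only by the engine random seed
#' `base_seed + replica`.
#'
#' @param plan a `pull_plan` (engine `"namd"` or `"gromacs"`).
#' @param dset a `direction_set`.
#' @param structure the `pdb_structure` the selections refer to.
#' @param overwrite overwrite a pre-existing non-empty root? Default `FALSE`:
#'   scaffolding into a non-empty root is refused.
#' @return an object of class `run_tree` (list with `root`, `dirs`, `plan`).
#' @export
scaffold <- function(plan, dset, structure, overwrite = FALSE) {
  root <- plan$output_root
  if (dir.exists(root) && length(list.files(root, all.files = TRUE, no.. = TRUE)) > 0 && !overwrite)
    pf_stop_input(sprintf("output root '%s' exists and is not empty (use overwrite = TRUE)", root))
  fixed_idx <- atom_select(structure, plan$fixed)
  pulled_idx <- atom_select(structure, plan$pulled)
  if (length(fixed_idx) == 0L || length(pulled_idx) == 0L)
    pf_stop_input("fixed/pulled selection resolved to zero atoms")
  if (length(intersect(fixed_idx, pulled_idx)) > 0L)
    pf_stop_input("fixed and pulled selections overlap")
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  d <- dset$directions
  for (i in seq_len(nrow(d))) {
    sub <- file.path(root, d$label[i])
    dir.create(sub, showWarnings = FALSE)
    v <- direction_row_vector(dset, i)
    if (plan$engine == "namd") {
      ref <- render_namd_reference_pdb(structure, fixed_idx, pulled_idx)
      write_pdb(ref, file.path(sub, "ref.pdb"))
      for (r in seq_len(plan$n_replicas)) {
        writeLines(render_namd_config(plan, v, ref_pdb = "ref.pdb",
                                      output_name = sprintf("smd_r%d", r),
                                      seed = plan$base_seed + r),
                   file.path(sub, sprintf("smd_r%d.conf", r)))
      }
    } else if (plan$engine == "gromacs") {
      writeLines(render_ndx(list(fixed = fixed_idx, pulled = pulled_idx)),
                 file.path(sub, "index.ndx"))
      for (r in seq_len(plan$n_replicas)) {
        writeLines(render_gromacs_mdp(plan, v, seed = plan$base_seed + r),
                   file.path(sub, sprintf("pull_r%d.mdp", r)))
      }
    } else {
      pf_stop_config("scaffold supports namd and gromacs engines")
    }
    script <- file.path(sub, "run.sh")
    writeLines(render_run_script(plan, d$label[i]), script)
    Sys.chmod(script, "0755")
  }
  write_direction_table(dset, file.path(root, "manifest.tsv"))
  write_campaign_cfg(plan, file.path(root, "campaign.cfg"))
  # base:: because the `structure` argument shadows base::structure() here
  base::structure(list(root = root, dirs = file.path(root, d$label), plan = plan),
                  class = "run_tree")
}

#' @export
print.run_tree <- function(x, ...) {
  cat(sprintf("run_tree: %s (%d direction(s), engine %s, %d replica(s))\n",
              x$root, length(x$dirs), x$plan$engine, x$plan$n_replicas))
  invisible(x)
}
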