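# High-level drivers wiring the modules into the multidirectional SMD
# workflow: setup (PDB -> run tree), simulate (toy engine campaign) and
# analyze (run tree -> tables/plots). The command-line entry point in
# inst/cli/pullfan is a thin wrapper around these.

#' Set up a multidirectional SMD campaign from a PDB file
#'
#' Reads the complex, computes the principal axis between the fixed and
#' pulled selections, generates the direction fan, scaffolds the engine
#' input tree and writes a VMD Tcl arrow script (`directions.tcl`) at the
#' root.
#'
#' @param pdb path to the complex in PDB format.
#' @param fixed,pulled selection strings (see [atom_select()]); must resolve
#'   non-empty and disjoint.
#' @param engine `"namd"` or `"gromacs"`.
#' @param thetas,phis direction grid in degrees.
#' @param spring_k,pull_velocity,timestep,n_steps,n_replicas,base_seed,
#'   engine_passthrough see [pull_plan()].
#' @param output_root campaign directory to create.
#' @param arrow_scale VMD arrow length in Angstrom.
#' @param overwrite allow scaffolding into a non-empty root.
#' @return the [scaffold()] `run_tree`, invisibly.
#' @export
smd_setup <- function(pdb, fixed, pulled, engine = "namd",
                      thetas = c(0, 45, 90), phis = c(0, 90, 180, 270),
                      spring_k = 7, pull_velocity = 0.00002, timestep = 2,
                      n_steps = 5e6, n_replicas = 5, base_seed = 1000L,
                      engine_passthrough = list(), output_root = "pullfan_run",
                      arrow_scale = 20, overwrite = FALSE) {
  structure_ <- read_pdb(pdb)
  axis <- principal_axis(structure_, fixed, pulled)
  dset <- generate_directions(axis, thetas, phis)
  plan <- pull_plan(engine = engine, spring_k = spring_k,
                    pull_velocity = pull_velocity, timestep = timestep,
                    n_steps = n_steps, n_replicas = n_replicas,
                    fixed = fixed, pulled = pulled, output_root = output_root,
                    engine_passthrough = engine_passthrough, base_seed = base_seed)
  tree <- scaffold(plan, dset, structure_, overwrite = overwrite)
  origin <- center_of_mass(structure_, pulled)
  writeLines(render_vmd_arrows(dset, origin = origin, scale = arrow_scale),
             file.path(tree$root, "directions.tcl"))
  message(sprintf("setup: %d direction(s), %d replica(s), engine %s -> %s",
                  nrow(dset$directions), n_replicas, engine, output_root))
  invisible(tree)
}

#' Run the toy-engine campaign for a direction set
#'
#' Convenience wrapper around [run_toy_campaign()] that defaults to the
#' built-in anisotropic complex and derives the direction fan from the
#' model's own fixed -> pulled axis.
#'
#' @param output_root campaign directory to write.
#' @param model a [toy_model()]; default [make_anisotropic_complex()].
#' @param thetas,phis direction grid in degrees.
#' @param n_replicas,base_seed,k_spring,v_pull,dt,n_steps,log_stride see
#'   [run_toy_campaign()].
#' @param complex_seed seed for the built-in complex geometry.
#' @return invisibly, the [run_toy_campaign()] result.
#' @export
smd_simulate <- function(output_root, model = NULL,
                         thetas = c(0, 45, 90), phis = c(0, 90, 180, 270),
                         n_replicas = 5, base_seed = 1000L,
                         k_spring = 50, v_pull = 0.04, dt = 0.002,
                         n_steps = 2e5, log_stride = 200L, complex_seed = 1L) {
  if (is.null(model)) {
    model <- make_anisotropic_complex(complex_seed)$model
  }
  wp <- model$masses[model$pulled_idx] / sum(model$masses[model$pulled_idx])
  wf <- model$masses[model$fixed_idx] / sum(model$masses[model$fixed_idx])
  axis <- colSums(model$positions[model$pulled_idx, , drop = FALSE] * wp) -
          colSums(model$positions[model$fixed_idx, , drop = FALSE] * wf)
  dset <- generate_directions(axis, thetas, phis)
  run_toy_campaign(model, dset, n_replicas = n_replicas, base_seed = base_seed,
                   k_spring = k_spring, v_pull = v_pull, dt = dt,
                   n_steps = n_steps, log_stride = log_stride, root = output_root)
}

detect_direction_engine <- function(dirpath) {
  logs <- list.files(dirpath, pattern = "\\.log$", full.names = TRUE)
  has_smd <- any(vapply(logs, function(f)
    any(startsWith(readLines(f, n = 200, warn = FALSE), "SMD ")), logical(1)))
  xvgs <- list.files(dirpath, pattern = "^pullf.*\\.xvg$", full.names = TRUE)
  if (has_smd && length(xvgs) > 0L)
    pf_stop_config(sprintf("%s contains both NAMD SMD logs and pull .xvg files; pass an explicit engine", dirpath))
  if (has_smd) "namd" else if (length(xvgs) > 0L) "gromacs" else "none"
}

#' Analyze a multidirectional campaign tree
#'
#' Walks the per-direction subdirectories listed in `manifest.tsv`,
#' auto-detects the engine dialect (NAMD-style `SMD` log lines versus
#' GROMACS `pullf*.xvg`), parses every replica into force traces and writes:
#' the per-direction force-time ensemble tables, the anisotropy table
#' (`anisotropy.tsv`) and optional plots. Directions with no parsable output
#' are reported as warnings and skipped; the run fails only if every
#' direction is empty. Analysis is deterministic: two invocations on the
#' same inputs give identical results.
#'
#' @param root campaign directory (from [scaffold()] or [run_toy_campaign()]).
#' @param out_dir where to write result tables; default `<root>/analysis`.
#' @param grid_dt replica-aggregation grid spacing in ps (default: smallest
#'   native interval, see [aggregate_replicas()]).
#' @param smooth_window smoothing for rupture-force extraction (default 0,
#'   off).
#' @param plots also write PNG plots.
#' @return list with `anisotropy` (data frame), `ensembles` (named list of
#'   `replica_ensemble`), `skipped` (character vector of direction labels
#'   with no output).
#' @export
smd_analyze <- function(root, out_dir = file.path(root, "analysis"),
                        grid_dt = NULL, smooth_window = 0, plots = FALSE) {
  manifest <- read_direction_table(file.path(root, "manifest.tsv"))
  cfg <- read_campaign_cfg(file.path(root, "campaign.cfg"))
  timestep_fs <- as.numeric(cfg$timestep_fs %||% 2)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list()
  ensembles <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(manifest))) {
    label <- manifest$label[i]
    v <- as.numeric(manifest[i, c("vx", "vy", "vz")])
    dirpath <- file.path(root, label)
    if (!dir.exists(dirpath)) { skipped <- c(skipped, label); next }
    engine <- detect_direction_engine(dirpath)
    traces <- list()
    if (engine == "namd") {
      logs <- sort(list.files(dirpath, pattern = "\\.log$", full.names = TRUE))
      for (r in seq_along(logs)) {
        tr <- tryCatch(parse_namd_smd_log(logs[r], timestep = timestep_fs,
                                          direction = v, replica_id = r),
                       pullfan_error = function(e) NULL)
        if (!is.null(tr)) traces[[length(traces) + 1L]] <- tr
      }
    } else if (engine == "gromacs") {
      xvgs <- sort(list.files(dirpath, pattern = "^pullf.*\\.xvg$", full.names = TRUE))
      for (r in seq_along(xvgs)) {
        tr <- tryCatch(parse_xvg(xvgs[r], kind = "pullf", direction = v, replica_id = r),
                       pullfan_error = function(e) NULL)
        if (!is.null(tr)) traces[[length(traces) + 1L]] <- tr
      }
    }
    if (length(traces) == 0L) {
      warning(sprintf("direction %s: no parsable SMD output, skipped", label), call. = FALSE)
      skipped <- c(skipped, label)
      next
    }
    ens <- aggregate_replicas(traces, grid_dt = grid_dt)
    ensembles[[label]] <- ens
    summaries[[length(summaries) + 1L]] <-
      rupture_summary(traces, label, manifest$theta[i], manifest$phi[i],
                      smooth_window = smooth_window)
    write_tsv_table(data.frame(time = ens$common_time, mean_force = ens$mean_force,
                               sd_force = ens$sd_force),
                    file.path(out_dir, sprintf("force_time_%s.tsv", label)),
                    units = "time ps, force pN")
    if (plots) {
      ggplot2::ggsave(file.path(out_dir, sprintf("force_time_%s.png", label)),
                      plot_force_time(ens, title = label), width = 6, height = 4, dpi = 120)
    }
  }
  if (length(summaries) == 0L)
    pf_stop_input(sprintf("no direction in %s contains parsable SMD output", root))
  tab <- anisotropy_table(summaries)
  write_tsv_table(tab, file.path(out_dir, "anisotropy.tsv"),
                  units = "theta/phi deg, forces pN")
  if (plots) {
    ggplot2::ggsave(file.path(out_dir, "anisotropy.png"), plot_anisotropy(tab),
                    width = 6, height = 4, dpi = 120)
  }
  list(anisotropy = tab, ensembles = ensembles, skipped = skipped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a flat key = value run configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#' Used by the command-line wrapper, where flags override file values which
#' override defaults.
#'
#' @param path config file path.
#' @return named list of character values.
#' @export
read_run_config <- function(path) {
  read_campaign_cfg(path)
}
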