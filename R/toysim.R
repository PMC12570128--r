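# Desk-scale steered overdamped-Langevin (Brownian) simulator of bead-spring
# complexes with breakable interface bonds. It emits NAMD-dialect SMD log
# text, so the whole setup -> run -> analysis loop can be exercised without
# an MD engine; it also doubles as the synthetic-fixture generator.
#
# Internal units: A, ps, pN, amu; friction gamma in pN ps / A;
# kB = 0.0138065 pN A / K.

#' Construct a toy bead-spring model
#'
#' @param positions n x 3 matrix of bead positions (Angstrom).
#' @param masses per-bead masses (amu).
#' @param friction per-bead friction gamma (pN ps / A, > 0); scalar recycled.
#' @param bonds data frame with columns `i`, `j` (1-based bead indices),
#'   `k` (pN/A), `r0` (A), `breakable` (logical), `r_break` (A; must exceed
#'   `r0` for breakable bonds).
#' @param temperature bath temperature in K (>= 0).
#' @param fixed_idx,pulled_idx disjoint 1-based index sets: immobilized
#'   beads and the spring-attached group.
#' @return an object of class `toy_model`.
#' @export
toy_model <- function(positions, masses, friction, bonds, temperature = 0,
                      fixed_idx, pulled_idx) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  masses <- rep_len(masses, n)
  friction <- rep_len(friction, n)
  if (any(friction <= 0)) pf_stop_config("friction must be > 0")
  if (temperature < 0) pf_stop_config("temperature must be >= 0")
  if (length(intersect(fixed_idx, pulled_idx)) > 0L)
    pf_stop_config("fixed and pulled bead sets overlap")
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0) {
    bad <- bonds$breakable & bonds$r_break <= bonds$r0
    if (any(bad)) pf_stop_config("breakable bonds must have r_break > r0")
  }
  structure(list(positions = positions, masses = masses, friction = friction,
                 bonds = bonds, temperature = temperature,
                 fixed_idx = sort(as.integer(fixed_idx)),
                 pulled_idx = sort(as.integer(pulled_idx))),
            class = "toy_model")
}

#' @export
print.toy_model <- function(x, ...) {
  cat(sprintf("toy_model: %d beads (%d fixed, %d pulled), %d bonds (%d breakable), T = %g K\n",
              nrow(x$positions), length(x$fixed_idx), length(x$pulled_idx),
              nrow(x$bonds), sum(x$bonds$breakable), x$temperature))
  invisible(x)
}

#' Constant-velocity SMD protocol for the toy engine
#'
#' @param direction unit 3-vector (normalized if not).
#' @param k_spring virtual spring constant (pN/A).
#' @param v_pull pulling velocity (A/ps).
#' @param dt timestep (ps, > 0).
#' @param n_steps number of steps.
#' @param seed RNG seed for the thermal noise.
#' @param log_stride emit one SMD log line (and one trajectory frame) every
#'   this many steps (>= 1).
#' @return an object of class `smd_protocol`.
#' @export
smd_protocol <- function(direction, k_spring = 50, v_pull = 0.04, dt = 0.002,
                         n_steps = 2e5, seed = 1L, log_stride = 200L) {
  if (dt <= 0) pf_stop_config("dt must be > 0")
  if (log_stride < 1) pf_stop_config("log_stride must be >= 1")
  structure(list(direction = normalize3(direction), k_spring = k_spring,
                 v_pull = v_pull, dt = dt, n_steps = as.integer(n_steps),
                 seed = as.integer(seed), log_stride = as.integer(log_stride)),
            class = "smd_protocol")
}

#' Instantaneous SMD spring force
#'
#' The constant-velocity spring law: the spring's free end moves at `v_pull`
#' along the direction, so the scalar force is
#' `k_spring * (v_pull * t - (com - com0) . direction)` and the force vector
#' is that scalar times the direction.
#'
#' @param t time (ps).
#' @param com_pulled current pulled-group COM (3-vector, A).
#' @param com0 pulled-group COM at t = 0.
#' @param proto an [smd_protocol()].
#' @return list with `scalar` (pN) and `vector` (pN, length 3).
#' @export
smd_force <- function(t, com_pulled, com0, proto) {
  ext <- proto$v_pull * t - sum((com_pulled - com0) * proto$direction)
  f <- proto$k_spring * ext
  list(scalar = f, vector = f * proto$direction)
}

#' Run a steered toy simulation
#'
#' Overdamped Euler-Maruyama dynamics: each free bead moves by
#' `(F/gamma) dt + sqrt(2 kB T dt / gamma) xi` per step; fixed beads never
#' move; breakable bonds are removed permanently the first step their length
#' exceeds `r_break`. Every `log_stride` steps one NAMD-dialect line
#' `SMD <step> <COM xyz> <F xyz>` is emitted with forces converted to
#' kcal mol^-1 A^-1, so [parse_namd_smd_log()] consumes the log unchanged.
#' Runs with the same model, protocol and seed are byte-identical.
#'
#' @param model a [toy_model()].
#' @param proto an [smd_protocol()].
#' @return list with `log` (character vector of SMD lines), `trace` (the
#'   equivalent [force_trace()] in pN, built without the text round-trip),
#'   `frames` (list of n x 3 coordinate matrices at log steps), `breaks`
#'   (data frame of bond-break events).
#' @export
run_toy_smd <- function(model, proto) {
  stopifnot(inherits(model, "toy_model"), inherits(proto, "smd_protocol"))
  n <- nrow(model$positions)
  is_fixed <- seq_len(n) %in% model$fixed_idx
  b <- model$bonds
  set.seed(proto$seed)
  res <- cpp_run_toy_smd(model$positions, model$masses, model$friction,
                         as.integer(b$i), as.integer(b$j),
                         as.numeric(b$k), as.numeric(b$r0),
                         as.logical(b$breakable), as.numeric(b$r_break),
                         model$temperature, is_fixed,
                         as.integer(model$pulled_idx), proto$direction,
                         proto$k_spring, proto$v_pull, proto$dt,
                         proto$n_steps, proto$log_stride, .KB_PN_A_K)
  lg <- res$log
  log_lines <- sprintf("SMD %d %.10g %.10g %.10g %.10g %.10g %.10g",
                       as.integer(lg[, 1]), lg[, 2], lg[, 3], lg[, 4],
                       pN_to_kcal_mol_A(lg[, 5]), pN_to_kcal_mol_A(lg[, 6]),
                       pN_to_kcal_mol_A(lg[, 7]))
  fvec <- lg[, 5:7, drop = FALSE]
  trace <- force_trace(time = lg[, 1] * proto$dt,
                       force = as.numeric(fvec %*% proto$direction),
                       position = lg[, 2:4, drop = FALSE],
                       direction = proto$direction, source = "toysim",
                       replica_id = 1L)
  frames <- lapply(seq_len(dim(res$frames)[3]), function(k) res$frames[, , k])
  list(log = log_lines, trace = trace, frames = frames, breaks = res$breaks)
}

## ---- built-in anisotropic complex -----------------------------------------

#' Built-in anisotropic two-cluster complex
#'
#' A fixed 3 x 3 bead plate and a compact pulled 4-bead tetrahedral cluster,
#' joined by five breakable interface bonds anchored at different plate
#' positions with staggered stiffnesses and break lengths. The lopsided
#' anchor pattern makes the quasi-static rupture force differ between all
#' nine default pulling directions (roughly 44 to 119 pN), a desk-scale
#' stand-in for an anisotropic protein-protein interface. The compact
#' pulled cluster keeps interface torques small, so the steered dynamics
#' follows the rigid-body quasi-static pathway closely. Also returns the
#' model rendered as a `pdb_structure` (chain A fixed, chain B pulled) so
#' the full setup pipeline runs on it.
#'
#' @param seed integer seed for the small deterministic coordinate jitter
#'   that breaks exact lattice symmetry.
#' @return list with `model` (a [toy_model()]) and `structure`
#'   (a `pdb_structure`).
#' @export
make_anisotropic_complex <- function(seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(x = c(-3, 0, 3), y = c(-3, 0, 3))
  posA <- cbind(grid$x, grid$y, 0)
  # compact tetrahedron centred above the plate
  posB <- rbind(c(0, 0, 4), c(1.2, 0.7, 5.5), c(-1.2, 0.7, 5.5), c(0, -1.4, 5.5))
  pos <- rbind(posA, posB) + matrix(runif(length(posA) + length(posB), -0.05, 0.05),
                                    ncol = 3)
  nA <- nrow(posA)
  idx_at <- function(x, y) which(grid$x == x & grid$y == y)

  prA <- t(combn(nA, 2))            # stiff internal bonds, all pairs
  prB <- t(combn(nrow(posB), 2)) + nA
  # breakable interface bonds: lopsided anchors, staggered k and break length
  iface <- data.frame(
    i = c(idx_at(-3, -3), idx_at(-3, 3), idx_at(0, -3), idx_at(3, 0), idx_at(0, 0)),
    j = nA + c(1, 3, 4, 2, 1),
    k = c(36.6, 13.0, 23.5, 9.5, 17.2),
    r_break_extra = c(0.82, 2.55, 1.36, 2.86, 2.02)
  )
  bonds <- data.frame(
    i = c(prA[, 1], prB[, 1], iface$i),
    j = c(prA[, 2], prB[, 2], iface$j),
    k = c(rep(100, nrow(prA)), rep(200, nrow(prB)), iface$k),
    r0 = NA_real_,
    breakable = c(rep(FALSE, nrow(prA) + nrow(prB)), rep(TRUE, nrow(iface))),
    r_break = NA_real_
  )
  # rest lengths from the jittered geometry; breakable bonds snap at
  # r0 + r_break_extra
  bonds$r0 <- sqrt(rowSums((pos[bonds$i, ] - pos[bonds$j, ])^2))
  bonds$r_break <- ifelse(bonds$breakable,
                          bonds$r0 + c(rep(NA, nrow(prA) + nrow(prB)),
                                       iface$r_break_extra),
                          Inf)
  model <- toy_model(positions = pos, masses = 12, friction = 5, bonds = bonds,
                     temperature = 10, fixed_idx = seq_len(nA),
                     pulled_idx = nA + seq_len(nrow(posB)))
  list(model = model, structure = toy_structure(model))
}

#' Render a toy model as a PDB structure
#'
#' Fixed beads become chain A, pulled beads chain B, any remaining beads
#' chain C; beads are written as carbon CA atoms, one residue each.
#'
#' @param model a [toy_model()].
#' @return a `pdb_structure`.
#' @export
toy_structure <- function(model) {
  n <- nrow(model$positions)
  chain <- rep("C", n)
  chain[model$fixed_idx] <- "A"
  chain[model$pulled_idx] <- "B"
  atoms <- data.frame(
    record = "ATOM", serial = seq_len(n), name = "CA",
    resname = "ALA", chain = chain, resseq = seq_len(n),
    x = model$positions[, 1], y = model$positions[, 2], z = model$positions[, 3],
    occupancy = 1, beta = 0, segid = "", element = "C",
    stringsAsFactors = FALSE
  )
  new_structure(atoms, title = "toy bead-spring complex")
}

## ---- quasi-static rupture oracle ------------------------------------------

rodrigues <- function(rot) {
  th <- sqrt(sum(rot^2))
  if (th < 1e-12) return(diag(3))
  k <- rot / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Quasi-static rupture-force scan of a toy model
#'
#' Independent brute-force estimate of the rupture force along one
#' direction: the pulled cluster is treated as a rigid body whose COM is
#' displaced by `s` along the direction; at each `s` the interface-bond
#' energy is minimized over the remaining rigid-body degrees of freedom
#' (transverse translation and rotation), breakable bonds snap permanently
#' once their relaxed length exceeds `r_break`, and the restoring force
#' projected on the direction is recorded. The maximum over `s` is the
#' quasi-static rupture force. No dynamics, friction, spring or noise is
#' involved, so this is an independent check on the steered simulator.
#'
#' @param model a [toy_model()].
#' @param direction unit 3-vector.
#' @param ds scan step in Angstrom.
#' @param s_max scan range in Angstrom.
#' @return list with `s`, `force` (pN) and `f_max`.
#' @export
quasistatic_force_scan <- function(model, direction, ds = 0.05, s_max = 10) {
  direction <- normalize3(direction)
  frame <- build_frame(direction)
  pidx <- model$pulled_idx
  p0 <- model$positions[pidx, , drop = FALSE]
  w <- model$masses[pidx] / sum(model$masses[pidx])
  c0 <- colSums(p0 * w)
  b <- model$bonds
  inter <- which((b$i %in% pidx) != (b$j %in% pidx))
  if (length(inter) == 0L) pf_stop_input("model has no interface bonds to scan")
  # orient every interface bond fixed-side -> pulled-side
  bi <- b$i[inter]; bj <- b$j[inter]
  swap <- bi %in% pidx
  tmp <- bi[swap]; bi[swap] <- bj[swap]; bj[swap] <- tmp
  k_b <- b$k[inter]; r0_b <- b$r0[inter]
  breakable <- b$breakable[inter]; rb <- b$r_break[inter]
  p_fix <- model$positions[bi, , drop = FALSE]
  p_pull_local <- sweep(model$positions[bj, , drop = FALSE], 2, c0)

  active <- rep(TRUE, length(inter))
  par <- rep(0, 5)  # (a, b) transverse translation + rotation vector
  bond_vecs <- function(par, s) {
    R <- rodrigues(par[3:5])
    shift <- c0 + s * direction + par[1] * frame$e1 + par[2] * frame$e2
    q <- p_pull_local %*% t(R) + matrix(shift, length(bi), 3, byrow = TRUE)
    q - p_fix
  }
  energy <- function(par, s) {
    v <- bond_vecs(par, s)
    r <- sqrt(rowSums(v^2))
    sum(0.5 * k_b[active] * (r[active] - r0_b[active])^2)
  }
  s_grid <- seq(0, s_max, by = ds)
  force <- numeric(length(s_grid))
  for (si in seq_along(s_grid)) {
    s <- s_grid[si]
    repeat {
      if (!any(active)) break
      opt <- optim(par, energy, s = s, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-12))
      par <- opt$par
      v <- bond_vecs(par, s)
      r <- sqrt(rowSums(v^2))
      snap <- active & breakable & r > rb
      if (!any(snap)) break
      active[snap] <- FALSE
    }
    if (!any(active)) { force[si:length(force)] <- 0; break }
    v <- bond_vecs(par, s)
    r <- sqrt(rowSums(v^2))
    proj <- as.numeric(v %*% direction) / r
    force[si] <- sum(k_b[active] * (r[active] - r0_b[active]) * proj[active])
  }
  list(s = s_grid, force = force, f_max = max(force))
}

## ---- campaign driver ------------------------------------------------------

#' Run a full toy SMD campaign over a direction set
#'
#' Runs `n_replicas` steered simulations per direction (replica `r` uses
#' seed `base_seed + r`) and, when `root` is given, writes the same tree
#' layout as [scaffold()]: one subdirectory per direction holding
#' `replica_<r>.log` in NAMD SMD dialect, plus `manifest.tsv` and
#' `campaign.cfg` at the root, ready for [smd_analyze()].
#'
#' @param model a [toy_model()].
#' @param dset a `direction_set`.
#' @param n_replicas replicas per direction.
#' @param base_seed integer; replica `r` runs with seed `base_seed + r`.
#' @param k_spring,v_pull,dt,n_steps,log_stride protocol parameters (see
#'   [smd_protocol()]).
#' @param root optional campaign output directory.
#' @param write_frames also write each replica's trajectory as a multi-model
#'   PDB (only meaningful with `root`; off by default to keep trees small).
#' @return invisibly, a list with `traces` (per direction: list of
#'   [force_trace()]), `summaries` (per direction [rupture_summary()]) and
#'   `anisotropy` (the [anisotropy_table()]).
#' @export
run_toy_campaign <- function(model, dset, n_replicas = 5, base_seed = 1000L,
                             k_spring = 50, v_pull = 0.04, dt = 0.002,
                             n_steps = 2e5, log_stride = 200L,
                             root = NULL, write_frames = FALSE) {
  d <- dset$directions
  if (!is.null(root)) {
    dir.create(root, recursive = TRUE, showWarnings = FALSE)
    write_direction_table(dset, file.path(root, "manifest.tsv"))
    plan <- pull_plan(engine = "toysim", spring_k = k_spring, pull_velocity = v_pull,
                      timestep = dt * 1000, n_steps = n_steps,
                      n_replicas = n_replicas, base_seed = base_seed)
    write_campaign_cfg(plan, file.path(root, "campaign.cfg"))
  }
  traces <- vector("list", nrow(d))
  summaries <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    v <- direction_row_vector(dset, i)
    dir_traces <- vector("list", n_replicas)
    if (!is.null(root)) dir.create(file.path(root, d$label[i]), showWarnings = FALSE)
    for (r in seq_len(n_replicas)) {
      proto <- smd_protocol(direction = v, k_spring = k_spring, v_pull = v_pull,
                            dt = dt, n_steps = n_steps,
                            seed = base_seed + r, log_stride = log_stride)
      run <- run_toy_smd(model, proto)
      tr <- run$trace
      tr$replica_id <- r
      dir_traces[[r]] <- tr
      if (!is.null(root)) {
        writeLines(run$log, file.path(root, d$label[i], sprintf("replica_%d.log", r)))
        if (write_frames) {
          write_trajectory_pdb(toy_structure(model), run$frames,
                               file.path(root, d$label[i], sprintf("replica_%d_traj.pdb", r)))
        }
      }
    }
    traces[[i]] <- dir_traces
    summaries[[i]] <- rupture_summary(dir_traces, d$label[i], d$theta[i], d$phi[i])
  }
  names(traces) <- d$label
  invisible(list(traces = traces, summaries = summaries,
                 anisotropy = anisotropy_table(summaries)))
}
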