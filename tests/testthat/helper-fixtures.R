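# Programmatic fixtures shared across the suite.

# A small two-chain PDB file with mixed elements and field values.
write_fixture_pdb <- function(path = tempfile(fileext = ".pdb"), n_per_chain = 5,
                              seed = 42) {
  set.seed(seed)
  lines <- character(0)
  serial <- 0L
  for (ch in c("A", "B")) {
    for (i in seq_len(n_per_chain)) {
      serial <- serial + 1L
      xyz <- round(runif(3, -20, 20), 3)
      el <- sample(c("C", "N", "O", "S"), 1)
      nm <- c(C = "CA", N = "N", O = "O", S = "SG")[[el]]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", nm), "ALA", ch, i, xyz[1], xyz[2], xyz[3],
        round(runif(1), 2), round(runif(1, 0, 50), 2), el))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# A random unit vector.
random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Synthetic NAMD SMD log with known contents; returns the known matrix too.
write_fixture_smd_log <- function(path = tempfile(fileext = ".log"),
                                  steps = c(100, 200, 300),
                                  pos = matrix(seq_len(3 * length(steps)), ncol = 3),
                                  forces = matrix(rnorm(3 * length(steps)), ncol = 3)) {
  lines <- c("Info: some NAMD preamble",
             sprintf("SMD %d %.10g %.10g %.10g %.10g %.10g %.10g",
                     steps, pos[, 1], pos[, 2], pos[, 3],
                     forces[, 1], forces[, 2], forces[, 3]),
             "WallClock: done")
  writeLines(lines, path)
  list(path = path, steps = steps, pos = pos, forces = forces)
}

# Synthetic pull-force .xvg.
write_fixture_xvg <- function(path = tempfile(fileext = ".xvg"),
                              time = seq(0, 9) * 0.5,
                              force = rnorm(10, 50, 10)) {
  lines <- c("# GROMACS pull force output",
             "@    title \"Pull force\"",
             "@    xaxis  label \"Time (ps)\"",
             sprintf("%.12g\t%.12g", time, force),
             "")
  writeLines(lines, path)
  list(path = path, time = time, force = force)
}

# Tiny free-bead toy model (no bonds).
free_bead_model <- function(gamma = 5, temperature = 0) {
  toy_model(positions = matrix(0, 1, 3), masses = 1, friction = gamma,
            bonds = data.frame(i = integer(0), j = integer(0), k = numeric(0),
                               r0 = numeric(0), breakable = logical(0),
                               r_break = numeric(0)),
            temperature = temperature, fixed_idx = integer(0), pulled_idx = 1L)
}

# Two beads joined by one breakable bond along z.
single_bond_model <- function(k_b = 5, r0 = 3, r_break = 5, gamma = 1) {
  toy_model(positions = rbind(c(0, 0, 0), c(0, 0, r0)), masses = 1,
            friction = gamma,
            bonds = data.frame(i = 1L, j = 2L, k = k_b, r0 = r0,
                               breakable = TRUE, r_break = r_break),
            temperature = 0, fixed_idx = 1L, pulled_idx = 2L)
}
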