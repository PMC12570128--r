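test_that("fixed-column PDB parsing reads coordinates, element and flags", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "HETATM    2 FE   HEM B   7      -4.500  10.250   0.125  0.50 12.34          FE"
  ), f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(unlist(s$atoms[1, c("x", "y", "z")], use.names = FALSE), c(1, 2, 3))
  expect_equal(s$atoms$element, c("C", "FE"))
  expect_equal(s$atoms$mass, c(12.011, 55.845))
  expect_equal(s$atoms$occupancy[2], 0.5)
  expect_equal(s$atoms$beta[2], 12.34)
  expect_equal(s$atoms$chain, c("A", "B"))
})

test_that("element inference from atom names handles hydrogens and metals", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1 HG11 VAL A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  VAL A   1       1.000   0.000   0.000  1.00  0.00",
    "HETATM    3 MG    MG B   2       2.000   0.000   0.000  1.00  0.00"
  ), f)
  s <- read_pdb(f)
  expect_equal(s$atoms$element, c("H", "C", "MG"))
})

test_that("unknown elements fall back to carbon mass with a warning", {
  expect_warning(m <- element_mass("Qq"), "fallback")
  expect_equal(m, 12.011)
  expect_gt(suppressWarnings(element_mass("ZZ")), 0)
})

test_that("multi-model files use the first model for the structure", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       9.000   9.000   9.000  1.00  0.00           C",
    "ENDMDL"
  ), f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 0)
})

test_that("read errors are specific: missing file, no atoms, bad coordinates", {
  expect_error(read_pdb(tempfile()), "not found", class = "pullfan_input_error")
  f <- tempfile(); writeLines("REMARK nothing here", f)
  expect_error(read_pdb(f), "no ATOM", class = "pullfan_format_error")
  f2 <- tempfile()
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       bad     0.000   0.000  1.00  0.00           C"
  ), f2)
  expect_error(read_pdb(f2), "line 2", class = "pullfan_format_error")
})

test_that("PDB round-trip preserves every parsed field", {
  f <- write_fixture_pdb()
  s1 <- read_pdb(f)
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(s1, f2)
  s2 <- read_pdb(f2)
  for (col in c("serial", "name", "resname", "chain", "resseq",
                "x", "y", "z", "occupancy", "beta", "element", "mass")) {
    expect_equal(s2$atoms[[col]], s1$atoms[[col]], info = col)
  }
})

test_that("write_pdb overrides beta/occupancy columns with 2 decimals", {
  f <- write_fixture_pdb(n_per_chain = 5)
  s <- read_pdb(f)
  out <- tempfile(fileext = ".pdb")
  write_pdb(s, out, beta_override = setNames(rep(1, 3), 1:3),
            occupancy_override = setNames(rep(0.25, 5), 6:10))
  lines <- grep("^ATOM", readLines(out), value = TRUE)
  expect_equal(substr(lines[1], 61, 66), "  1.00")
  expect_equal(sum(substr(lines, 55, 60) == "  0.25"), 5L)
  back <- read_pdb(out)
  expect_equal(back$atoms$beta[1:3], rep(1, 3))
  expect_equal(back$atoms$occupancy[6:10], rep(0.25, 5))
  # untouched coordinate fields are byte-identical to the original
  orig <- grep("^ATOM", readLines(f), value = TRUE)
  expect_equal(substr(lines, 31, 54), substr(orig, 31, 54))
})

test_that("selection grammar: chain, resid ranges, boolean operators", {
  f <- write_fixture_pdb(n_per_chain = 5)
  s <- read_pdb(f)
  expect_equal(atom_select(s, "chain A"), 1:5)
  expect_equal(atom_select(s, "chain B"), 6:10)
  expect_equal(atom_select(s, "chain A and resid 1-3"), 1:3)
  expect_equal(atom_select(s, "chain A or chain B"), 1:10)
  expect_equal(atom_select(s, "not chain A"), 6:10)
  expect_equal(atom_select(s, "(chain A or chain B) and resid 2"), c(2L, 7L))
  expect_equal(atom_select(s, "CHAIN A AND RESID 1"), 1L)  # keywords case-insensitive
  expect_error(atom_select(s, "chain"), "needs a value", class = "pullfan_format_error")
  expect_error(atom_select(s, "chain A and and B"), "position", class = "pullfan_format_error")
  expect_error(atom_select(s, "banana A"), "unknown keyword", class = "pullfan_format_error")
  expect_warning(atom_select(s, "chain Z"), "no atoms")
})

test_that("selection partition property: X union not-X is everything", {
  for (seed in 1:5) {
    f <- write_fixture_pdb(seed = seed, n_per_chain = sample(3:8, 1))
    s <- read_pdb(f)
    for (expr in c("chain A", "resid 2-4", "name CA")) {
      inside <- atom_select(s, expr)
      outside <- suppressWarnings(atom_select(s, paste("not", expr)))
      expect_equal(sort(c(inside, outside)), seq_len(nrow(s$atoms)))
      expect_length(intersect(inside, outside), 0)
    }
  }
})

test_that("center of mass is the mass-weighted mean and is equivariant", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           H",
    "ATOM      2  O   GLY A   1       0.000   0.000   4.000  1.00  0.00           C"
  ), f)
  s <- read_pdb(f)  # masses 1.008 and 12.011
  com <- center_of_mass(s)
  expect_equal(com[3], 4 * 12.011 / (1.008 + 12.011))
  expect_equal(center_of_mass(s, weighting = "geometric")[3], 2)

  fx <- write_fixture_pdb()
  sf <- read_pdb(fx)
  com0 <- center_of_mass(sf)
  set.seed(7)
  for (i in 1:5) {
    t <- runif(3, -50, 50)
    R <- random_rotation()
    s2 <- sf
    xyz <- as.matrix(sf$atoms[, c("x", "y", "z")])
    moved <- xyz %*% t(R) + matrix(t, nrow(xyz), 3, byrow = TRUE)
    s2$atoms$x <- moved[, 1]; s2$atoms$y <- moved[, 2]; s2$atoms$z <- moved[, 3]
    expect_equal(center_of_mass(s2), as.numeric(R %*% com0 + t), tolerance = 1e-10)
  }
  expect_error(center_of_mass(s, integer(0)), class = "pullfan_input_error")
})

test_that("principal axis is unit, antisymmetric and translation-invariant", {
  f <- write_fixture_pdb()
  s <- read_pdb(f)
  ax <- principal_axis(s, "chain A", "chain B")
  expect_equal(sqrt(sum(ax^2)), 1, tolerance = 1e-12)
  expect_equal(principal_axis(s, "chain B", "chain A"), -ax)
  s2 <- s
  s2$atoms$x <- s$atoms$x + 100; s2$atoms$y <- s$atoms$y - 3; s2$atoms$z <- s$atoms$z + 0.5
  expect_equal(principal_axis(s2, "chain A", "chain B"), ax, tolerance = 1e-10)
})

test_that("coincident centers of mass give a degenerate-axis error", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   1.000   1.000  1.00  0.00           C",
    "ATOM      2  CA  ALA B   1       1.000   1.000   1.000  1.00  0.00           C"
  ), f)
  s <- read_pdb(f)
  expect_error(principal_axis(s, "chain A", "chain B"), "degenerate",
               class = "pullfan_input_error")
})

test_that("parsing agrees with an independent PDB reader on the fixture", {
  skip_if_not_installed("bio3d")
  f <- write_fixture_pdb()
  s <- read_pdb(f)
  ref <- bio3d::read.pdb(f)
  expect_equal(s$atoms$x, ref$atom$x)
  expect_equal(s$atoms$y, ref$atom$y)
  expect_equal(s$atoms$z, ref$atom$z)
  expect_equal(s$atoms$name, ref$atom$elety)
  expect_equal(s$atoms$chain, ref$atom$chain)
})
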