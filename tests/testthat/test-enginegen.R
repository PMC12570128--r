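random_plan <- function(engine) {
  pull_plan(engine = engine,
            spring_k = runif(1, 0.1, 5000),
            pull_velocity = runif(1, 1e-6, 1),
            timestep = sample(c(1, 2, 4), 1),
            n_steps = sample(1e3:1e6, 1),
            n_replicas = sample(1:5, 1),
            fixed = "chain A", pulled = "chain B",
            engine_passthrough = list(comment_tag = paste0("run", sample(1e4, 1))))
}

test_that("NAMD config contains the SMD contract lines with formatted direction", {
  plan <- pull_plan("namd", spring_k = 7, pull_velocity = 2e-5, timestep = 2,
                    n_steps = 100, engine_passthrough = list(outputname2 = "smd_run"))
  txt <- render_namd_config(plan, c(0, 0, 1))
  expect_match(txt, "SMD                on")
  expect_match(txt, "SMDDir             0.000000 0.000000 1.000000", fixed = TRUE)
  expect_match(txt, "fixedAtomsCol      B")
  expect_match(txt, "outputname2        smd_run")
  expect_error(render_namd_config(plan, c(0, 0, 2)), class = "pullfan_internal_error")
})

test_that("NAMD render -> parse recovers k, v and direction exactly (randomized)", {
  set.seed(101)
  for (i in 1:100) {
    plan <- random_plan("namd")
    v <- random_unit()
    got <- parse_namd_config(render_namd_config(plan, v))
    expect_identical(got$spring_k, plan$spring_k)
    expect_identical(got$pull_velocity, plan$pull_velocity)
    expect_identical(got$direction, v)
  }
})

test_that("GROMACS mdp contains pull-code contract and parses back exactly", {
  plan <- pull_plan("gromacs", spring_k = 1000, pull_velocity = 0.01,
                    timestep = 2, n_steps = 500)
  txt <- render_gromacs_mdp(plan, c(0, 0, 1))
  expect_match(txt, "pull                   = yes", fixed = TRUE)
  expect_match(txt, "pull-coord1-vec        = 0.000000 0.000000 1.000000", fixed = TRUE)
  expect_match(txt, "pull-coord1-rate       = 0.010000", fixed = TRUE)
  expect_match(txt, "pull-coord1-k          = 1000.000000", fixed = TRUE)
  expect_match(txt, "freezedim              = Y Y Y", fixed = TRUE)
  set.seed(202)
  for (i in 1:100) {
    plan <- random_plan("gromacs")
    v <- random_unit()
    got <- parse_gromacs_mdp(render_gromacs_mdp(plan, v))
    expect_identical(got$spring_k, plan$spring_k)
    expect_identical(got$pull_velocity, plan$pull_velocity)
    expect_identical(got$direction, v)
    expect_identical(got$groups, c("fixed", "pulled"))
  }
})

test_that("numbers in engine files use a period decimal separator", {
  old <- Sys.getenv("LC_NUMERIC")
  plan <- pull_plan("gromacs", spring_k = 1234.5, pull_velocity = 0.25,
                    timestep = 2, n_steps = 10)
  txt <- render_gromacs_mdp(plan, c(0, 0, 1))
  expect_false(grepl(",", txt, fixed = TRUE))
  expect_match(txt, "1234.500000", fixed = TRUE)
})

test_that("reference PDB tags fixed atoms in B and pulled atoms in occupancy", {
  f <- write_fixture_pdb(n_per_chain = 5)
  s <- read_pdb(f)
  ref <- render_namd_reference_pdb(s, fixed_idx = 1:4, pulled_idx = 5:10)
  expect_equal(sum(ref$atoms$beta == 1), 4L)
  expect_equal(sum(ref$atoms$occupancy == 1), 6L)
  expect_equal(sum(ref$atoms$beta == 0), 6L)
  out <- tempfile(fileext = ".pdb")
  write_pdb(ref, out)
  back <- read_pdb(out)
  expect_equal(back$atoms$beta, ref$atoms$beta)
  expect_equal(back$atoms$occupancy, ref$atoms$occupancy)
  expect_error(render_namd_reference_pdb(s, 1:5, 5:10), "overlap",
               class = "pullfan_input_error")
})

test_that("ndx files are 1-based, wrapped at 15 and round-trip", {
  txt <- render_ndx(list(pulled = 1:3))
  expect_match(txt, "[ pulled ]", fixed = TRUE)
  expect_match(txt, "1 2 3", fixed = TRUE)
  txt20 <- render_ndx(list(big = 1:20))
  body <- strsplit(txt20, "\n")[[1]]
  expect_equal(length(body), 3L)  # header + 15 + 5
  expect_equal(length(strsplit(body[2], " ")[[1]]), 15L)
  set.seed(303)
  for (i in 1:20) {
    groups <- list(fixed = sort(sample(1000, sample(1:40, 1))),
                   pulled = sort(sample(1000, sample(1:40, 1))))
    expect_identical(parse_ndx(render_ndx(groups)),
                     lapply(groups, as.integer))
  }
  expect_error(render_ndx(setNames(list(1:2, 3:4), c("a", "a"))),
               class = "pullfan_config_error")
})

test_that("scaffold builds one labelled subdirectory per direction", {
  f <- write_fixture_pdb()
  s <- read_pdb(f)
  dset <- generate_directions(principal_axis(s, "chain A", "chain B"))
  root <- tempfile("tree")
  plan <- pull_plan("namd", spring_k = 7, pull_velocity = 2e-5, timestep = 2,
                    n_steps = 100, n_replicas = 3, fixed = "chain A",
                    pulled = "chain B", output_root = root)
  tree <- scaffold(plan, dset, s)
  subs <- list.dirs(root, recursive = FALSE)
  expect_equal(length(subs), 9L)
  expect_setequal(basename(subs), dset$directions$label)
  expect_true(file.exists(file.path(root, "manifest.tsv")))
  one <- file.path(root, dset$directions$label[2])
  expect_true(file.exists(file.path(one, "ref.pdb")))
  expect_equal(sum(file.exists(file.path(one, sprintf("smd_r%d.conf", 1:3)))), 3L)
  # exactly one runnable script per subdirectory
  expect_equal(length(list.files(one, pattern = "\\.sh$")), 1L)
  run_sh <- readLines(file.path(one, "run.sh"))
  expect_equal(sum(grepl("^namd3", run_sh)), 3L)
  # per-replica seeds are distinct
  seeds <- vapply(1:3, function(r) {
    cfg <- readLines(file.path(one, sprintf("smd_r%d.conf", r)))
    as.integer(sub("seed\\s+", "", grep("^seed", cfg, value = TRUE)))
  }, integer(1))
  expect_equal(length(unique(seeds)), 3L)
})

test_that("scaffolding twice without overwrite refuses and leaves the tree intact", {
  f <- write_fixture_pdb()
  s <- read_pdb(f)
  dset <- generate_directions(principal_axis(s, "chain A", "chain B"),
                              thetas = c(0, 45), phis = c(0, 180))
  root <- tempfile("tree")
  plan <- pull_plan("gromacs", spring_k = 1000, pull_velocity = 0.01,
                    timestep = 2, n_steps = 100, fixed = "chain A",
                    pulled = "chain B", output_root = root)
  scaffold(plan, dset, s)
  before <- list.files(root, recursive = TRUE)
  expect_error(scaffold(plan, dset, s), "not empty", class = "pullfan_input_error")
  expect_identical(list.files(root, recursive = TRUE), before)
  expect_silent(scaffold(plan, dset, s, overwrite = TRUE))
})

test_that("directory count matches the direction set for arbitrary grids", {
  f <- write_fixture_pdb()
  s <- read_pdb(f)
  set.seed(404)
  for (i in 1:3) {
    thetas <- c(0, sort(runif(sample(1:3, 1), 20, 90)))
    phis <- sort(runif(sample(2:4, 1), 0, 300))
    dset <- generate_directions(principal_axis(s, "chain A", "chain B"), thetas, phis)
    root <- tempfile("tree")
    plan <- pull_plan("namd", spring_k = 1, pull_velocity = 1, timestep = 2,
                      n_steps = 10, fixed = "chain A", pulled = "chain B",
                      output_root = root)
    scaffold(plan, dset, s)
    expect_equal(length(list.dirs(root, recursive = FALSE)),
                 nrow(dset$directions))
  }
})

test_that("force unit conversions invert exactly", {
  x <- c(0.001, 1, 57.3, 1e4)
  expect_equal(pN_to_kcal_mol_A(kcal_mol_A_to_pN(x)), x, tolerance = 1e-12)
  expect_equal(pN_to_kJ_mol_nm(kJ_mol_nm_to_pN(x)), x, tolerance = 1e-12)
  expect_equal(kcal_mol_A_to_pN(10), 694.786)
  expect_equal(kJ_mol_nm_to_pN(100), 166.054)
})
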