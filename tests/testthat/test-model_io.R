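test_that("read_pdb transcribes ATOM records and agrees with an independent parser", {
  path <- system.file("extdata", "synthetic_crystal_site.pdb",
                      package = "mechprof")
  s <- read_pdb(path)
  expect_s3_class(s, "md_structure")
  expect_equal(nrow(s$atoms), 10L)
  expect_equal(s$atoms$name[3], "SD")
  expect_equal(s$atoms$element[3], "S")
  expect_equal(unname(unlist(s$atoms[3, c("x", "y", "z")])), c(0, 0, 0))
  expect_equal(s$atoms$resno[s$atoms$resname == "LGC"][1], 801L)

  # cross-check against bio3d's PDB parser
  ref <- bio3d::read.pdb(path)
  expect_equal(nrow(ref$atom), nrow(s$atoms))
  expect_equal(ref$atom$elety, s$atoms$name)
  expect_equal(cbind(ref$atom$x, ref$atom$y, ref$atom$z),
               unname(as.matrix(s$atoms[, c("x", "y", "z")])))
})

test_that("read_pdb parses a minimal hand-written record", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(unname(unlist(s$atoms[1, c("x", "y", "z")])), c(1, 2, 3))
})

test_that("malformed coordinate fields produce a parse error naming the line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1         abc   2.000   3.000  1.00  0.00           C"),
    f)
  expect_error(read_pdb(f), "line 2")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f2)
  expect_error(read_pdb(f2), "no ATOM/HETATM")
})

test_that("altLoc conformers resolve to highest occupancy with ties to first", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       4.000   0.000   0.000  0.50  0.00           C"),
    f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 2)  # higher occupancy wins
  expect_equal(s$atoms$x[s$atoms$name == "CB"], 3)  # tie -> first in file
})

test_that("multi-model files read as trajectories and warn as single structures", {
  sim <- generate_trajectory(trajectory_recipe(seed = 3, n_frames = 4))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sim$trajectory, f)
  expect_warning(s1 <- read_pdb(f), "MODEL")
  traj <- read_trajectory(f)
  expect_equal(n_frames(traj), 4L)
  expect_equal(nrow(traj$topology$atoms), 19L)
  expect_equal(traj$frames[[1]],
               unname(as.matrix(s1$atoms[, c("x", "y", "z")])))
})

test_that("PDB trajectory round trip preserves identities and printed precision", {
  sim <- generate_trajectory(trajectory_recipe(seed = 11, n_frames = 5))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sim$trajectory, f)
  back <- read_trajectory(f)
  a0 <- sim$trajectory$topology$atoms
  expect_equal(back$topology$atoms$name, a0$name)
  expect_equal(back$topology$atoms$resname, a0$resname)
  expect_equal(back$topology$atoms$resno, a0$resno)
  for (i in seq_len(5))
    expect_equal(back$frames[[i]], round(sim$trajectory$frames[[i]], 3))
})

test_that("XYZ trajectories read, round-trip to 3 decimals, and reject ragged frames", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "f1", "C 0 0 0", "N 1 0 0", "O 0 1 0", "H 0 0 1", "S 1 1 1",
               "5", "f2", "C 0 0 0.1", "N 1 0 0.1", "O 0 1 0.1", "H 0 0 1.1", "S 1 1 1.1",
               "5", "f3", "C 0 0 0.2", "N 1 0 0.2", "O 0 1 0.2", "H 0 0 1.2", "S 1 1 1.2"),
             f)
  traj <- read_trajectory(f)
  expect_equal(n_frames(traj), 3L)
  expect_equal(nrow(traj$topology$atoms), 5L)

  sim <- generate_trajectory(trajectory_recipe(seed = 5, n_frames = 50))
  f2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(sim$trajectory, f2)
  back <- read_trajectory(f2)
  expect_equal(n_frames(back), 50L)
  for (i in c(1, 25, 50))
    expect_equal(back$frames[[i]], round(sim$trajectory$frames[[i]], 3))

  f3 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "f1", "C 0 0 0", "N 1 0 0", "O 0 1 0", "H 0 0 1", "S 1 1 1",
               "4", "f2", "C 0 0 0", "N 1 0 0", "O 0 1 0", "H 0 0 1"), f3)
  expect_error(read_trajectory(f3), "frame 2")
})

test_that("energy records read from CSV with validation and mode flags", {
  tab <- read_energy_records(table3_path())
  expect_s3_class(tab, "energy_record_table")
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$E_LB[tab$model_id == "model1" & tab$state == "TS"], 15.0)
  expect_equal(attr(tab, "modes")[["E_solv_eps4"]], "absolute")
  expect_equal(attr(tab, "incomplete_profiles"), character(0))

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# modes: E_LB=relative E_solv_eps4=absolute ZPE=relative",
               "model_id,state,E_LB,E_solv_eps4,ZPE",
               "m,initial,0,-30,0",
               "m,TS,15,-27,0.2"), f)
  partial <- read_energy_records(f)
  expect_equal(attr(partial, "incomplete_profiles"), "m")
  expect_true("E_MB" %in% attr(partial, "missing_columns"))
})

test_that("energy-record validation rejects duplicates, bad cells and empty files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# modes: E_LB=relative E_solv_eps4=absolute ZPE=relative",
               "model_id,state,E_LB,E_solv_eps4,ZPE",
               "m,TS,15,-27,0.2",
               "m,TS,16,-26,0.3"), f)
  expect_error(read_energy_records(f), "duplicate")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# modes: E_LB=relative E_solv_eps4=absolute ZPE=relative",
               "model_id,state,E_LB,E_solv_eps4,ZPE",
               "m,TS,fifteen,-27,0.2"), f2)
  expect_error(read_energy_records(f2), "E_LB")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), f3)
  expect_error(read_energy_records(f3), "empty")
})

test_that("energy tables round-trip through CSV and the JSON mirror", {
  tab <- read_energy_records(table3_path())
  for (ext in c(".csv", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_energy_records(tab, f)
    back <- read_energy_records(f)
    expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
    expect_equal(attr(back, "modes"), attr(tab, "modes"))
  }
})

test_that("topology annotations validate serials and round-trip as JSON", {
  sim <- generate_trajectory(trajectory_recipe(seed = 2, n_frames = 2))
  topo <- sim$annotation
  f <- withr::local_tempfile(fileext = ".json")
  write_annotation(topo, f)
  back <- read_annotation(f, sim$trajectory$topology)
  expect_equal(back$donors, topo$donors)
  expect_equal(back$acceptors, topo$acceptors)
  expect_equal(back$reactive_pair$carbon, topo$reactive_pair$carbon)

  expect_error(
    topology_annotation(sim$trajectory$topology,
                        donors = data.frame(donor = 999L, hydrogen = 3L),
                        acceptors = 13L),
    "serial")
  expect_error(
    topology_annotation(sim$trajectory$topology,
                        donors = data.frame(donor = 2L, hydrogen = 2L),
                        acceptors = 13L),
    "hydrogen")
})

test_that("hartree conversion uses the pinned factor", {
  expect_equal(hartree_to_kcal(1), 627.509474)
  expect_equal(hartree_to_kcal(-0.5), -313.754737)
})
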