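test_that("kabsch_superpose recovers exact matches and rigid transforms", {
  set.seed(101)
  p <- matrix(stats::rnorm(18, sd = 3), ncol = 3)
  fit <- kabsch_superpose(p, p)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)

  fit_t <- kabsch_superpose(p, sweep(p, 2, c(-5, 0, 0)))
  expect_equal(fit_t$rmsd, 0, tolerance = 1e-10)

  R <- random_rotation()
  fit_r <- kabsch_superpose(p %*% R + matrix(rep(c(1, 2, 3), each = 6), ncol = 3), p)
  expect_equal(fit_r$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(fit_r$rotation), 1, tolerance = 1e-10)
})

test_that("kabsch rmsd matches the quaternion oracle on random perturbed pairs", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    p <- matrix(stats::rnorm(3 * n, sd = 4), ncol = 3)
    q <- (p + matrix(stats::rnorm(3 * n, sd = 0.4), ncol = 3)) %*%
      random_rotation()
    fit <- kabsch_superpose(p, q)
    expect_equal(fit$rmsd, quaternion_rmsd(p, q), tolerance = 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  }
})

test_that("kabsch_superpose rejects degenerate input", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 atoms")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("rmsd_series is zero at the reference and for duplicated frames", {
  sim <- generate_trajectory(trajectory_recipe(seed = 4, n_frames = 3))
  traj <- sim$trajectory
  traj$frames[[2]] <- traj$frames[[1]]
  ser <- rmsd_series(traj)
  expect_equal(ser$rmsd[1], 0)
  expect_equal(ser$rmsd[2], 0, tolerance = 1e-10)
  expect_true(all(ser$rmsd >= 0))
})

test_that("a balanced displacement of magnitude delta gives rmsd exactly delta", {
  # atoms on a planar cross; displacements +/- delta*e_z sum to zero
  # translation and zero torque, so the identity is the optimal fit
  delta <- 0.37
  p0 <- rbind(c(5, 0, 0), c(-5, 0, 0), c(0, 5, 0), c(0, -5, 0))
  disp <- rbind(c(0, 0, delta), c(0, 0, delta), c(0, 0, -delta), c(0, 0, -delta))
  set.seed(7)
  moved <- (p0 + disp) %*% random_rotation()
  expect_equal(kabsch_superpose(moved, p0)$rmsd, delta, tolerance = 1e-6)
})

test_that("rmsd_series output is invariant to a global rigid motion of all frames", {
  sim <- generate_trajectory(trajectory_recipe(seed = 8, n_frames = 10))
  ser <- rmsd_series(sim$trajectory)
  set.seed(9)
  R <- random_rotation()
  moved <- sim$trajectory
  moved$frames <- lapply(moved$frames, function(f)
    sweep(f %*% R, 2, c(3, -2, 7), "+"))
  ser2 <- rmsd_series(moved)
  expect_equal(ser2$rmsd, ser$rmsd, tolerance = 1e-8)
})

test_that("hydrogen-bond detection honors the distance and angle cutoffs", {
  x <- collinear_hbond_structure(2.9)
  obs <- detect_hbonds_frame(x$struct, x$topo)
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$d_DA, 2.9)
  expect_equal(obs$linearity_deviation, 0, tolerance = 1e-8)

  far <- collinear_hbond_structure(3.3)
  expect_equal(nrow(detect_hbonds_frame(far$struct, far$topo)), 0L)

  # boundary is inclusive
  edge <- collinear_hbond_structure(3.2)
  expect_equal(nrow(detect_hbonds_frame(edge$struct, edge$topo)), 1L)

  # bent geometry: acceptor perpendicular to the D-H axis fails the
  # 50-degree linearity-deviation cutoff
  bent <- collinear_hbond_structure(2.9)
  bent$struct$atoms[3, c("x", "y", "z")] <- c(1, 2.7, 0)
  expect_equal(nrow(detect_hbonds_frame(bent$struct, bent$topo)), 0L)
})

test_that("vectorized detection equals brute-force enumeration on random frames", {
  set.seed(303)
  crit <- hbond_criterion()
  for (i in 1:40) {
    x <- random_annotated_frame(n_donors = sample(2:4, 1),
                                n_acceptors = sample(2:5, 1))
    got <- detect_hbonds_frame(x$struct, x$topo, crit)
    want <- brute_force_hbonds(x$struct, x$topo, crit)
    ord <- function(d) d[order(d$donor, d$acceptor), , drop = FALSE]
    expect_equal(ord(got)[, c("donor", "acceptor")],
                 ord(want)[, c("donor", "acceptor")],
                 ignore_attr = TRUE)
    expect_equal(sort(got$d_DA), sort(want$d_DA), tolerance = 1e-10)
  }
})

test_that("occupancy equals the generator's planted ground truth exactly", {
  sim <- generate_trajectory(trajectory_recipe(seed = 42, n_frames = 100))
  occ <- hbond_occupancy(sim$trajectory, sim$annotation, threshold = 0)
  get <- function(d, a) occ$occupancy[occ$donor == d & occ$acceptor == a]
  expect_equal(get("HIS162:NE2", "LIG400:O2"),
               100 * length(sim$truth$contact_frames$H162) / 100)
  expect_equal(get("GLN38:NE2", "LIG400:O3"),
               100 * length(sim$truth$contact_frames$Q38) / 100)
  expect_equal(get("TRP163:NE1", "LIG400:O2"),
               100 * length(sim$truth$contact_frames$W163) / 100)
  # never-formed candidate pairs appear with occupancy 0 at threshold 0
  expect_true(any(occ$occupancy == 0))
  # at a reporting threshold they are absent, and a saturated bond is 100%
  occ5 <- hbond_occupancy(sim$trajectory, sim$annotation, threshold = 5)
  expect_false(any(occ5$occupancy == 0))
  sat <- generate_trajectory(trajectory_recipe(
    seed = 1, n_frames = 40,
    contacts = list(list(donor = "H162", occupancy = 1, noise_sd = 0))))
  osat <- hbond_occupancy(sat$trajectory, sat$annotation)
  expect_equal(osat$occupancy[osat$donor == "HIS162:NE2" &
                                osat$acceptor == "LIG400:O2"], 100)
})

test_that("occupancies are invariant to frame order and rigid motion", {
  sim <- generate_trajectory(trajectory_recipe(seed = 12, n_frames = 60))
  occ <- hbond_occupancy(sim$trajectory, sim$annotation, threshold = 0)
  perm <- sim$trajectory
  set.seed(13)
  perm$frames <- perm$frames[sample(60)]
  perm$times <- NULL
  occ_p <- hbond_occupancy(perm, sim$annotation, threshold = 0)
  expect_equal(occ_p, occ)
  R <- random_rotation()
  rigid <- sim$trajectory
  rigid$frames <- lapply(rigid$frames, function(f)
    sweep(f %*% R, 2, c(-4, 9, 2), "+"))
  occ_r <- hbond_occupancy(rigid, sim$annotation, threshold = 0)
  expect_equal(occ_r$occupancy, occ$occupancy, tolerance = 1e-10)
})

test_that("water bridges require both legs and match brute force plus ground truth", {
  # constructed: water midway between an indole-type N-H donor and a
  # carboxylate O, both legs within cutoffs
  atoms <- data.frame(
    serial = 1:6,
    name = c("NE1", "HE1", "O2", "OW", "HW1", "HW2"),
    element = c("N", "H", "O", "O", "H", "H"),
    resname = c("TRP", "TRP", "LIG", "HOH", "HOH", "HOH"),
    resno = c(163L, 163L, 400L, 500L, 500L, 500L), chain = "A",
    x = c(0, 0, 0, 0, 0, 0.9),
    y = c(0, 0, 0, 0, 0, 0.3),
    z = c(0, 1.01, 5.6, 2.8, 3.76, 2.5))
  struct <- md_structure(atoms)
  topo <- topology_annotation(struct,
                              donors = data.frame(donor = c(1L, 4L, 4L),
                                                  hydrogen = c(2L, 5L, 6L)),
                              acceptors = c(3L, 4L),
                              water_residue_names = "HOH")
  traj <- md_trajectory(struct, list(unname(as.matrix(atoms[, c("x", "y", "z")]))))
  br <- detect_water_bridges(traj, topo, endpoints_a = 1L, endpoints_b = 3L)
  expect_equal(nrow(br), 1L)
  expect_equal(br$water_resno, 500L)

  # one leg only: move the carboxylate out of reach of the water
  atoms2 <- atoms; atoms2$z[3] <- 9
  traj2 <- md_trajectory(md_structure(atoms2),
                         list(unname(as.matrix(atoms2[, c("x", "y", "z")]))))
  expect_equal(nrow(detect_water_bridges(traj2, topo,
                                         endpoints_a = 1L, endpoints_b = 3L)), 0L)
})

test_that("bridge detection matches brute force and planted occupancy on a trajectory", {
  sim <- generate_trajectory(trajectory_recipe(seed = 21, n_frames = 200))
  truth_frames <- sim$truth$bridge_frames
  br <- detect_water_bridges(sim$trajectory, sim$annotation,
                             endpoints_a = 8L, endpoints_b = 13L)
  expect_equal(sort(unique(br$frame)), sort(truth_frames))
  expect_equal(bridge_occupancy(sim$trajectory, sim$annotation,
                                endpoints_a = 8L, endpoints_b = 13L),
               100 * length(truth_frames) / 200)
  # per-frame agreement with brute-force triple enumeration
  crit <- hbond_criterion()
  for (i in sort(c(truth_frames[seq_len(min(5, length(truth_frames)))],
                   setdiff(1:200, truth_frames)[1:5]))) {
    fs <- frame_structure(sim$trajectory, i)
    wb <- brute_force_bridges(fs, sim$annotation, crit, 1L * 8L, 13L)
    expect_equal(i %in% br$frame, length(wb) > 0)
  }
})

test_that("random annotated frames with waters agree with the brute-force bridge oracle", {
  set.seed(404)
  crit <- hbond_criterion()
  for (i in 1:25) {
    x <- random_annotated_frame(n_donors = 2, n_acceptors = 3, n_waters = 2,
                                box = 6)
    a <- x$struct$atoms
    set_a <- a$serial[a$resname == "DON" & a$element == "N"]
    set_b <- a$serial[a$resname == "ACC"]
    traj <- md_trajectory(x$struct,
                          list(unname(as.matrix(a[, c("x", "y", "z")]))))
    got <- detect_water_bridges(traj, x$topo, crit, set_a, set_b)
    want <- brute_force_bridges(x$struct, x$topo, crit, set_a, set_b)
    expect_equal(sort(unique(got$water_resno)), sort(want))
  }
})

test_that("reactive distance takes the per-frame minimum over candidate oxygens", {
  atoms <- data.frame(
    serial = 1:3, name = c("CM", "O1", "O2"), element = c("C", "O", "O"),
    resname = c("SAM", "LIG", "LIG"), resno = c(1L, 2L, 2L), chain = "A",
    x = c(0, 3, 4), y = 0, z = 0)
  struct <- md_structure(atoms)
  topo <- topology_annotation(struct, donors = data.frame(donor = integer(),
                                                          hydrogen = integer()),
                              acceptors = integer(0),
                              reactive_pair = list(carbon = 1L, oxygens = c(2L, 3L)))
  traj <- md_trajectory(struct, list(unname(as.matrix(atoms[, c("x", "y", "z")]))))
  expect_equal(reactive_distance_series(traj, topo)$distance, 3.0)
  # tie: equidistant candidates give that distance
  tie <- traj; tie$frames[[1]][3, ] <- c(-3, 0, 0)
  expect_equal(reactive_distance_series(tie, topo)$distance, 3.0)
  # missing annotation errors
  topo2 <- topo; topo2$reactive_pair <- NULL
  expect_error(reactive_distance_series(traj, topo2), "reactive_pair")
})

test_that("planted reactive-distance statistics are recovered", {
  sim <- generate_trajectory(trajectory_recipe(seed = 31, n_frames = 400))
  ser <- reactive_distance_series(sim$trajectory, sim$annotation)
  expect_equal(ser$distance, sim$truth$reactive_distance, tolerance = 1e-10)
  expect_lt(abs(mean(ser$distance) - 3.1), 3 * 0.15 / sqrt(400))
  expect_lt(mean(ser$distance > 3.4), 0.05)   # rarely exceeds 3.4 A
})

test_that("measure_distance resolves unique selectors and reports ambiguity", {
  s <- read_pdb(system.file("extdata", "synthetic_crystal_site.pdb",
                            package = "mechprof"))
  expect_equal(measure_distance(s, "resname=SAH,name=SD", "resname=LGC,name=O1"),
               3.3)
  expect_equal(measure_distance(s, "name=SD", "name=SD"), 0)
  expect_error(measure_distance(s, "resname=LGC,element=O", "name=SD"),
               "exactly one")
  r <- measure_min_distance(s, "resname=SAH,element=S", "resname=LGC,element=O")
  expect_equal(r$distance, 3.3)
  expect_equal(r$serial2, 6L)
})

test_that("simple two-point geometry checks", {
  atoms <- data.frame(serial = 1:2, name = c("A1", "A2"), element = "C",
                      resname = "XXX", resno = 1:2, chain = "A",
                      x = c(0, 0), y = c(0, 3), z = c(0, 4))
  s <- md_structure(atoms)
  expect_equal(measure_distance(s, list(name = "A1"), list(name = "A2")), 5)
})

test_that("tightening either cutoff never increases any occupancy", {
  sim <- generate_trajectory(trajectory_recipe(seed = 17, n_frames = 80))
  set.seed(505)
  for (i in 1:60) {
    d1 <- stats::runif(1, 2.4, 4.5); a1 <- stats::runif(1, 15, 85)
    d2 <- stats::runif(1, 1.5, d1); a2 <- stats::runif(1, 10, a1)
    o1 <- hbond_occupancy(sim$trajectory, sim$annotation,
                          hbond_criterion(min(d1, 5), min(a1, 90)), threshold = 0)
    o2 <- hbond_occupancy(sim$trajectory, sim$annotation,
                          hbond_criterion(min(d2, 5), min(a2, 90)), threshold = 0)
    key <- function(o) paste(o$donor, o$acceptor)
    m <- match(key(o2), key(o1))
    expect_true(all(o2$occupancy <= o1$occupancy[m] + 1e-12))
  }
})
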