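# Seeded synthetic active-site trajectories and energy-record tables
# with exact ground truth.  The mock site is a minimal caricature
# (three donor residues, a substrate with acceptor oxygens, a methyl
# probe and one water), built to test the geometry code, not the
# chemistry: contacts are planted with a safety margin around the
# 3.2 Angstrom / 50 degree criterion so the ground-truth ledger and
# the detectors can never disagree by rounding.

#' Recipe for a synthetic active-site trajectory
#'
#' The generated site contains donors `H162`, `Q38` (contact planted
#' by placing the acceptor on the donor-hydrogen axis) and `W163`
#' (per-frame trichotomy: direct bond, water-mediated bridge to the
#' substrate carboxylate, or neither), a substrate (`LIG`) with
#' acceptor oxygens `O2`, `O3`, `O9`, a methyl-carbon probe (`SAM`)
#' whose minimum distance to the carboxylate oxygens follows a
#' Gaussian process, and one water (`HOH`).  Bonded frames draw the
#' donor-acceptor distance uniformly from 2.6-3.1 Angstrom, unbonded
#' frames from 3.6-4.5, keeping a margin from the 3.2 cutoff.
#'
#' @param seed integer RNG seed.
#' @param n_frames number of frames (>= 1).
#' @param contacts list of `list(donor, occupancy, noise_sd)` for
#'   donors `"H162"`, `"Q38"`, `"W163"`; occupancy in `[0,1]`,
#'   `noise_sd` the off-axis geometry jitter (Angstrom, truncated at
#'   0.3 to preserve the ledger guarantee).
#' @param bridge_occupancy fraction of frames with the water bridge
#'   (W163 to carboxylate via the water); together with the `W163`
#'   direct occupancy it must not exceed 1.
#' @param reactive_mean,reactive_sd mean and s.d. (Angstrom) of the
#'   methyl-carbon to carboxylate-oxygen distance process.
#' @param scaffold_noise_sd isotropic positional noise applied to the
#'   scaffold (C-alpha) atoms only (Angstrom).
#' @param dt_ps frame spacing in ps.
#' @return object of class `trajectory_recipe`.
#' @export
trajectory_recipe <- function(seed = 1L, n_frames = 2000L,
                              contacts = list(
                                list(donor = "H162", occupancy = 0.95, noise_sd = 0.05),
                                list(donor = "Q38",  occupancy = 0.75, noise_sd = 0.05),
                                list(donor = "W163", occupancy = 0.20, noise_sd = 0.05)),
                              bridge_occupancy = 0.20,
                              reactive_mean = 3.1, reactive_sd = 0.15,
                              scaffold_noise_sd = 0.5, dt_ps = 10) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  occ <- stats::setNames(rep(0, 3), c("H162", "Q38", "W163"))
  nsd <- stats::setNames(rep(0.05, 3), c("H162", "Q38", "W163"))
  for (ct in contacts) {
    if (!ct$donor %in% names(occ))
      stop("unknown contact donor: ", ct$donor)
    if (ct$occupancy < 0 || ct$occupancy > 1)
      stop("occupancy must lie in [0, 1]")
    if (ct$noise_sd < 0) stop("noise_sd must be >= 0")
    occ[ct$donor] <- ct$occupancy
    nsd[ct$donor] <- ct$noise_sd
  }
  if (bridge_occupancy < 0 || bridge_occupancy > 1)
    stop("bridge_occupancy must lie in [0, 1]")
  if (occ[["W163"]] + bridge_occupancy > 1)
    stop("W163 direct occupancy plus bridge_occupancy exceeds 1")
  if (reactive_sd < 0 || scaffold_noise_sd < 0)
    stop("standard deviations must be >= 0")
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 occupancy = occ, noise_sd = nsd,
                 bridge_occupancy = bridge_occupancy,
                 reactive_mean = reactive_mean, reactive_sd = reactive_sd,
                 scaffold_noise_sd = scaffold_noise_sd, dt_ps = dt_ps),
            class = "trajectory_recipe")
}

# atom table of the mock site; serials are stable handles used below
synthetic_site_atoms <- function() {
  data.frame(
    serial  = 1:19,
    name    = c("CA", "NE2", "HE2",          # HIS 162
                "CA", "NE2", "HE21",         # GLN 38
                "CA", "NE1", "HE1",          # TRP 163
                "CA",                        # GLY 240
                "CA",                        # GLY 37
                "O1", "O2", "O3", "O9",      # LIG 400
                "CM",                        # SAM 401
                "OW", "HW1", "HW2"),         # HOH 500
    element = c("C", "N", "H", "C", "N", "H", "C", "N", "H", "C", "C",
                "O", "O", "O", "O", "C", "O", "H", "H"),
    resname = c(rep("HIS", 3), rep("GLN", 3), rep("TRP", 3), "GLY", "GLY",
                rep("LIG", 4), "SAM", rep("HOH", 3)),
    resno   = c(rep(162L, 3), rep(38L, 3), rep(163L, 3), 240L, 37L,
                rep(400L, 4), 401L, rep(500L, 3)),
    chain   = "A",
    x = 0, y = 0, z = 0,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic trajectory with exact ground truth
#'
#' Deterministic for a fixed seed (Mersenne-Twister with inversion
#' normals).  The returned `truth` ledger records, exactly, the frame
#' sets in which each contact was planted, the per-frame W163
#' category (`direct` / `bridge` / `neither`) and the planted
#' reactive-distance series, and is the oracle against which the
#' detectors are tested.
#'
#' @param recipe [trajectory_recipe()].
#' @return list with `trajectory` ([md_trajectory]), `annotation`
#'   ([topology_annotation()]) and `truth` (ledger list).
#' @export
generate_trajectory <- function(recipe = trajectory_recipe()) {
  if (!inherits(recipe, "trajectory_recipe"))
    stop("recipe must be a trajectory_recipe")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(recipe$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  nf <- recipe$n_frames
  atoms <- synthetic_site_atoms()
  base <- matrix(0, nrow(atoms), 3)
  base[1, ]  <- c(-2, 6, 0)    # HIS CA
  base[2, ]  <- c(0, 6, 0)     # HIS NE2 (donor)
  base[3, ]  <- c(1.01, 6, 0)  # HIS HE2
  base[4, ]  <- c(-2, -6, 0)   # GLN CA
  base[5, ]  <- c(0, -6, 0)    # GLN NE2
  base[6, ]  <- c(1.01, -6, 0) # GLN HE21
  base[7, ]  <- c(-3, 6, 6)    # TRP CA
  base[10, ] <- c(0, 0, -8)    # GLY 240 CA
  base[11, ] <- c(6, 0, -8)    # GLY 37 CA
  base[15, ] <- c(-5, 0, -6)   # LIG O9 (static spectator acceptor)
  parked_water <- c(8, -8, 6)

  jitter2 <- function(sd) pmin(0.3, pmax(-0.3, stats::rnorm(2, 0, sd)))
  draw_d <- function(bonded) if (bonded) stats::runif(1, 2.6, 3.1) else stats::runif(1, 3.6, 4.5)

  occ <- recipe$occupancy; nsd <- recipe$noise_sd
  bonded_h162 <- stats::runif(nf) < occ[["H162"]]
  bonded_q38  <- stats::runif(nf) < occ[["Q38"]]
  u <- stats::runif(nf)
  category <- ifelse(u < recipe$bridge_occupancy, "bridge",
                     ifelse(u < recipe$bridge_occupancy + occ[["W163"]],
                            "direct", "neither"))
  d_react <- stats::rnorm(nf, recipe$reactive_mean, recipe$reactive_sd)
  d_react <- pmax(d_react, 0.5)

  frames <- vector("list", nf)
  for (t in seq_len(nf)) {
    f <- base
    # H162 NE2-HE2 ... LIG O2, acceptor on the donor-hydrogen (+x) axis
    j <- jitter2(nsd[["H162"]])
    f[13, ] <- f[2, ] + c(draw_d(bonded_h162[t]), j[1], j[2])
    # Q38 NE2-HE21 ... LIG O3
    j <- jitter2(nsd[["Q38"]])
    f[14, ] <- f[5, ] + c(draw_d(bonded_q38[t]), j[1], j[2])
    # LIG O1 rides above O2; reactive-pair decoy, not an acceptor
    f[12, ] <- f[13, ] + c(0, 2.2, 0)
    # SAM methyl carbon at the planted reactive distance from O2
    f[16, ] <- f[13, ] + c(0, -d_react[t], 0)
    # W163 and the water
    o2 <- f[13, ]
    if (category[t] == "bridge") {
      dw2 <- stats::runif(1, 2.6, 3.1)   # water ... O2 leg
      dw1 <- stats::runif(1, 2.6, 3.1)   # W163 ... water leg
      ow <- o2 + c(0, 0, dw2)
      f[17, ] <- ow
      f[18, ] <- ow + 0.96 * (o2 - ow) / sqrt(sum((o2 - ow)^2))
      f[19, ] <- ow + c(0, 0.96, 0)
      f[8, ] <- ow + c(0, 0, dw1)
      f[9, ] <- f[8, ] + 1.01 * (ow - f[8, ]) / sqrt(sum((ow - f[8, ])^2))
    } else {
      j <- jitter2(nsd[["W163"]])
      ne1 <- o2 + c(j[1], j[2], draw_d(category[t] == "direct"))
      f[8, ] <- ne1
      f[9, ] <- ne1 + 1.01 * (o2 - ne1) / sqrt(sum((o2 - ne1)^2))
      f[17, ] <- parked_water
      f[18, ] <- parked_water + c(0.96, 0, 0)
      f[19, ] <- parked_water + c(0, 0.96, 0)
    }
    # scaffold noise on the C-alpha trace only
    ca <- c(1, 4, 7, 10, 11)
    f[ca, ] <- f[ca, ] + matrix(stats::rnorm(length(ca) * 3, 0,
                                             recipe$scaffold_noise_sd),
                                ncol = 3)
    frames[[t]] <- f
  }
  atoms$x <- frames[[1]][, 1]; atoms$y <- frames[[1]][, 2]
  atoms$z <- frames[[1]][, 3]
  topo <- md_structure(atoms, title = "synthetic active site")
  traj <- md_trajectory(topo, frames, times = recipe$dt_ps * seq_len(nf))
  annotation <- topology_annotation(
    topo,
    donors = data.frame(donor = c(2L, 5L, 8L, 17L, 17L),
                        hydrogen = c(3L, 6L, 9L, 18L, 19L)),
    acceptors = c(13L, 14L, 15L, 17L),
    water_residue_names = "HOH",
    reactive_pair = list(carbon = 16L, oxygens = c(13L, 12L)))
  truth <- list(
    seed = recipe$seed, n_frames = nf,
    contact_frames = list(H162 = which(bonded_h162),
                          Q38 = which(bonded_q38),
                          W163 = which(category == "direct")),
    bridge_frames = which(category == "bridge"),
    category = category,
    reactive_distance = d_react,
    endpoints = list(w163 = 8L, carboxylate = 13L))
  list(trajectory = traj, annotation = annotation, truth = truth)
}

## ---- energy tables ------------------------------------------------------

#' Recipe for a synthetic energy-record table
#'
#' Per-model true components: relative electronic energies (`E_MB`,
#' `E_LB`) and `ZPE` (0 for the initial state by definition) and
#' absolute solvation energies at dielectric 4 and 80.  The implied
#' barrier at dielectric eps is
#' `E_LB(TS) + [E_solv(eps,TS) - E_solv(eps,initial)] + ZPE(TS)`.
#'
#' @param seed integer seed (used only when `perturb_sd > 0`).
#' @param models named list: model id to
#'   `list(initial = c(E_MB=, E_LB=, E_solv_eps4=, E_solv_eps80=, ZPE=), TS = ..., final = ...)`.
#' @param perturb_sd Gaussian noise (kcal/mol) added to the TS/final
#'   components when positive; 0 (default) keeps the table exactly at
#'   the recipe's values.
#' @return object of class `profile_recipe`.
#' @export
profile_recipe <- function(seed = 1L, models = NULL, perturb_sd = 0) {
  if (is.null(models)) {
    models <- list(mock = list(
      initial = c(E_MB = 0, E_LB = 0, E_solv_eps4 = -33, E_solv_eps80 = -45, ZPE = 0),
      TS      = c(E_MB = 13, E_LB = 15, E_solv_eps4 = -30, E_solv_eps80 = -40, ZPE = 0.2),
      final   = c(E_MB = -18, E_LB = -14, E_solv_eps4 = -28, E_solv_eps80 = -38, ZPE = 1.5)))
  }
  for (m in names(models)) {
    st <- models[[m]]
    if (!all(STATE_LABELS %in% names(st)))
      stop("model '", m, "' needs initial, TS and final components")
    rel0 <- st$initial[c("E_MB", "E_LB", "ZPE")]
    if (any(rel0 != 0))
      stop("initial-state relative components must be 0 (model '", m, "')")
  }
  if (perturb_sd < 0) stop("perturb_sd must be >= 0")
  structure(list(seed = as.integer(seed), models = models,
                 perturb_sd = perturb_sd), class = "profile_recipe")
}

#' Implied composite barrier of a profile recipe
#' @param recipe [profile_recipe()].
#' @param model_id model name in the recipe.
#' @param epsilon dielectric constant, 4 or 80.
#' @return kcal/mol.
#' @export
implied_barrier <- function(recipe, model_id, epsilon = 4) {
  st <- recipe$models[[model_id]]
  if (is.null(st)) stop("no model '", model_id, "' in recipe")
  cn <- solv_column(epsilon)
  unname(st$TS[["E_LB"]] + (st$TS[[cn]] - st$initial[[cn]]) + st$TS[["ZPE"]])
}

#' Generate an energy-record table from a recipe
#'
#' With `perturb_sd = 0` the assembled barrier of every model equals
#' the recipe's implied barrier exactly.
#'
#' @param recipe [profile_recipe()].
#' @return [energy_record_table()] (E_MB/E_LB/ZPE relative, solvation
#'   absolute).
#' @export
generate_energy_table <- function(recipe = profile_recipe()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(recipe$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  rows <- list()
  for (m in names(recipe$models)) {
    for (s in STATE_LABELS) {
      v <- recipe$models[[m]][[s]]
      if (recipe$perturb_sd > 0 && s != "initial")
        v <- v + stats::rnorm(length(v), 0, recipe$perturb_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        model_id = m, state = s, E_MB = v[["E_MB"]], E_LB = v[["E_LB"]],
        E_solv_eps4 = v[["E_solv_eps4"]], E_solv_eps80 = v[["E_solv_eps80"]],
        ZPE = v[["ZPE"]])
    }
  }
  energy_record_table(do.call(rbind, rows),
                      modes = c(E_MB = "relative", E_LB = "relative",
                                E_solv_eps4 = "absolute",
                                E_solv_eps80 = "absolute", ZPE = "relative"))
}

#' Random profile recipe (for property testing)
#'
#' Draws plausible component magnitudes: TS electronic energies in
#' 5-25 kcal/mol, exo- or endo-energetic final states, solvation
#' magnitudes decreasing along the reaction as charge is quenched.
#'
#' @param seed integer seed.
#' @param n_models number of models in the recipe.
#' @return [profile_recipe()] with `perturb_sd = 0`.
#' @export
random_profile_recipe <- function(seed = 1L, n_models = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  models <- list()
  for (k in seq_len(n_models)) {
    s0 <- -stats::runif(1, 25, 50)
    models[[paste0("m", k)]] <- list(
      initial = c(E_MB = 0, E_LB = 0, E_solv_eps4 = s0,
                  E_solv_eps80 = s0 * stats::runif(1, 1.2, 1.5), ZPE = 0),
      TS = c(E_MB = stats::runif(1, 4, 22), E_LB = stats::runif(1, 5, 25),
             E_solv_eps4 = s0 + stats::runif(1, 1, 6),
             E_solv_eps80 = s0 * 1.35 + stats::runif(1, 1, 8),
             ZPE = stats::rnorm(1, 0, 1)),
      final = c(E_MB = stats::rnorm(1, -15, 8), E_LB = stats::rnorm(1, -12, 8),
                E_solv_eps4 = s0 + stats::runif(1, 3, 9),
                E_solv_eps80 = s0 * 1.35 + stats::runif(1, 4, 11),
                ZPE = stats::rnorm(1, 1, 0.8)))
  }
  profile_recipe(seed = seed, models = models, perturb_sd = 0)
}
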