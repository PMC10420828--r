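# Geometric trajectory analyses: Kabsch superposition RMSD,
# hydrogen-bond and water-bridge detection, occupancy statistics,
# reactive-distance series.

#' Hydrogen-bond criterion
#'
#' The default geometric criterion counts a donor(D)-hydrogen(H)...
#' acceptor(A) triple as bonded when the D-A distance is at most 3.2
#' Angstrom and the D-H-A angle deviates from linearity (180 degrees)
#' by at most 50 degrees, i.e. the D-H-A angle is at least 130
#' degrees.  Both comparisons are inclusive.
#'
#' @param distance_cutoff donor-acceptor distance cutoff in Angstrom.
#' @param angle_cutoff maximum deviation of the D-H-A angle from
#'   linearity, in degrees.
#' @return object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(distance_cutoff = 3.2, angle_cutoff = 50) {
  if (distance_cutoff <= 0 || distance_cutoff > 5)
    stop("distance_cutoff must be in (0, 5] Angstrom")
  if (angle_cutoff <= 0 || angle_cutoff > 90)
    stop("angle_cutoff must be in (0, 90] degrees")
  structure(list(distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff), class = "hbond_criterion")
}

#' Kabsch superposition
#'
#' Least-squares rigid-body superposition of `mobile` onto
#' `reference` via singular value decomposition of the covariance
#' matrix, constrained to a proper rotation (determinant +1).
#'
#' @param mobile,reference numeric `n x 3` matrices, `n >= 3`,
#'   matching rows.
#' @return list with `rotation` (3x3, applied as `x %*% rotation`),
#'   `translation` (length-3), and `rmsd` (Angstrom) after optimal
#'   superposition.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be matching n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  pm <- sweep(mobile, 2, cm); pr <- sweep(reference, 2, cr)
  for (p in list(pm, pr)) {
    s <- svd(p, nu = 0, nv = 0)$d
    if (s[2] < 1e-8 * max(s[1], 1e-12))
      stop("degenerate (collinear) point set: superposition is ill-defined")
  }
  C <- crossprod(pm, pr)                     # 3x3 covariance
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- pm %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - pr)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% rot), rmsd = rmsd)
}

#' RMSD time series
#'
#' Per-frame RMSD after Kabsch superposition onto a reference frame.
#' The default selection is the C-alpha trace (atoms named `CA`),
#' unweighted, with the first frame as reference, so the series starts
#' at 0.
#'
#' @param traj [md_trajectory].
#' @param selection integer vector of atom serials; default all atoms
#'   named `"CA"`.
#' @param reference_frame frame index of the reference (default 1).
#' @return data.frame of class `rmsd_series` with columns `frame`,
#'   `rmsd` (Angstrom); the selection descriptor is kept in the
#'   `selection` attribute.
#' @export
rmsd_series <- function(traj, selection = NULL, reference_frame = 1L) {
  topo <- traj$topology
  if (is.null(selection)) selection <- select_atoms(topo, name = "CA")
  if (length(selection) < 3L)
    stop("selection must resolve to at least 3 atoms")
  rows <- serial_to_row(topo, selection)
  if (reference_frame < 1L || reference_frame > n_frames(traj))
    stop("reference_frame out of range")
  ref <- traj$frames[[reference_frame]][rows, , drop = FALSE]
  rmsd <- vapply(traj$frames, function(f)
    kabsch_superpose(f[rows, , drop = FALSE], ref)$rmsd, numeric(1))
  rmsd[reference_frame] <- 0   # exact by definition
  structure(data.frame(frame = seq_along(rmsd), rmsd = rmsd),
            class = c("rmsd_series", "data.frame"), selection = selection,
            reference_frame = reference_frame)
}

# internal: observations for one coordinate matrix.
# topo_idx holds row indices (not serials) precomputed by hbond_index().
hbonds_in_coords <- function(xyz, topo_idx, crit) {
  di <- topo_idx$donor_row; hi <- topo_idx$hydrogen_row
  ai <- topo_idx$acceptor_row
  nd <- length(di); na <- length(ai)
  if (nd == 0L || na == 0L)
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), d_DA = numeric(),
                      linearity_deviation = numeric()))
  dd <- rep(seq_len(nd), times = na)
  aa <- rep(seq_len(na), each = nd)
  # exclude self pairs and same-residue pairs
  keep <- topo_idx$donor_res[dd] != topo_idx$acceptor_res[aa] &
    di[dd] != ai[aa]
  dd <- dd[keep]; aa <- aa[keep]
  D <- xyz[di[dd], , drop = FALSE]
  H <- xyz[hi[dd], , drop = FALSE]
  A <- xyz[ai[aa], , drop = FALSE]
  d_da <- sqrt(rowSums((D - A)^2))
  ok <- d_da <= crit$distance_cutoff
  dd <- dd[ok]; aa <- aa[ok]
  D <- D[ok, , drop = FALSE]; H <- H[ok, , drop = FALSE]
  A <- A[ok, , drop = FALSE]; d_da <- d_da[ok]
  hd <- D - H; ha <- A - H
  cosang <- rowSums(hd * ha) /
    (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
  cosang <- pmin(1, pmax(-1, cosang))
  dev <- 180 - acos(cosang) * 180 / pi
  ok <- dev <= crit$angle_cutoff
  data.frame(donor = topo_idx$donor_serial[dd[ok]],
             hydrogen = topo_idx$hydrogen_serial[dd[ok]],
             acceptor = topo_idx$acceptor_serial[aa[ok]],
             d_DA = d_da[ok], linearity_deviation = dev[ok])
}

hbond_index <- function(struct, topo) {
  drow <- serial_to_row(struct, topo$donors$donor)
  hrow <- serial_to_row(struct, topo$donors$hydrogen)
  arow <- serial_to_row(struct, topo$acceptors)
  a <- struct$atoms
  reskey <- paste(a$chain, a$resno, a$insert, sep = "\r")
  list(donor_row = drow, hydrogen_row = hrow, acceptor_row = arow,
       donor_serial = topo$donors$donor, hydrogen_serial = topo$donors$hydrogen,
       acceptor_serial = topo$acceptors,
       donor_res = reskey[drow], acceptor_res = reskey[arow])
}

#' Detect hydrogen bonds
#'
#' Returns every annotated donor-hydrogen/acceptor triple satisfying
#' the geometric criterion.  Donor and acceptor in the same residue
#' are excluded.  `detect_hbonds_frame()` analyzes one structure (or
#' one coordinate matrix against a topology); `detect_hbonds()` runs
#' over all frames of a trajectory.
#'
#' @param traj [md_trajectory].
#' @param topo [topology_annotation()].
#' @param crit [hbond_criterion()].
#' @param frames optional integer vector of frame indices (default all).
#' @return data.frame with columns `frame`, `donor`, `hydrogen`,
#'   `acceptor`, `d_DA`, `linearity_deviation`.
#' @export
detect_hbonds <- function(traj, topo, crit = hbond_criterion(), frames = NULL) {
  idx <- hbond_index(traj$topology, topo)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  out <- lapply(frames, function(i) {
    obs <- hbonds_in_coords(traj$frames[[i]], idx, crit)
    if (nrow(obs)) cbind(frame = i, obs) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(), donor = integer(),
                      hydrogen = integer(), acceptor = integer(),
                      d_DA = numeric(), linearity_deviation = numeric())
  out
}

#' @rdname detect_hbonds
#' @param struct [md_structure] holding the frame's coordinates.
#' @export
detect_hbonds_frame <- function(struct, topo, crit = hbond_criterion()) {
  idx <- hbond_index(struct, topo)
  xyz <- unname(as.matrix(struct$atoms[, c("x", "y", "z")]))
  hbonds_in_coords(xyz, idx, crit)
}

#' Hydrogen-bond occupancy table
#'
#' Occupancy of a donor/acceptor pair is the percentage of analyzed
#' frames in which at least one qualifying observation for that pair
#' exists.  Pair identity is the (residue, atom-name) descriptor of
#' both ends, so several simultaneous geometries in one frame count
#' once.  The denominator is always the total number of frames (no
#' frame skipping).  Pairs are reported when occupancy exceeds
#' `threshold` percent (strictly); with `threshold <= 0` every
#' candidate donor/acceptor pair is reported, including those never
#' observed (occupancy 0).
#'
#' @inheritParams detect_hbonds
#' @param threshold reporting threshold in percent (default 5).
#' @return data.frame of class `occupancy_table` with columns `donor`,
#'   `acceptor` (descriptors) and `occupancy` (percent), sorted by
#'   decreasing occupancy; `n_frames` kept as an attribute.
#' @export
hbond_occupancy <- function(traj, topo, crit = hbond_criterion(),
                            threshold = 5) {
  nf <- n_frames(traj)
  obs <- detect_hbonds(traj, topo, crit)
  ddesc <- atom_descriptor(traj$topology, obs$donor)
  adesc <- atom_descriptor(traj$topology, obs$acceptor)
  key <- paste(ddesc, adesc, sep = "\t")
  counts <- if (nrow(obs)) {
    tapply(obs$frame, key, function(f) length(unique(f)))
  } else integer()
  if (threshold <= 0) {
    # enumerate all candidate pairs so never-formed contacts appear
    idx <- hbond_index(traj$topology, topo)
    dd <- rep(seq_along(idx$donor_row), times = length(idx$acceptor_row))
    aa <- rep(seq_along(idx$acceptor_row), each = length(idx$donor_row))
    ok <- idx$donor_res[dd] != idx$acceptor_res[aa] &
      idx$donor_row[dd] != idx$acceptor_row[aa]
    allkey <- unique(paste(
      atom_descriptor(traj$topology, idx$donor_serial[dd[ok]]),
      atom_descriptor(traj$topology, idx$acceptor_serial[aa[ok]]),
      sep = "\t"))
    zero <- setdiff(allkey, names(counts))
    counts <- c(counts, stats::setNames(rep(0L, length(zero)), zero))
  }
  occ <- 100 * as.numeric(counts) / nf
  parts <- strsplit(names(counts), "\t", fixed = TRUE)
  out <- data.frame(donor = vapply(parts, `[`, "", 1L),
                    acceptor = vapply(parts, `[`, "", 2L),
                    occupancy = occ)
  out <- out[if (threshold <= 0) rep(TRUE, nrow(out)) else out$occupancy > threshold, ,
             drop = FALSE]
  out <- out[order(-out$occupancy, out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("occupancy_table", "data.frame"), n_frames = nf)
}

#' Detect water bridges
#'
#' A water bridge is reported in a frame when a single water molecule
#' simultaneously forms qualifying hydrogen bonds (in either polarity)
#' to an atom of endpoint set A and an atom of endpoint set B.
#' Endpoint atoms must belong to non-water residues.
#'
#' @inheritParams detect_hbonds
#' @param endpoints_a,endpoints_b integer vectors of atom serials.
#' @return data.frame with columns `frame`, `water_resno`,
#'   `endpoint_a`, `endpoint_b` plus the two legs' donor/acceptor
#'   serials (`leg_a_donor`, `leg_a_acceptor`, `leg_b_donor`,
#'   `leg_b_acceptor`).
#' @export
detect_water_bridges <- function(traj, topo, crit = hbond_criterion(),
                                 endpoints_a, endpoints_b, frames = NULL) {
  stopifnot(length(endpoints_a) >= 1L, length(endpoints_b) >= 1L)
  a <- traj$topology$atoms
  is_water <- a$resname %in% topo$water_residue_names
  if (any(is_water[serial_to_row(traj$topology, c(endpoints_a, endpoints_b))]))
    stop("bridge endpoints must belong to non-water residues")
  water_of <- function(serials) {
    i <- serial_to_row(traj$topology, serials)
    ifelse(is_water[i], a$resno[i], NA_integer_)
  }
  obs <- detect_hbonds(traj, topo, crit, frames = frames)
  if (!nrow(obs))
    return(data.frame(frame = integer(), water_resno = integer(),
                      endpoint_a = integer(), endpoint_b = integer(),
                      leg_a_donor = integer(), leg_a_acceptor = integer(),
                      leg_b_donor = integer(), leg_b_acceptor = integer()))
  obs$dw <- water_of(obs$donor)          # water residue if donor is water
  obs$aw <- water_of(obs$acceptor)
  out <- list()
  # a "leg" to an endpoint set: water donates to an endpoint acceptor,
  # or an endpoint donor donates to a water acceptor atom
  legs_to <- function(o, set) {
    rbind(
      data.frame(water = o$dw[!is.na(o$dw) & o$acceptor %in% set],
                 endpoint = o$acceptor[!is.na(o$dw) & o$acceptor %in% set],
                 donor = o$donor[!is.na(o$dw) & o$acceptor %in% set],
                 acceptor = o$acceptor[!is.na(o$dw) & o$acceptor %in% set]),
      data.frame(water = o$aw[!is.na(o$aw) & o$donor %in% set],
                 endpoint = o$donor[!is.na(o$aw) & o$donor %in% set],
                 donor = o$donor[!is.na(o$aw) & o$donor %in% set],
                 acceptor = o$acceptor[!is.na(o$aw) & o$donor %in% set]))
  }
  for (fr in unique(obs$frame)) {
    o <- obs[obs$frame == fr, , drop = FALSE]
    la <- legs_to(o, endpoints_a)
    lb <- legs_to(o, endpoints_b)
    shared <- intersect(la$water, lb$water)
    for (w in shared) {
      ia <- which(la$water == w)[1]
      ib <- which(lb$water == w)[1]
      out[[length(out) + 1L]] <- data.frame(
        frame = fr, water_resno = w,
        endpoint_a = la$endpoint[ia], endpoint_b = lb$endpoint[ib],
        leg_a_donor = la$donor[ia], leg_a_acceptor = la$acceptor[ia],
        leg_b_donor = lb$donor[ib], leg_b_acceptor = lb$acceptor[ib])
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), water_resno = integer(),
                      endpoint_a = integer(), endpoint_b = integer(),
                      leg_a_donor = integer(), leg_a_acceptor = integer(),
                      leg_b_donor = integer(), leg_b_acceptor = integer()))
  do.call(rbind, out)
}

#' Water-bridge occupancy
#'
#' Percentage of frames containing at least one qualifying bridge.
#' @inheritParams detect_water_bridges
#' @return numeric scalar (percent).
#' @export
bridge_occupancy <- function(traj, topo, crit = hbond_criterion(),
                             endpoints_a, endpoints_b) {
  br <- detect_water_bridges(traj, topo, crit, endpoints_a, endpoints_b)
  100 * length(unique(br$frame)) / n_frames(traj)
}

#' Reactive-distance time series
#'
#' Per frame, the minimum over the annotated candidate acceptor
#' oxygens of the methyl-carbon to oxygen distance.
#'
#' @param traj [md_trajectory].
#' @param topo [topology_annotation()] with a `reactive_pair`.
#' @return data.frame of class `distance_series` with columns `frame`,
#'   `distance` (Angstrom).
#' @export
reactive_distance_series <- function(traj, topo) {
  rp <- topo$reactive_pair
  if (is.null(rp)) stop("topology annotation has no reactive_pair")
  ci <- serial_to_row(traj$topology, rp$carbon)
  oi <- serial_to_row(traj$topology, rp$oxygens)
  d <- vapply(traj$frames, function(f) {
    diff2 <- sweep(f[oi, , drop = FALSE], 2, f[ci, ])
    sqrt(min(rowSums(diff2^2)))
  }, numeric(1))
  structure(data.frame(frame = seq_along(d), distance = d),
            class = c("distance_series", "data.frame"),
            label = "min methyl C to candidate acceptor O")
}

#' Distance between two uniquely selected atoms
#'
#' @param struct [md_structure].
#' @param sel1,sel2 selector lists (see [select_atoms()]) or selector
#'   strings (see [parse_selector()]); each must resolve to exactly
#'   one atom.
#' @return distance in Angstrom.
#' @export
measure_distance <- function(struct, sel1, sel2) {
  one <- function(sel) {
    if (is.character(sel)) sel <- parse_selector(sel)
    s <- do.call(select_atoms, c(list(struct), sel))
    if (length(s) != 1L)
      stop(sprintf("selector must match exactly one atom; matched %d: %s",
                   length(s),
                   paste(utils::head(atom_descriptor(struct, s), 8),
                         collapse = ", ")))
    s
  }
  i <- serial_to_row(struct, c(one(sel1), one(sel2)))
  xyz <- as.matrix(struct$atoms[i, c("x", "y", "z")])
  sqrt(sum((xyz[1, ] - xyz[2, ])^2))
}

#' Minimum distance between two atom sets
#'
#' Shortest pairwise distance between the atoms matched by the two
#' selectors; used e.g. for the crystal-structure contact between a
#' cofactor sulfur and the nearest substrate carboxylate oxygen.
#'
#' @inheritParams measure_distance
#' @return list with `distance` (Angstrom) and the two atom serials
#'   (`serial1`, `serial2`) realizing it.
#' @export
measure_min_distance <- function(struct, sel1, sel2) {
  set <- function(sel) {
    if (is.character(sel)) sel <- parse_selector(sel)
    s <- do.call(select_atoms, c(list(struct), sel))
    if (!length(s)) stop("selector matched no atoms")
    s
  }
  s1 <- set(sel1); s2 <- set(sel2)
  x1 <- as.matrix(struct$atoms[serial_to_row(struct, s1), c("x", "y", "z")])
  x2 <- as.matrix(struct$atoms[serial_to_row(struct, s2), c("x", "y", "z")])
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
  d2[d2 < 0] <- 0
  k <- arrayInd(which.min(d2), dim(d2))
  list(distance = sqrt(d2[k]), serial1 = s1[k[1]], serial2 = s2[k[2]])
}
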