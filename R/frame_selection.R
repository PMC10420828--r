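# Selection of catalytically competent frames and classification of
# the key-contact pattern (direct vs water-mediated).

#' Frame-selection criteria
#'
#' @param reactive_distance_max maximum methyl-carbon to acceptor
#'   distance (Angstrom) for a frame to count as catalytically
#'   competent; the comparison is strict (`<`), default 2.8.
#' @param direct_a,direct_b atom serial vectors defining the direct
#'   key contact (a qualifying hydrogen bond between any A atom and
#'   any B atom, in either polarity).
#' @param bridge_a,bridge_b atom serial vectors for the water-bridge
#'   endpoints; default to the direct-contact endpoints.
#' @return object of class `selection_criteria`.
#' @export
selection_criteria <- function(reactive_distance_max = 2.8,
                               direct_a, direct_b,
                               bridge_a = direct_a, bridge_b = direct_b) {
  if (reactive_distance_max <= 0)
    stop("reactive_distance_max must be positive")
  structure(list(reactive_distance_max = reactive_distance_max,
                 direct_a = direct_a, direct_b = direct_b,
                 bridge_a = bridge_a, bridge_b = bridge_b),
            class = "selection_criteria")
}

#' Filter catalytically competent frames
#'
#' Frames whose reactive distance is strictly below the cutoff.
#'
#' @param series [reactive_distance_series()] output (or any
#'   data.frame with `frame` and `distance`).
#' @param criteria [selection_criteria()] or a numeric cutoff.
#' @return integer vector of frame indices.
#' @export
filter_catalytic_frames <- function(series, criteria = 2.8) {
  cutoff <- if (inherits(criteria, "selection_criteria"))
    criteria$reactive_distance_max else criteria
  if (!nrow(series)) stop("empty distance series")
  series$frame[series$distance < cutoff]
}

classify_coords <- function(traj, frame, topo, hb_crit, sel_crit) {
  obs <- detect_hbonds(traj, topo, hb_crit, frames = frame)
  direct <- any((obs$donor %in% sel_crit$direct_a & obs$acceptor %in% sel_crit$direct_b) |
                  (obs$donor %in% sel_crit$direct_b & obs$acceptor %in% sel_crit$direct_a))
  br <- detect_water_bridges(traj, topo, hb_crit,
                             sel_crit$bridge_a, sel_crit$bridge_b,
                             frames = frame)
  bridged <- nrow(br) > 0L
  if (direct && bridged) "BOTH"
  else if (direct) "DIRECT"
  else if (bridged) "WATER_MEDIATED"
  else "NEITHER"
}

#' Classify one frame's key-contact pattern
#'
#' `DIRECT` when the named direct hydrogen bond qualifies and no
#' water bridge does; `WATER_MEDIATED` for the converse; `BOTH` /
#' `NEITHER` otherwise.
#'
#' @param traj [md_trajectory].
#' @param frame frame index.
#' @param topo [topology_annotation()].
#' @param hb_crit [hbond_criterion()].
#' @param sel_crit [selection_criteria()].
#' @return character scalar pattern label.
#' @export
classify_frame <- function(traj, frame, topo, hb_crit = hbond_criterion(),
                           sel_crit) {
  classify_coords(traj, frame, topo, hb_crit, sel_crit)
}

#' Label every frame of a trajectory
#'
#' Combines the reactive-distance filter and the contact-pattern
#' classification into one table.
#'
#' @inheritParams classify_frame
#' @return data.frame of class `frame_labels` with columns `frame`,
#'   `distance`, `catalytic`, `pattern`.
#' @export
label_frames <- function(traj, topo, hb_crit = hbond_criterion(), sel_crit) {
  series <- reactive_distance_series(traj, topo)
  pattern <- vapply(series$frame, function(i)
    classify_coords(traj, i, topo, hb_crit, sel_crit), character(1))
  structure(data.frame(frame = series$frame, distance = series$distance,
                       catalytic = series$distance < sel_crit$reactive_distance_max,
                       pattern = pattern),
            class = c("frame_labels", "data.frame"))
}

#' Select representative frames per contact pattern
#'
#' For each pattern present among the catalytic frames, the
#' representative is the medoid under pairwise Kabsch-superposed
#' heavy-atom RMSD over the given selection: the frame minimizing the
#' mean RMSD to all other catalytic frames of the same pattern.  Ties
#' are broken by the lowest frame index.  Patterns with no catalytic
#' frame are reported as absent (dropped), not an error.
#'
#' @param traj [md_trajectory].
#' @param labels [label_frames()] output.
#' @param selection atom serials used for the RMSD (default: all
#'   non-hydrogen atoms of the topology).
#' @param per_pattern number of representatives per pattern (ranked by
#'   mean RMSD), default 1.
#' @return named list mapping pattern to integer frame indices.
#' @export
select_representatives <- function(traj, labels, selection = NULL,
                                   per_pattern = 1L) {
  topo <- traj$topology
  if (is.null(selection))
    selection <- topo$atoms$serial[topo$atoms$element != "H"]
  rows <- serial_to_row(topo, selection)
  cand <- labels[labels$catalytic, , drop = FALSE]
  out <- list()
  for (p in unique(cand$pattern)) {
    fr <- sort(cand$frame[cand$pattern == p])
    if (length(fr) == 1L) { out[[p]] <- fr; next }
    coords <- lapply(fr, function(i) traj$frames[[i]][rows, , drop = FALSE])
    k <- length(fr)
    rmat <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      r <- kabsch_superpose(coords[[i]], coords[[j]])$rmsd
      rmat[i, j] <- rmat[j, i] <- r
    }
    mean_r <- rowSums(rmat) / (k - 1L)
    ord <- order(mean_r, fr)   # deterministic tie-break: lowest index
    out[[p]] <- fr[ord[seq_len(min(per_pattern, k))]]
  }
  out
}
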