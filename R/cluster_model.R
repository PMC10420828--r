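# Quantum-cluster active-site model construction: residue subset
# extraction with per-residue scope, frozen-boundary bookkeeping,
# optional link-hydrogen capping, charge/multiplicity validation.

BACKBONE_NAMES <- c("N", "H", "H1", "H2", "H3", "CA", "HA", "HA1", "HA2",
                    "HA3", "C", "O", "OXT")

# single-bond covalent radii (Angstrom) for bond-graph inference
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                    P = 1.07, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39,
                    MG = 1.41, ZN = 1.22, FE = 1.32, "NA" = 1.66, K = 2.03,
                    CA = 1.76)

ATOMIC_NUMBERS <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15, F = 9,
                    CL = 17, BR = 35, I = 53, MG = 12, ZN = 30, FE = 26,
                    "NA" = 11, K = 19, CA = 20)

# bonds between atom rows i<j when distance <= 1.2 * (r_i + r_j)
covalent_bond_pairs <- function(atoms, scale = 1.2) {
  r <- COVALENT_RADII[atoms$element]
  r[is.na(r)] <- 0.77
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(), 0, 2))
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  cut <- outer(r, r, "+") * scale
  hit <- which(upper.tri(d2) & sqrt(d2) <= cut, arr.ind = TRUE)
  hit
}

#' Truncation specification for a cluster model
#'
#' @param residues data.frame with columns `chain`, `resno` and
#'   `scope`, scope one of `"whole"`, `"sidechain"`, `"backbone"`.
#' @param frozen_serials atom serials to freeze (must end up in the
#'   model); typically the truncation-point atoms, fixed to emulate
#'   the surrounding protein scaffold.
#' @param include_waters residue numbers of water molecules to
#'   include whole.
#' @param cap_with_hydrogens place a link hydrogen at 1.09 Angstrom
#'   along each cut covalent bond (default FALSE: the truncation
#'   scheme relies on frozen boundary atoms instead).
#' @return object of class `truncation_spec`.
#' @export
truncation_spec <- function(residues, frozen_serials = integer(),
                            include_waters = integer(),
                            cap_with_hydrogens = FALSE) {
  residues <- as.data.frame(residues)
  if (!all(c("chain", "resno", "scope") %in% names(residues)))
    stop("residues needs chain, resno and scope columns")
  if (!all(residues$scope %in% c("whole", "sidechain", "backbone")))
    stop("scope must be 'whole', 'sidechain' or 'backbone'")
  if (nrow(residues) == 0L && !length(include_waters))
    stop("truncation spec selects no residues")
  structure(list(residues = residues,
                 frozen_serials = as.integer(frozen_serials),
                 include_waters = as.integer(include_waters),
                 cap_with_hydrogens = isTRUE(cap_with_hydrogens)),
            class = "truncation_spec")
}

#' Build a quantum-cluster model from a frame structure
#'
#' Extracts the union of the scoped residues and listed waters from
#' the frame, applies the frozen mask, and (optionally) caps cut
#' covalent bonds with link hydrogens.  Atom ordering is
#' deterministic: residues in spec order (atoms in file order within
#' each), then waters in listed order, then caps.  Construction is a
#' pure function of (frame, spec, charge, multiplicity).
#'
#' @param frame [md_structure] (e.g. a selected trajectory frame).
#' @param spec [truncation_spec()].
#' @param charge total model charge (integer).
#' @param multiplicity spin multiplicity (positive integer; 1 =
#'   singlet).
#' @param provenance optional string recording the source frame.
#' @return object of class `cluster_model`: a list with `structure`
#'   ([md_structure]), `frozen` (logical mask), `charge`,
#'   `multiplicity`, `boundary` (serials of included atoms whose
#'   covalent bonds were cut), `n_caps`, `provenance`.
#' @export
build_cluster_model <- function(frame, spec, charge = 0L, multiplicity = 1L,
                                provenance = NULL) {
  if (!inherits(spec, "truncation_spec")) stop("spec must be a truncation_spec")
  if (multiplicity < 1L) stop("multiplicity must be >= 1")
  a <- frame$atoms
  pick <- integer()
  for (k in seq_len(nrow(spec$residues))) {
    r <- spec$residues[k, ]
    in_res <- which(a$chain == r$chain & a$resno == r$resno)
    if (!length(in_res))
      stop(sprintf("residue %s%d not present in frame", r$chain, r$resno))
    rows <- switch(r$scope,
      whole = in_res,
      backbone = in_res[a$name[in_res] %in% BACKBONE_NAMES],
      sidechain = in_res[!a$name[in_res] %in% BACKBONE_NAMES])
    if (!length(rows))
      stop(sprintf("scope '%s' selects no atoms of residue %s%d (%s)",
                   r$scope, r$chain, r$resno, a$resname[in_res[1]]))
    pick <- c(pick, rows)
  }
  for (w in spec$include_waters) {
    rows <- which(a$resno == w)
    if (!length(rows)) stop(sprintf("water residue %d not present in frame", w))
    pick <- c(pick, rows)
  }
  pick <- unique(pick)
  sel <- a[pick, , drop = FALSE]

  # boundary: included atoms covalently bonded to excluded atoms
  bonds <- covalent_bond_pairs(a)
  inc <- seq_len(nrow(a)) %in% pick
  cut <- bonds[xor(inc[bonds[, 1]], inc[bonds[, 2]]), , drop = FALSE]
  boundary_rows <- unique(ifelse(inc[cut[, 1]], cut[, 1], cut[, 2]))
  boundary <- a$serial[boundary_rows]

  caps <- NULL
  if (spec$cap_with_hydrogens && nrow(cut)) {
    xyz <- as.matrix(a[, c("x", "y", "z")])
    cap_list <- lapply(seq_len(nrow(cut)), function(i) {
      ii <- if (inc[cut[i, 1]]) cut[i, 1] else cut[i, 2]
      jj <- if (inc[cut[i, 1]]) cut[i, 2] else cut[i, 1]
      v <- xyz[jj, ] - xyz[ii, ]
      p <- xyz[ii, ] + 1.09 * v / sqrt(sum(v^2))
      data.frame(serial = NA_integer_, name = "HL", element = "H",
                 resname = a$resname[ii], resno = a$resno[ii],
                 chain = a$chain[ii], insert = a$insert[ii],
                 x = p[1], y = p[2], z = p[3])
    })
    caps <- do.call(rbind, cap_list)
    caps$serial <- max(a$serial) + seq_len(nrow(caps))
  }
  atoms <- rbind(sel[, c("serial", "name", "element", "resname", "resno",
                         "chain", "insert", "x", "y", "z")], caps)
  bad_frozen <- setdiff(spec$frozen_serials, atoms$serial)
  if (length(bad_frozen))
    stop("frozen serial(s) not part of the model: ",
         paste(bad_frozen, collapse = ", "))
  frozen <- atoms$serial %in% spec$frozen_serials
  structure(list(structure = md_structure(atoms, title = "cluster model"),
                 frozen = frozen, charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 boundary = boundary, n_caps = if (is.null(caps)) 0L else nrow(caps),
                 cap_enabled = spec$cap_with_hydrogens,
                 provenance = provenance),
            class = "cluster_model")
}

#' Number of atoms in a cluster model (including caps)
#' @param model [build_cluster_model()] output.
#' @return integer.
#' @export
count_atoms <- function(model) nrow(model$structure$atoms)

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: %d atoms (%d frozen, %d caps), charge %+d, multiplicity %d\n",
              count_atoms(x), sum(x$frozen), x$n_caps, x$charge, x$multiplicity))
  invisible(x)
}

#' Validate a cluster model
#'
#' Advisory checks: (i) boundary atoms with cut covalent bonds that
#' are neither frozen nor capped; (ii) frozen fraction outside the
#' 1-50% range typical of cluster truncation schemes; (iii) electron
#' count inconsistent with the declared spin multiplicity (an even
#' number of electrons requires odd multiplicity, and vice versa).
#'
#' @param model [build_cluster_model()] output.
#' @return data.frame of findings with columns `type`, `message`
#'   (zero rows when clean).
#' @export
validate_model <- function(model) {
  findings <- list()
  add <- function(type, message)
    findings[[length(findings) + 1L]] <<- data.frame(type = type, message = message)
  if (!model$cap_enabled) {
    loose <- setdiff(model$boundary,
                     model$structure$atoms$serial[model$frozen])
    if (length(loose))
      add("dangling_boundary",
          sprintf("boundary atom(s) with cut bonds neither frozen nor capped: %s",
                  paste(loose, collapse = ", ")))
  }
  frac <- mean(model$frozen)
  if (frac < 0.01 || frac > 0.5)
    add("frozen_fraction",
        sprintf("frozen fraction %.1f%% outside the expected 1-50%% range",
                100 * frac))
  z <- ATOMIC_NUMBERS[model$structure$atoms$element]
  if (!anyNA(z)) {
    nelec <- sum(z) - model$charge
    if ((nelec %% 2L == 0L) != (model$multiplicity %% 2L == 1L))
      add("spin_parity",
          sprintf("%d electrons incompatible with multiplicity %d",
                  nelec, model$multiplicity))
  }
  if (!length(findings))
    return(data.frame(type = character(), message = character()))
  do.call(rbind, findings)
}

#' Export / import a cluster model as XYZ plus frozen-atom index file
#'
#' Writes `path` in XYZ format and `<path>.frozen` holding one frozen
#' atom serial per line (the serials are the 1-based positions in the
#' XYZ file), so the frozen mask round-trips losslessly.
#'
#' @param model [build_cluster_model()] output.
#' @param path output `.xyz` path.
#' @return `path`, invisibly.
#' @export
write_cluster_xyz <- function(model, path) {
  write_xyz(model$structure, path)
  writeLines(as.character(which(model$frozen)), paste0(path, ".frozen"))
  invisible(path)
}

#' @rdname write_cluster_xyz
#' @param charge,multiplicity bookkeeping values to attach on read.
#' @export
read_cluster_xyz <- function(path, charge = 0L, multiplicity = 1L) {
  traj <- read_trajectory(path, format = "xyz")
  atoms <- traj$topology$atoms
  frozen <- rep(FALSE, nrow(atoms))
  fpath <- paste0(path, ".frozen")
  if (file.exists(fpath)) {
    idx <- as.integer(readLines(fpath))
    frozen[idx] <- TRUE
  }
  structure(list(structure = md_structure(atoms, title = "cluster model"),
                 frozen = frozen, charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 boundary = integer(), n_caps = 0L, cap_enabled = FALSE,
                 provenance = path),
            class = "cluster_model")
}

#' Export a cluster model as PDB with the frozen flag in the B-factor
#'
#' Frozen atoms get B-factor 1.00, free atoms 0.00 (documented
#' convention of this package's exports).
#'
#' @inheritParams write_cluster_xyz
#' @export
write_cluster_pdb <- function(model, path) {
  write_pdb(model$structure, path, bfac = as.numeric(model$frozen))
  invisible(path)
}
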