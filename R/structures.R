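#' mechprof: active-site trajectory analysis and reaction energy profiles
#'
#' Tools for the geometric post-processing of enzyme active-site MD
#' trajectories (hydrogen-bond and water-bridge occupancies, RMSD,
#' reactive distances, catalytic frame selection) and for the
#' bookkeeping side of the quantum-chemical cluster approach
#' (truncated active-site models, composite reaction energy profiles,
#' Eyring rate/barrier interconversion).
#'
#' @keywords internal
"_PACKAGE"

#' Construct a molecular structure
#'
#' A structure is an ordered table of atoms with Cartesian coordinates
#' in Angstrom.  Atom serials must be unique; they are the handles used
#' by topology annotations, selections and cluster specifications.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`, `insert`, `x`, `y`, `z`.  `insert`
#'   (PDB insertion code) may be omitted and defaults to `""`.
#' @param title character scalar.
#' @return object of class `md_structure`.
#' @export
md_structure <- function(atoms, title = "") {
  req <- c("serial", "name", "element", "resname", "resno", "chain", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  atoms$serial <- as.integer(atoms$serial)
  if (anyDuplicated(atoms$serial))
    stop("atom serials must be unique within a structure")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("atom coordinates must be finite")
  if (any(!nzchar(atoms$element))) stop("every atom needs a non-empty element")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("md_structure: %d atoms, %d residues%s\n",
              nrow(a), nrow(unique(a[, c("chain", "resno", "insert")])),
              if (nzchar(x$title)) paste0(" (", x$title, ")") else ""))
  invisible(x)
}

#' Construct a trajectory
#'
#' A trajectory is a frame-invariant topology (an [md_structure]) plus
#' an ordered list of coordinate matrices, one `n_atoms x 3` matrix per
#' frame, in Angstrom.  Row `i` of every frame corresponds to atom `i`
#' of the topology.
#'
#' @param topology [md_structure].
#' @param frames list of numeric `n_atoms x 3` matrices.
#' @param times optional numeric vector of frame times (ps), strictly
#'   increasing.
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, frames, times = NULL) {
  if (!inherits(topology, "md_structure")) stop("topology must be an md_structure")
  if (!length(frames)) stop("trajectory needs at least one frame")
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3L || nrow(f) != n)
      stop(sprintf("frame %d does not have %d x 3 coordinates", i, n))
    if (!all(is.finite(f))) stop(sprintf("frame %d has non-finite coordinates", i))
  }
  if (!is.null(times)) {
    if (length(times) != length(frames))
      stop("times must have one entry per frame")
    if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  }
  structure(list(topology = topology, frames = frames, times = times),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj [md_trajectory].
#' @return integer.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Select atom serials by attribute
#'
#' Matches atoms on any combination of `serial`, `name`, `element`,
#' `resname`, `resno`, `chain`.  Unused criteria are ignored; vector
#' values select any of their elements.
#'
#' @param struct [md_structure].
#' @param serial,name,element,resname,resno,chain optional filters.
#' @return integer vector of matching atom serials (possibly empty).
#' @export
select_atoms <- function(struct, serial = NULL, name = NULL, element = NULL,
                         resname = NULL, resno = NULL, chain = NULL) {
  a <- struct$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(serial))  keep <- keep & a$serial %in% serial
  if (!is.null(name))    keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(resno))   keep <- keep & a$resno %in% resno
  if (!is.null(chain))   keep <- keep & a$chain %in% chain
  a$serial[keep]
}

# map atom serials to row indices of the topology; error on unknowns
serial_to_row <- function(struct, serials) {
  idx <- match(serials, struct$atoms$serial)
  if (anyNA(idx))
    stop("unknown atom serial(s): ",
         paste(serials[is.na(idx)], collapse = ", "))
  idx
}

# human-readable atom descriptor, e.g. "HIS162:NE2"
atom_descriptor <- function(struct, serials) {
  i <- serial_to_row(struct, serials)
  a <- struct$atoms
  paste0(a$resname[i], a$resno[i], ":", a$name[i])
}

#' Parse a selector string
#'
#' Selector strings are comma-separated `key=value` pairs, e.g.
#' `"resname=SAH,element=S"`.  Valid keys: serial, name, element,
#' resname, resno, chain.
#'
#' @param text selector string.
#' @return named list usable as arguments to [select_atoms()].
#' @export
parse_selector <- function(text) {
  parts <- strsplit(trimws(text), ",", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed selector component: '", p, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% c("serial", "name", "element", "resname", "resno", "chain"))
      stop("unknown selector key: '", key, "'")
    if (key %in% c("serial", "resno")) val <- as.integer(val)
    out[[key]] <- val
  }
  out
}
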