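# Fixed-column PDB and multi-frame XYZ readers/writers, plus the
# energy-record and topology-annotation formats.  Coordinates are
# Angstrom everywhere; energies kcal/mol everywhere.

KCAL_PER_HARTREE <- 627.509474

#' Convert hartree to kcal/mol
#' @param x energies in hartree.
#' @return energies in kcal/mol (1 hartree = 627.509474 kcal/mol).
#' @export
hartree_to_kcal <- function(x) x * KCAL_PER_HARTREE

# parse one vector of ATOM/HETATM lines into an atoms data.frame;
# lineno carries original file line numbers for error messages
parse_pdb_atoms <- function(lines, lineno) {
  num <- function(field, chars, what) {
    v <- suppressWarnings(as.numeric(chars))
    bad <- which(is.na(v) & nzchar(trimws(chars)))
    if (length(bad) == 0L) bad <- which(is.na(v))
    if (anyNA(v))
      stop(sprintf("malformed %s field at line %d: '%s'",
                   what, lineno[bad[1]], trimws(chars[bad[1]])), call. = FALSE)
    v
  }
  sub_ <- function(from, to) substr(lines, from, to)
  atoms <- data.frame(
    serial  = as.integer(num("serial", sub_(7, 11), "serial")),
    name    = trimws(sub_(13, 16)),
    altloc  = trimws(sub_(17, 17)),
    resname = trimws(sub_(18, 20)),
    chain   = trimws(sub_(22, 22)),
    resno   = as.integer(num("resno", sub_(23, 26), "residue number")),
    insert  = trimws(sub_(27, 27)),
    x = num("x", sub_(31, 38), "x coordinate"),
    y = num("y", sub_(39, 46), "y coordinate"),
    z = num("z", sub_(47, 54), "z coordinate"),
    stringsAsFactors = FALSE
  )
  occ_chars <- sub_(55, 60)
  occ <- suppressWarnings(as.numeric(occ_chars))
  occ[is.na(occ)] <- 1.0
  atoms$occupancy <- occ
  elem <- trimws(sub_(77, 78))
  # fall back to the leading letters of the atom name when the element
  # column is blank (common in older files)
  blank <- !nzchar(elem)
  guess <- gsub("[^A-Za-z].*$", "", atoms$name)
  guess <- ifelse(nchar(guess) > 1 & substr(guess, 1, 1) %in% c("H", "C", "N", "O", "S", "P"),
                  substr(guess, 1, 1), guess)
  elem[blank] <- guess[blank]
  atoms$element <- toupper(elem)
  atoms
}

# altLoc policy: keep the highest-occupancy conformer per
# (chain, resno, insert, resname, name); ties -> first in file order
resolve_altloc <- function(atoms) {
  if (all(!nzchar(atoms$altloc))) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resname, atoms$name,
               sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
    if (length(i) == 1L) return(i)
    i[which.max(atoms$occupancy[i])]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

# split raw PDB lines into per-MODEL blocks of ATOM/HETATM lines
pdb_model_blocks <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    if (!any(is_atom)) stop("no ATOM/HETATM records found", call. = FALSE)
    return(list(list(lines = lines[is_atom], lineno = which(is_atom))))
  }
  ends <- c(model_starts[-1] - 1L, length(lines))
  blocks <- list()
  for (k in seq_along(model_starts)) {
    rng <- model_starts[k]:ends[k]
    sel <- rng[is_atom[rng]]
    if (length(sel)) blocks[[length(blocks) + 1L]] <-
        list(lines = lines[sel], lineno = sel)
  }
  if (!length(blocks)) stop("no ATOM/HETATM records found", call. = FALSE)
  blocks
}

#' Read a PDB file
#'
#' Parses ATOM and HETATM records (treated uniformly) into an
#' [md_structure].  Alternate locations are resolved by keeping the
#' highest-occupancy conformer (ties broken by file order); insertion
#' codes are retained as part of the residue identity.  Only the first
#' MODEL is read (with a warning if more are present); use
#' [read_trajectory()] for multi-model files.
#'
#' @param path file path.
#' @return [md_structure] with atoms in file order.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- pdb_model_blocks(lines)
  if (length(blocks) > 1L)
    warning(sprintf("file has %d MODEL blocks; reading the first only",
                    length(blocks)))
  b <- blocks[[1]]
  atoms <- resolve_altloc(parse_pdb_atoms(b$lines, b$lineno))
  atoms$altloc <- atoms$occupancy <- NULL
  title <- sub("^TITLE\\s+", "", grep("^TITLE", lines, value = TRUE)[1])
  md_structure(atoms, title = if (is.na(title)) "" else title)
}

# format one atoms data.frame (+ xyz override) as PDB ATOM lines
format_pdb_lines <- function(atoms, xyz = NULL, bfac = NULL) {
  if (is.null(xyz)) xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (is.null(bfac)) bfac <- rep(0, nrow(atoms))
  name <- ifelse(nchar(atoms$name) >= 4L, substr(atoms$name, 1, 4),
                 sprintf(" %-3s", atoms$name))
  sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L, name, atoms$resname,
          substr(paste0(atoms$chain, " "), 1, 1), atoms$resno %% 10000L,
          substr(paste0(atoms$insert, " "), 1, 1),
          xyz[, 1], xyz[, 2], xyz[, 3], 1.0, bfac, atoms$element)
}

#' Write a structure or trajectory as PDB
#'
#' Structures become single-model files; trajectories multi-model
#' files.  Fields the data model does not carry (anisotropic factors,
#' connectivity, headers) are not preserved: this writer is lossy by
#' contract and emits only ATOM records (HETATM input atoms are written
#' as ATOM).
#'
#' @param x [md_structure] or [md_trajectory].
#' @param path output file path.
#' @param bfac optional numeric B-factor column (structures only).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, bfac = NULL) {
  if (inherits(x, "md_structure")) {
    out <- c(if (nzchar(x$title)) sprintf("TITLE     %s", x$title),
             format_pdb_lines(x$atoms, bfac = bfac), "END")
  } else if (inherits(x, "md_trajectory")) {
    atoms <- x$topology$atoms
    out <- unlist(lapply(seq_along(x$frames), function(i) {
      c(sprintf("MODEL     %4d", i),
        format_pdb_lines(atoms, xyz = x$frames[[i]]), "ENDMDL")
    }))
    out <- c(out, "END")
  } else stop("x must be an md_structure or md_trajectory")
  writeLines(out, path)
  invisible(path)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n <= 0L)
      stop(sprintf("expected an atom count at line %d", pos))
    if (pos + 1L + n > length(lines))
      stop(sprintf("truncated frame %d at line %d", length(frames) + 1L, pos))
    body <- lines[(pos + 2L):(pos + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad))
      stop(sprintf("malformed XYZ atom line %d", pos + 1L + bad[1]))
    el <- vapply(toks, `[`, "", 1L)
    co <- vapply(toks, function(t) as.numeric(t[2:4]), numeric(3))
    if (anyNA(co))
      stop(sprintf("non-numeric coordinate in frame %d", length(frames) + 1L))
    frames[[length(frames) + 1L]] <-
      list(elements = el, xyz = t(co), comment = lines[pos + 1L])
    pos <- pos + 2L + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

#' Read a trajectory
#'
#' Reads a multi-model PDB or a multi-frame (concatenated) XYZ file.
#' All frames must share the first frame's atom count and ordering;
#' the topology is taken from the first frame.  XYZ carries no residue
#' information, so XYZ topologies get `resname = "UNK"`, `resno = 1`
#' and atom names equal to the element symbols.
#'
#' @param path file path.
#' @param format `"pdb"` or `"xyz"`; guessed from the extension when
#'   omitted.
#' @return [md_trajectory].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    blocks <- pdb_model_blocks(lines)
    parsed <- lapply(blocks, function(b) {
      resolve_altloc(parse_pdb_atoms(b$lines, b$lineno))
    })
    n <- nrow(parsed[[1]])
    frames <- vector("list", length(parsed))
    for (i in seq_along(parsed)) {
      if (nrow(parsed[[i]]) != n)
        stop(sprintf("frame %d has %d atoms; expected %d",
                     i, nrow(parsed[[i]]), n))
      frames[[i]] <- unname(as.matrix(parsed[[i]][, c("x", "y", "z")]))
    }
    atoms <- parsed[[1]]
    atoms$altloc <- atoms$occupancy <- NULL
    md_trajectory(md_structure(atoms), frames)
  } else {
    raw <- read_xyz_frames(path)
    n <- length(raw[[1]]$elements)
    for (i in seq_along(raw))
      if (length(raw[[i]]$elements) != n)
        stop(sprintf("frame %d has %d atoms; expected %d",
                     i, length(raw[[i]]$elements), n))
    el <- raw[[1]]$elements
    atoms <- data.frame(serial = seq_len(n), name = el, element = toupper(el),
                        resname = "UNK", resno = 1L, chain = "A",
                        x = raw[[1]]$xyz[, 1], y = raw[[1]]$xyz[, 2],
                        z = raw[[1]]$xyz[, 3], stringsAsFactors = FALSE)
    md_trajectory(md_structure(atoms, title = trimws(raw[[1]]$comment)),
                  lapply(raw, function(f) unname(f$xyz)))
  }
}

#' Write a trajectory as multi-frame XYZ
#'
#' Coordinates are printed at 3 decimals (the format's conventional
#' precision); anything beyond that is lost on a round trip.
#'
#' @param traj [md_trajectory] (an [md_structure] is treated as a
#'   single frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  if (inherits(traj, "md_structure"))
    traj <- md_trajectory(traj, list(unname(as.matrix(traj$atoms[, c("x", "y", "z")]))))
  el <- traj$topology$atoms$element
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    writeLines(c(sprintf("%d", length(el)), sprintf("frame %d", i),
                 sprintf("%-2s %12.3f %12.3f %12.3f", el, f[, 1], f[, 2], f[, 3])),
               con)
  }
  invisible(path)
}

## ---- energy record tables ----------------------------------------------

ENERGY_COLUMNS <- c("E_MB", "E_LB", "E_solv_eps4", "E_solv_eps80", "ZPE")
STATE_LABELS <- c("initial", "TS", "final")

#' Construct an energy-record table
#'
#' Rows are stationary points keyed by `(model_id, state)`, with state
#' one of `initial`, `TS`, `final` (or a scan distance in Angstrom,
#' stored as its character form).  Energy columns (kcal/mol):
#' `E_MB` (small-basis electronic), `E_LB` (large-basis electronic),
#' `E_solv_eps4`, `E_solv_eps80` (continuum solvation at dielectric 4
#' and 80) and `ZPE` (zero-point vibrational).  Each column carries a
#' mode flag, `"relative"` (relative to the model's initial state) or
#' `"absolute"`.
#'
#' @param rows data.frame with `model_id`, `state` and a subset of the
#'   energy columns.
#' @param modes named character vector mapping present energy columns
#'   to `"relative"` or `"absolute"`.
#' @return data.frame of class `energy_record_table` with a `modes`
#'   attribute; missing optional columns are recorded in the
#'   `missing_columns` attribute, and models lacking a full
#'   initial/TS/final triple in `incomplete_profiles`.
#' @export
energy_record_table <- function(rows, modes) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("energy-record table must have at least one row")
  if (!all(c("model_id", "state") %in% names(rows)))
    stop("rows need 'model_id' and 'state' columns")
  present <- intersect(ENERGY_COLUMNS, names(rows))
  if (!length(present)) stop("no recognized energy columns present")
  missing_cols <- setdiff(ENERGY_COLUMNS, present)
  if (!all(present %in% names(modes)))
    stop("mode flag missing for column(s): ",
         paste(setdiff(present, names(modes)), collapse = ", "))
  bad_mode <- !modes[present] %in% c("relative", "absolute")
  if (any(bad_mode))
    stop("modes must be 'relative' or 'absolute' (got: ",
         paste(modes[present][bad_mode], collapse = ", "), ")")
  key <- paste(rows$model_id, rows$state, sep = "\r")
  if (anyDuplicated(key)) {
    d <- rows[duplicated(key), c("model_id", "state")][1, ]
    stop(sprintf("duplicate record for (%s, %s)", d$model_id, d$state))
  }
  for (cn in present) {
    v <- rows[[cn]]
    if (!is.numeric(v) || !all(is.finite(v)))
      stop("column ", cn, " must be finite numeric")
  }
  incomplete <- character()
  for (m in unique(rows$model_id)) {
    st <- rows$state[rows$model_id == m]
    if (any(st %in% STATE_LABELS) && !all(STATE_LABELS %in% st))
      incomplete <- c(incomplete, m)
  }
  rownames(rows) <- NULL
  structure(rows, class = c("energy_record_table", "data.frame"),
            modes = modes[present], missing_columns = missing_cols,
            incomplete_profiles = incomplete)
}

#' Read an energy-record table (CSV or JSON)
#'
#' The CSV dialect requires a one-line header schema before the column
#' header, declaring each energy column's mode, e.g.
#' `# modes: E_MB=relative E_LB=relative E_solv_eps4=absolute ...`.
#' The JSON mirror holds `{"modes": {...}, "rows": [...]}`.
#'
#' @param path file path (`.csv` or `.json`).
#' @return [energy_record_table()].
#' @export
read_energy_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    return(energy_record_table(as.data.frame(obj$rows),
                               unlist(obj$modes)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty energy-record file: ", path)
  if (!grepl("^#\\s*modes:", lines[1]))
    stop("first line must declare column modes ('# modes: COL=relative ...')")
  toks <- strsplit(trimws(sub("^#\\s*modes:", "", lines[1])), "\\s+")[[1]]
  kv <- strsplit(toks, "=", fixed = TRUE)
  if (any(vapply(kv, length, 1L) != 2L))
    stop("malformed mode declaration: ", lines[1])
  modes <- vapply(kv, `[`, "", 2L)
  names(modes) <- vapply(kv, `[`, "", 1L)
  body <- utils::read.csv(textConnection(lines[-1]), stringsAsFactors = FALSE,
                          colClasses = "character")
  for (cn in intersect(ENERGY_COLUMNS, names(body))) {
    v <- suppressWarnings(as.numeric(body[[cn]]))
    if (anyNA(v)) {
      row <- which(is.na(v))[1]
      stop(sprintf("non-numeric value '%s' in column %s, data row %d",
                   body[[cn]][row], cn, row))
    }
    body[[cn]] <- v
  }
  energy_record_table(body, modes)
}

#' Write an energy-record table (CSV or JSON)
#'
#' @param table [energy_record_table()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_energy_records <- function(table, path) {
  modes <- attr(table, "modes")
  rows <- as.data.frame(table)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(modes = as.list(modes), rows = rows), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    hdr <- paste0("# modes: ",
                  paste(names(modes), modes, sep = "=", collapse = " "))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

## ---- topology annotations ----------------------------------------------

#' Construct a topology annotation
#'
#' Donor/acceptor chemistry is supplied explicitly (not inferred from
#' element tables): `donors` pairs each donor heavy atom with one of
#' its hydrogens, `acceptors` lists acceptor heavy atoms, and
#' `reactive_pair` names the methyl carbon and its candidate acceptor
#' oxygens for the reactive-distance series.
#'
#' @param structure [md_structure] the serials refer to.
#' @param donors data.frame with columns `donor`, `hydrogen` (serials).
#' @param acceptors integer vector of acceptor atom serials.
#' @param water_residue_names character vector, e.g. `c("HOH","SOL")`.
#' @param reactive_pair `list(carbon = serial, oxygens = serials)`, or
#'   NULL.
#' @return object of class `topology_annotation`.
#' @export
topology_annotation <- function(structure, donors, acceptors,
                                water_residue_names = c("HOH", "SOL", "WAT", "TIP3"),
                                reactive_pair = NULL) {
  donors <- as.data.frame(donors)
  if (!all(c("donor", "hydrogen") %in% names(donors)))
    stop("donors needs 'donor' and 'hydrogen' columns")
  serial_to_row(structure, donors$donor)
  serial_to_row(structure, donors$hydrogen)
  if (any(donors$donor == donors$hydrogen))
    stop("a donor heavy atom cannot be its own hydrogen")
  serial_to_row(structure, acceptors)
  if (!is.null(reactive_pair)) {
    serial_to_row(structure, reactive_pair$carbon)
    if (length(reactive_pair$oxygens) < 1L)
      stop("reactive_pair needs at least one candidate acceptor oxygen")
    serial_to_row(structure, reactive_pair$oxygens)
  }
  structure(list(donors = donors, acceptors = as.integer(acceptors),
                 water_residue_names = water_residue_names,
                 reactive_pair = reactive_pair),
            class = "topology_annotation")
}

#' Read/write a topology annotation as JSON
#' @param path file path.
#' @param structure [md_structure] used to validate serials.
#' @return [topology_annotation()].
#' @export
read_annotation <- function(path, structure) {
  obj <- jsonlite::fromJSON(path)
  rp <- if (!is.null(obj$reactive_pair))
    list(carbon = obj$reactive_pair$carbon,
         oxygens = obj$reactive_pair$oxygens)
  topology_annotation(structure, as.data.frame(obj$donors), obj$acceptors,
                      obj$water_residue_names, rp)
}

#' @rdname read_annotation
#' @param topo [topology_annotation()] to serialize.
#' @export
write_annotation <- function(topo, path) {
  jsonlite::write_json(list(donors = topo$donors,
                            acceptors = topo$acceptors,
                            water_residue_names = topo$water_residue_names,
                            reactive_pair = topo$reactive_pair),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
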