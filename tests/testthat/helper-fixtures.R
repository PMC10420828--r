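# Small in-code fixtures shared across test files.

# a collinear donor-hydrogen-acceptor construction at distance d
collinear_hbond_structure <- function(d_da = 2.9) {
  atoms <- data.frame(
    serial = 1:3,
    name = c("ND", "HD", "OA"), element = c("N", "H", "O"),
    resname = c("DON", "DON", "ACC"), resno = c(1L, 1L, 2L), chain = "A",
    x = c(0, 1, d_da), y = 0, z = 0)
  struct <- md_structure(atoms)
  topo <- topology_annotation(struct,
                              donors = data.frame(donor = 1L, hydrogen = 2L),
                              acceptors = 3L)
  list(struct = struct, topo = topo)
}

# two whole glycines plus one water: 2 x 7 + 3 = 17 atoms
glycine_water_structure <- function() {
  gly <- function(resno, offset) {
    data.frame(
      name = c("N", "H", "CA", "HA2", "HA3", "C", "O"),
      element = c("N", "H", "C", "H", "H", "C", "O"),
      resname = "GLY", resno = resno, chain = "A",
      x = offset + c(0, -0.6, 1.45, 1.8, 1.8, 2.0, 3.2),
      y = c(0, 0.8, 0, 0.9, -0.9, -1.3, -1.4),
      z = 0)
  }
  wat <- data.frame(
    name = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
    resname = "HOH", resno = 500L, chain = "A",
    x = c(0, 0.96, -0.3), y = c(6, 6, 6.9), z = 0)
  atoms <- rbind(gly(10L, 0), gly(11L, 8), wat)
  atoms$serial <- seq_len(nrow(atoms))
  md_structure(atoms)
}

# five-residue frame with distinct side chains for truncation tests
five_residue_structure <- function() {
  res <- function(resno, resname, offset, side_names, side_elements) {
    bb <- data.frame(
      name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      resname = resname, resno = resno, chain = "A",
      x = offset + c(0, 1.45, 2.0, 3.2), y = c(0, 0, -1.3, -1.4), z = 0)
    # side chain as a short bonded chain hanging off CA
    sc <- data.frame(
      name = side_names, element = side_elements,
      resname = resname, resno = resno, chain = "A",
      x = offset + 1.45, y = 1.45 * seq_along(side_names),
      z = 0.2 * seq_along(side_names))
    rbind(bb, sc)
  }
  atoms <- rbind(
    res(1L, "ALA", 0,  c("CB"), c("C")),
    res(2L, "SER", 5,  c("CB", "OG"), c("C", "O")),
    res(3L, "CYS", 10, c("CB", "SG"), c("C", "S")),
    res(4L, "ALA", 15, c("CB"), c("C")),
    res(5L, "SER", 20, c("CB", "OG"), c("C", "O")))
  atoms$serial <- seq_len(nrow(atoms))
  md_structure(atoms)
}

table3_path <- function()
  system.file("extdata", "table3_energies.csv", package = "mechprof")

table2_path <- function()
  system.file("extdata", "table2_scan.csv", package = "mechprof")

read_scan_points <- function(model) {
  df <- utils::read.csv(table2_path())
  data.frame(distance = df$distance, energy = df[[model]])
}
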