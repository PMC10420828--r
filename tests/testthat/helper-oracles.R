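# Independent oracles used to cross-check the implementation.  These
# deliberately use different algorithms / code paths than the package
# (eigen-decomposition quaternion RMSD vs SVD Kabsch; scalar triple
# loops vs vectorized detection).

# Quaternion characteristic RMSD (Theobald-style key matrix): the
# optimal-superposition RMSD from the largest eigenvalue of the 4x4
# key matrix, no rotation ever constructed.
quaternion_rmsd <- function(mobile, reference) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(p, q)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(p^2) + sum(q^2) - 2 * lmax) / nrow(p)
  sqrt(max(0, msd))
}

# Scalar brute-force hydrogen-bond detector: explicit loop over all
# donor/acceptor combinations with the same inclusive criterion.
brute_force_hbonds <- function(struct, topo, crit) {
  a <- struct$atoms
  pos <- function(serial) {
    i <- which(a$serial == serial)
    c(a$x[i], a$y[i], a$z[i])
  }
  reskey <- function(serial) {
    i <- which(a$serial == serial)
    paste(a$chain[i], a$resno[i], a$insert[i])
  }
  out <- NULL
  for (k in seq_len(nrow(topo$donors))) {
    d <- topo$donors$donor[k]; h <- topo$donors$hydrogen[k]
    for (acc in topo$acceptors) {
      if (acc == d) next
      if (reskey(acc) == reskey(d)) next
      pd <- pos(d); ph <- pos(h); pa <- pos(acc)
      dda <- sqrt(sum((pd - pa)^2))
      if (dda > crit$distance_cutoff) next
      v1 <- pd - ph; v2 <- pa - ph
      ang <- acos(min(1, max(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      dev <- 180 - ang
      if (dev > crit$angle_cutoff) next
      out <- rbind(out, data.frame(donor = d, hydrogen = h, acceptor = acc,
                                   d_DA = dda, linearity_deviation = dev))
    }
  }
  if (is.null(out))
    out <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), d_DA = numeric(),
                      linearity_deviation = numeric())
  out
}

# Brute-force water-bridge detector built on the brute-force H-bond
# detector: triple loop over waters and the two endpoint sets.
brute_force_bridges <- function(struct, topo, crit, set_a, set_b) {
  a <- struct$atoms
  obs <- brute_force_hbonds(struct, topo, crit)
  water_res <- unique(a$resno[a$resname %in% topo$water_residue_names])
  water_atoms <- function(w) a$serial[a$resno == w &
                                        a$resname %in% topo$water_residue_names]
  bridged_waters <- integer()
  for (w in water_res) {
    wa <- water_atoms(w)
    leg <- function(set) {
      hit <- FALSE
      for (i in seq_len(nrow(obs))) {
        if ((obs$donor[i] %in% wa && obs$acceptor[i] %in% set) ||
            (obs$donor[i] %in% set && obs$acceptor[i] %in% wa)) hit <- TRUE
      }
      hit
    }
    if (leg(set_a) && leg(set_b)) bridged_waters <- c(bridged_waters, w)
  }
  bridged_waters
}

# structure for one trajectory frame (coords swapped in)
frame_structure <- function(traj, i) {
  s <- traj$topology
  s$atoms[, c("x", "y", "z")] <- traj$frames[[i]]
  s
}

# random rotation matrix from a normalized quaternion
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
           2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
           2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)),
         3, 3, byrow = TRUE)
}

# random small annotated frame (<= 30 atoms) for brute-force
# comparisons: donors with attached hydrogens, acceptors, optionally
# waters, scattered in a box so contacts actually occur
random_annotated_frame <- function(n_donors = 3, n_acceptors = 4,
                                   n_waters = 0, box = 7) {
  rows <- list(); serial <- 0L; resno <- 0L
  add <- function(name, element, resname, p) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, element = element, resname = resname,
      resno = resno, chain = "A", x = p[1], y = p[2], z = p[3])
    serial
  }
  donors <- NULL
  for (i in seq_len(n_donors)) {
    resno <- resno + 1L
    pd <- stats::runif(3, 0, box)
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    d <- add("ND", "N", "DON", pd)
    h <- add("HD", "H", "DON", pd + 1.0 * u)
    donors <- rbind(donors, data.frame(donor = d, hydrogen = h))
  }
  acceptors <- integer()
  for (i in seq_len(n_acceptors)) {
    resno <- resno + 1L
    acceptors <- c(acceptors, add("OA", "O", "ACC", stats::runif(3, 0, box)))
  }
  for (i in seq_len(n_waters)) {
    resno <- resno + 1L
    pw <- stats::runif(3, 0, box)
    o <- add("OW", "O", "HOH", pw)
    u1 <- stats::rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- stats::rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
    h1 <- add("HW1", "H", "HOH", pw + 0.96 * u1)
    h2 <- add("HW2", "H", "HOH", pw + 0.96 * u2)
    donors <- rbind(donors,
                    data.frame(donor = c(o, o), hydrogen = c(h1, h2)))
    acceptors <- c(acceptors, o)
  }
  struct <- md_structure(do.call(rbind, rows))
  topo <- topology_annotation(struct, donors, acceptors,
                              water_residue_names = "HOH")
  list(struct = struct, topo = topo)
}
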