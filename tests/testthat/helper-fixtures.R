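# Small structures built in code, shared across test files.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     record = "ATOM", altloc = " ", icode = " ",
                     element = "") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resname, chain, resno, icode, x, y, z, element)
}

# n-residue poly-ALA chain along x (gently wiggled so the CA trace is
# never collinear), 5 atoms per residue
toy_chain <- function(n = 5, chain = "A", spacing = 3.8) {
  rows <- list()
  for (i in seq_len(n)) {
    base <- c((i - 1) * spacing, 0.8 * sin(i), 0.6 * cos(2 * i))
    pos <- list(N = base + c(-0.7, 1.2, 0), CA = base,
                C = base + c(0.8, -1.1, 0.3), O = base + c(0.9, -2.2, 0.6),
                CB = base + c(0, 0.4, 1.4))
    for (nm in names(pos)) {
      rows[[length(rows) + 1]] <- data.frame(
        name = nm, element = substr(nm, 1, 1), resname = "ALA", resno = i,
        icode = "", chain = chain, x = pos[[nm]][1], y = pos[[nm]][2],
        z = pos[[nm]][3], stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  Molecule(atoms, label = "toy-chain")
}

# hollow shell of single-atom residues, for swarm-placement geometry
sphere_shell <- function(n = 80, radius = 20, chain = "A") {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", element = "C", resname = "ALA",
    resno = seq_len(n), icode = "", chain = chain,
    x = radius * sin(phi) * cos(theta),
    y = radius * sin(phi) * sin(theta),
    z = radius * cos(phi), stringsAsFactors = FALSE)
  Molecule(atoms, kind = "protein", label = "shell")
}

random_unit_quaternion <- function() {
  q <- stats::rnorm(4)
  quat_normalize(q)
}

random_test_pose <- function(n_modes = 0) {
  Pose(stats::rnorm(3, sd = 5), random_unit_quaternion(),
       if (n_modes) stats::rnorm(n_modes) else numeric(0))
}
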