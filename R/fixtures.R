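#' Build a peptide in extended conformation from sequence
#'
#' Forward-kinematics construction of a backbone-only peptide (N, CA, C,
#' O and CB except for glycine) with ideal bond lengths and angles and
#' phi = psi = omega = 180 degrees (fully extended trans chain).
#' Consecutive CA-CA distances come out at ~3.80 angstrom as dictated by
#' the trans peptide geometry.
#'
#' @param sequence one-letter amino-acid string, e.g. `"PQQATDD"`.
#' @param chain chain id (default `"A"`).
#' @return a [Molecule] of kind `peptide` (or `protein` above 30
#'   residues), residues numbered from 1.
#' @export
build_extended_peptide <- function(sequence, chain = "A") {
  aa1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!length(letters1)) stop_gd("empty sequence")
  if (any(!letters1 %in% names(aa1)))
    stop_gd("unknown residue code: ", letters1[!letters1 %in% names(aa1)][1])
  res3 <- unname(aa1[letters1])
  n_res <- length(res3)
  # ideal backbone geometry (angstrom, degrees)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231; b_CACB <- 1.521
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.8
  a_CCACB <- 110.1; t_NCCACB <- 122.68
  N <- CA <- C <- vector("list", n_res)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(b_NCA, 0, 0)
  ang <- a_NCAC * pi / 180
  C[[1]] <- CA[[1]] + b_CAC * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)[-1]) {
    N[[i]] <- nerf(N[[i - 1]], CA[[i - 1]], C[[i - 1]], b_CN, a_CACN, 180)  # psi
    CA[[i]] <- nerf(CA[[i - 1]], C[[i - 1]], N[[i]], b_NCA, a_CNCA, 180)   # omega
    C[[i]] <- nerf(C[[i - 1]], N[[i]], CA[[i]], b_CAC, a_NCAC, 180)        # phi
  }
  rows <- list()
  for (i in seq_len(n_res)) {
    O <- nerf(N[[i]], CA[[i]], C[[i]], b_CO, a_CACO, 0)  # psi + 180
    atoms <- list(N = N[[i]], CA = CA[[i]], C = C[[i]], O = O)
    if (res3[i] != "GLY")
      atoms$CB <- nerf(N[[i]], C[[i]], CA[[i]], b_CACB, a_CCACB, t_NCCACB)
    for (nm in names(atoms)) {
      rows[[length(rows) + 1]] <- data.frame(
        name = nm, element = substr(nm, 1, 1), resname = res3[i], resno = i,
        icode = "", chain = chain, x = atoms[[nm]][1], y = atoms[[nm]][2],
        z = atoms[[nm]][3], stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  Molecule(atoms, label = paste0("peptide-", sequence))
}

# NeRF atom placement: position d bonded to c with the given bond length,
# angle(b, c, d) and torsion(a, b, c, d), in degrees.
nerf <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Atom positions of a five-atom pseudo-alanine residue centered on a CA
# position, oriented by an orthonormal frame (e_r outward, e_t1/e_t2
# tangent).
pseudo_residue_xyz <- function(ca, e_r, e_t1, e_t2) {
  rbind(N = ca + 1.46 * e_t1,
        CA = ca,
        C = ca - 0.76 * e_t1 + 1.25 * e_t2,
        O = ca - 0.80 * e_t1 + 2.48 * e_t2,
        CB = ca + 1.52 * e_r)
}

pseudo_residue <- function(ca, e_r, e_t1, e_t2, resno, chain) {
  pos <- pseudo_residue_xyz(ca, e_r, e_t1, e_t2)
  data.frame(
    name = rownames(pos), element = substr(rownames(pos), 1, 1),
    resname = "ALA", resno = resno, icode = "", chain = chain,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    stringsAsFactors = FALSE, row.names = NULL)
}

# Radial CA position along lattice direction e_r: the shell radius R0, or,
# where the ray runs into the native ligand cloud, the largest radius
# (below the cloud) at which the residue's closest heavy atom sits `gap`
# angstrom from the nearest ligand atom.
mold_radius <- function(e_r, fr, cloud, R0, gap) {
  dist_at <- function(r)
    min(cross_dist(pseudo_residue_xyz(r * e_r, e_r, fr$e_t1, fr$e_t2), cloud))
  rs <- seq(0.5, R0, by = 0.25)
  ds <- vapply(rs, dist_at, numeric(1))
  if (all(ds >= gap)) return(R0)
  first <- which(ds < gap)[1]
  if (first == 1) return(rs[1])
  stats::uniroot(function(r) dist_at(r) - gap, c(rs[first - 1], rs[first]),
                 tol = 1e-4)$root
}

tangent_frame <- function(e_r) {
  ref <- if (abs(e_r[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e_t1 <- unit(cross3(ref, e_r))
  list(e_t1 = e_t1, e_t2 = unit(cross3(e_r, e_t1)))
}

#' Generate a synthetic receptor-ligand complex with a known answer
#'
#' Builds a toy docking problem entirely in code: the ligand is a short
#' helix-like poly-Ala fragment (axis along x, centered at the origin);
#' the receptor is a pseudo-protein shell of poly-Ala residues on a
#' spherical Fibonacci lattice of radius ~16 angstrom whose +z pole is
#' molded into a concave groove complementary to the ligand. Molding
#' works by placing the native ligand just inside the pole and receding
#' each receptor lattice ray until the residue's closest heavy atom sits
#' `ca_gap` angstrom from the nearest native ligand atom, so the native
#' pose has many near-optimal contacts and the score landscape has a
#' genuine funnel.
#' Interface residues (heavy-atom cross distance below 5 angstrom in the
#' native pose) are returned as ground-truth restraints for both
#' partners.
#'
#' @param seed integer; small coordinate jitter makes each seed a
#'   distinct but reproducible complex.
#' @param n_receptor_residues receptor size (default 60, minimum 4).
#' @param n_ligand_residues ligand size (default 12, minimum 4).
#' @param ca_gap closest-heavy-atom molding distance, angstrom (default
#'   3.9, near the pair-potential optimum so the native pose is a deep
#'   score maximum).
#' @return list with `receptor`, `ligand` ([Molecule]s), `native_pose`
#'   (a [Pose]), `restraints` (a `RestraintSet`), and `native_coords`
#'   (posed ligand coordinates).
#' @export
make_toy_complex <- function(seed = 1, n_receptor_residues = 60,
                             n_ligand_residues = 12, ca_gap = 3.9) {
  if (n_receptor_residues < 4 || n_ligand_residues < 4)
    stop_gd("need at least 4 residues on each side")
  R0 <- 16; native_z <- 12
  with_seed(seed, {
    # helix-like ligand along x, centered at origin; the radius tapers
    # along the axis so the molded groove rejects end-for-end flips
    rise <- 1.5; turn <- 100 * pi / 180
    lrows <- list()
    radials <- list()
    for (k in seq_len(n_ligand_residues)) {
      r_h <- 1.5 + 1.6 * (k - 1) / max(1, n_ligand_residues - 1)
      axis_pos <- c((k - 1) * rise, 0, 0)
      radial <- c(0, cos(k * turn), sin(k * turn))
      radials[[k]] <- radial
      ca <- axis_pos + r_h * radial + stats::rnorm(3, sd = 0.05)
      fr <- tangent_frame(radial)
      lrows[[k]] <- pseudo_residue(ca, radial, fr$e_t1, fr$e_t2, k, "B")
    }
    latoms <- do.call(rbind, lrows)
    # acidic residues spread along the helix pair with basic receptor
    # residues below (electrostatic steering marks the native register)
    lq_res <- unique(round(stats::quantile(seq_len(n_ligand_residues),
                                           c(0.2, 0.5, 0.8))))
    for (k in lq_res) {
      sel <- latoms$resno == k
      latoms$resname[sel] <- "ASP"
      ca_row <- latoms[sel & latoms$name == "CA", ]
      od1 <- c(ca_row$x, ca_row$y, ca_row$z) + 1.4 * radials[[k]]
      latoms <- rbind(latoms, data.frame(
        name = "OD1", element = "O", resname = "ASP", resno = k, icode = "",
        chain = "B", x = od1[1], y = od1[2], z = od1[3],
        stringsAsFactors = FALSE))
    }
    latoms <- latoms[order(latoms$resno), ]
    latoms$serial <- seq_len(nrow(latoms))
    cen <- colMeans(as.matrix(latoms[, c("x", "y", "z")]))
    latoms$x <- latoms$x - cen[1]; latoms$y <- latoms$y - cen[2]
    latoms$z <- latoms$z - cen[3]
    ligand <- Molecule(latoms, label = "toy-ligand")
    native_pose <- Pose(c(0, 0, native_z), c(1, 0, 0, 0))
    native_cloud <- apply_pose(ligand, native_pose)
    # receptor shell molded around the native ligand
    i <- seq_len(n_receptor_residues) - 0.5
    phi <- acos(1 - 2 * i / n_receptor_residues)   # polar angle from +z
    theta <- pi * (1 + sqrt(5)) * i
    rows <- list()
    dirs <- molded <- vector("list", n_receptor_residues)
    for (k in seq_len(n_receptor_residues)) {
      e_r <- c(sin(phi[k]) * cos(theta[k]), sin(phi[k]) * sin(theta[k]),
               cos(phi[k]))
      fr <- tangent_frame(e_r)
      r_k <- mold_radius(e_r, fr, native_cloud, R0, ca_gap)
      ca <- r_k * e_r + stats::rnorm(3, sd = 0.05)
      dirs[[k]] <- e_r
      molded[[k]] <- list(ca = ca, groove = r_k < R0 - 0.5)
      rows[[k]] <- pseudo_residue(ca, e_r, fr$e_t1, fr$e_t2, k, "A")
    }
    ratoms <- do.call(rbind, rows)
    # basic partner residue under each acidic ligand residue
    lig_hm <- heavy_mask(ligand)
    for (k in lq_res) {
      od1_nat <- native_cloud[ligand$atoms$name == "OD1" &
                                ligand$atoms$resno == k, , drop = FALSE]
      cas <- t(vapply(molded, `[[`, numeric(3), "ca"))
      cand <- which(vapply(molded, `[[`, logical(1), "groove") &
                      ratoms$resname[match(seq_along(molded),
                                           ratoms$resno)] == "ALA")
      if (!length(cand)) next
      jbest <- cand[which.min(cross_dist(od1_nat, cas[cand, , drop = FALSE]))]
      sel <- ratoms$resno == jbest
      ratoms$resname[sel] <- "LYS"
      nz <- molded[[jbest]]$ca + 1.9 * dirs[[jbest]]
      ratoms <- rbind(ratoms, data.frame(
        name = "NZ", element = "N", resname = "LYS", resno = jbest,
        icode = "", chain = "A", x = nz[1], y = nz[2], z = nz[3],
        stringsAsFactors = FALSE))
    }
    ratoms <- ratoms[order(ratoms$resno), ]
    ratoms$serial <- seq_len(nrow(ratoms))
    receptor <- Molecule(ratoms, label = "toy-receptor")
  })
  native_coords <- apply_pose(ligand, native_pose)
  rxyz <- coords(receptor, heavy_only = TRUE)
  # ground-truth interface restraints from native contacts
  d <- cross_dist(rxyz, native_coords[heavy_mask(ligand), , drop = FALSE])
  rres <- receptor$atoms$resno[heavy_mask(receptor)]
  lres <- ligand$atoms$resno[heavy_mask(ligand)]
  rec_hit <- sort(unique(rres[apply(d, 1, min) <= 5]))
  lig_hit <- sort(unique(lres[apply(d, 2, min) <= 5]))
  restraints <- parse_restraints(
    paste(sprintf("A.%d", rec_hit), collapse = " "),
    paste(sprintf("B.%d", lig_hit), collapse = " "))
  list(receptor = receptor, ligand = ligand, native_pose = native_pose,
       restraints = restraints, native_coords = native_coords)
}
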