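test_that("swarm centers sit placement_distance off an ideal shell", {
  shell <- sphere_shell(120, radius = 20)
  swarms <- generate_swarms(shell)
  expect_gt(length(swarms), 3)
  cen <- colMeans(coords(shell))
  r <- vapply(swarms, function(s) sqrt(sum((s$center - cen)^2)), numeric(1))
  expect_true(all(abs(r - 30) < 1))
  # spacing respected
  centers <- t(vapply(swarms, `[[`, numeric(3), "center"))
  d <- as.matrix(dist(centers)); diag(d) <- Inf
  expect_true(all(d >= 10 - 1e-9))
})

test_that("swarm count grows with receptor surface and respects the override", {
  small <- sphere_shell(80, radius = 14)
  big <- sphere_shell(320, radius = 28)
  n_small <- length(generate_swarms(small))
  n_big <- length(generate_swarms(big))
  expect_gt(n_big, n_small)
  # override: both directions
  expect_length(generate_swarms(big, n_swarms = 5), 5)
  expect_gte(length(generate_swarms(small, n_swarms = n_small + 10)),
             n_small + 10)
  expect_error(generate_swarms(Molecule(toy_chain(1)$atoms[1:3, ])),
               "receptor too small")
})

test_that("swarm generation is deterministic and rotation-equivariant", {
  shell <- sphere_shell(100, radius = 18)
  s1 <- generate_swarms(shell)
  s2 <- generate_swarms(shell)
  expect_identical(s1, s2)
  q <- quat_from_axis_angle(c(1, 2, 0.5), 1.1)
  rot <- shell
  rot$atoms[, c("x", "y", "z")] <- rotate_point(q, coords(shell))
  s3 <- generate_swarms(rot)
  expect_length(s3, length(s1))
  c1 <- t(vapply(s1, `[[`, numeric(3), "center"))
  c3 <- t(vapply(s3, `[[`, numeric(3), "center"))
  expect_equal(rotate_point(q, c1), c3, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("restraint filtering keeps only swarms near the declared patch", {
  shell <- sphere_shell(150, radius = 20)
  swarms <- generate_swarms(shell)
  # residue nearest the +z pole
  pole <- shell$atoms$resno[which.max(shell$atoms$z)]
  rs <- parse_restraints(sprintf("A.%d", pole))
  kept <- filter_swarms_by_restraints(swarms, shell, rs, keep_cutoff = 20)
  expect_lt(length(kept), length(swarms))
  patch <- as.matrix(shell$atoms[shell$atoms$resno == pole, c("x", "y", "z")])
  for (s in kept)
    expect_lte(min(cross_dist(matrix(s$center, 1), patch)), 20)
  # survivors are a pure subset
  ids <- vapply(swarms, `[[`, numeric(1), "id")
  expect_true(all(vapply(kept, `[[`, numeric(1), "id") %in% ids))
  # no receptor restraints: identity
  expect_identical(filter_swarms_by_restraints(swarms, shell,
                                               parse_restraints("")), swarms)
  expect_error(filter_swarms_by_restraints(swarms, shell,
                                           parse_restraints("Z.999")),
               "unknown restraint residue")
})

test_that("membrane filtering removes the slab plus cushion", {
  mk_swarm <- function(z, id) structure(list(id = id, center = c(0, 0, z),
                                             radius = 10, glowworms = NULL),
                                        class = "Swarm")
  slab <- structure(list(beads = cbind(0, 0, c(-15, 15)), z_min = -15,
                         z_max = 15), class = "MembraneModel")
  swarms <- list(mk_swarm(30, 1), mk_swarm(0, 2), mk_swarm(19, 3),
                 mk_swarm(-25, 4))
  kept <- filter_swarms_by_membrane(swarms, slab, cushion = 5)
  expect_equal(vapply(kept, `[[`, numeric(1), "id"), c(1, 4))
  expect_error(filter_swarms_by_membrane(list(mk_swarm(0, 1)), slab),
               "eliminates all swarms")
})

test_that("restraint and membrane filters commute", {
  shell <- sphere_shell(150, radius = 20)
  swarms <- generate_swarms(shell)
  pole <- shell$atoms$resno[which.max(shell$atoms$z)]
  rs <- parse_restraints(sprintf("A.%d", pole))
  slab <- structure(list(beads = cbind(0, 0, c(-8, 8)), z_min = -8,
                         z_max = 8), class = "MembraneModel")
  a <- filter_swarms_by_membrane(
    filter_swarms_by_restraints(swarms, shell, rs), slab)
  b <- filter_swarms_by_restraints(
    filter_swarms_by_membrane(swarms, slab), shell, rs)
  expect_identical(a, b)
})

test_that("glowworm initialization is seeded and restraint-oriented", {
  shell <- sphere_shell(100, radius = 16)
  lig <- toy_chain(5, chain = "B")
  swarm <- generate_swarms(shell)[[1]]
  s1 <- init_glowworms(swarm, lig, n_glowworms = 25, seed = 9)
  s2 <- init_glowworms(swarm, lig, n_glowworms = 25, seed = 9)
  expect_identical(s1, s2)
  expect_length(s1$glowworms, 25)
  expect_true(all(vapply(s1$glowworms, `[[`, numeric(1), "luciferin") == 5))
  tr <- t(vapply(s1$glowworms, function(g) g$pose$translation, numeric(3)))
  expect_true(all(sqrt(rowSums(sweep(tr, 2, swarm$center)^2)) <= swarm$radius))
  expect_error(init_glowworms(swarm, lig, n_glowworms = 1), "at least 2")

  # restraint orientation: with zero jitter the restrained ligand residue
  # must face the receptor restraint residue
  pole <- shell$atoms$resno[which.max(shell$atoms$z)]
  rs <- parse_restraints(sprintf("A.%d", pole), "B.5")
  top <- filter_swarms_by_restraints(generate_swarms(shell), shell, rs)[[1]]
  or <- init_glowworms(top, lig, n_glowworms = 20, restraints = rs,
                       receptor = shell, seed = 4, jitter_deg = 0)
  r_cen <- colMeans(as.matrix(shell$atoms[shell$atoms$resno == pole,
                                          c("x", "y", "z")]))
  body_cen <- centroid(lig)
  l_idx <- lig$atoms$resno == 5
  for (g in or$glowworms) {
    posed <- apply_pose(lig, g$pose)
    l_cen <- colMeans(posed[l_idx, , drop = FALSE])
    u <- unit(r_cen - g$pose$translation)
    v <- unit(l_cen - g$pose$translation)
    expect_gt(sum(u * v), 0.99)
  }
  expect_error(init_glowworms(top, lig, n_glowworms = 5,
                              restraints = parse_restraints("A.1", "B.99"),
                              receptor = shell, seed = 1),
               "unknown restraint residue")
})

test_that("swarm state files round-trip poses", {
  shell <- sphere_shell(60, radius = 15)
  lig <- toy_chain(4, chain = "B")
  swarm <- init_glowworms(generate_swarms(shell)[[1]], lig,
                          n_glowworms = 10, seed = 2, n_modes = 3)
  f <- withr::local_tempfile(fileext = ".txt")
  write_swarm_state(swarm, f)
  back <- read_swarm_state(f, n_modes = 3)
  expect_length(back, 10)
  for (i in 1:10) {
    expect_equal(back[[i]]$pose$translation,
                 swarm$glowworms[[i]]$pose$translation, tolerance = 1e-6)
    expect_equal(back[[i]]$pose$rotation,
                 swarm$glowworms[[i]]$pose$rotation, tolerance = 1e-6)
    expect_equal(back[[i]]$pose$mode_amplitudes,
                 swarm$glowworms[[i]]$pose$mode_amplitudes, tolerance = 1e-6)
  }
})
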