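test_that("ligand_rmsd is the plain per-atom deviation without fitting", {
  a <- matrix(c(0, 0, 0, 0, 0, 2), 2, 3, byrow = TRUE)
  b <- matrix(0, 2, 3)
  expect_equal(ligand_rmsd(a, a), 0)
  expect_equal(ligand_rmsd(a, b), sqrt(2))
  shifted <- sweep(a, 2, c(3, 4, 0), "+")
  expect_equal(ligand_rmsd(a, shifted), 5)
  expect_error(ligand_rmsd(a, b[1, , drop = FALSE]), "mismatch")
})

mk_swarm_with_poses <- function(poses, luciferin = NULL) {
  luciferin <- luciferin %||% rev(seq_along(poses))
  structure(list(
    id = 1, center = c(0, 0, 0), radius = 10,
    glowworms = lapply(seq_along(poses), function(i)
      list(id = i, pose = poses[[i]], luciferin = luciferin[i],
           vision_range = 5, score = luciferin[i], f_sat = 1,
           J = luciferin[i]))), class = "Swarm")
}

test_that("BSAS clustering matches a brute-force oracle and is order-stable", {
  lig <- toy_chain(4, chain = "B")
  cen <- centroid(lig)
  same <- mk_swarm_with_poses(replicate(4, Pose(cen), simplify = FALSE))
  expect_equal(max(cluster_swarm(same, lig)), 1)

  apart <- mk_swarm_with_poses(list(Pose(cen), Pose(cen + c(10, 0, 0)),
                                    Pose(cen + c(0, 10, 0))))
  expect_equal(sort(unique(cluster_swarm(apart, lig))), 1:3)

  set.seed(14)
  poses <- replicate(10, Pose(cen + rnorm(3, sd = 4),
                              random_unit_quaternion()), simplify = FALSE)
  ell <- runif(10, 1, 9)
  sw <- mk_swarm_with_poses(poses, ell)
  got <- cluster_swarm(sw, lig, rmsd_cutoff = 4)

  # independent brute-force BSAS in the visit order of the rule
  anchors <- which(lig$atoms$name == "CA")
  ac <- lapply(poses, function(p) apply_pose(lig, p)[anchors, ])
  visit <- order(-ell, seq_along(poses))
  reps <- integer(0); oracle <- integer(10)
  for (k in visit) {
    d <- vapply(reps, function(r) sqrt(mean(rowSums((ac[[k]] - ac[[r]])^2))),
                numeric(1))
    if (!length(reps) || all(d > 4)) {
      reps <- c(reps, k); oracle[k] <- length(reps)
    } else oracle[k] <- which.min(d)
  }
  expect_equal(as.integer(got), oracle)
  expect_equal(attr(got, "representatives"), reps)

  # input order does not matter given the luciferin visit rule: the
  # partition over glowworm ids and the representative set are unchanged
  perm <- sample(10)
  sw2 <- sw
  sw2$glowworms <- sw$glowworms[perm]
  got2 <- cluster_swarm(sw2, lig, rmsd_cutoff = 4)
  ids2 <- vapply(sw2$glowworms, `[[`, numeric(1), "id")
  expect_setequal(lapply(unname(split(1:10, as.integer(got))), sort),
                  lapply(unname(split(ids2, as.integer(got2))), sort))
  expect_equal(sort(attr(got2, "representatives")),
               sort(attr(got, "representatives")))
})

test_that("ranking sorts by score with deterministic tie-breaking", {
  models <- data.frame(swarm_id = c(2, 1, 3, 1), glowworm_id = c(4, 9, 1, 2),
                       score = c(3, 1, 2, 1), f_sat = 1, cluster_id = 1)
  models$pose <- I(replicate(4, Pose(c(0, 0, 0)), simplify = FALSE))
  ranked <- rank_models(models)
  expect_equal(ranked$score, c(3, 2, 1, 1))
  expect_equal(ranked$rank, 1:4)
  # tie between the two score-1 models broken by (swarm, glowworm)
  expect_equal(ranked$swarm_id[3:4], c(1, 1))
  expect_equal(ranked$glowworm_id[3:4], c(2, 9))
  one <- rank_models(models[1, , drop = FALSE])
  expect_equal(one$rank, 1)
  # every input appears exactly once
  expect_setequal(paste(ranked$swarm_id, ranked$glowworm_id),
                  paste(models$swarm_id, models$glowworm_id))
})

test_that("restraint filtering of models thresholds f_sat and re-ranks", {
  models <- data.frame(swarm_id = 1, glowworm_id = 1:3, score = c(9, 8, 7),
                       f_sat = c(1.0, 0.4, 0.6), cluster_id = 1)
  models$pose <- I(replicate(3, Pose(c(0, 0, 0)), simplify = FALSE))
  models <- rank_models(models)
  rs <- parse_restraints("A.1")
  kept <- filter_models_by_restraints(models, rs, min_fsat = 0.5)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$rank, 1:2)
  expect_equal(kept$f_sat, c(1.0, 0.6))
  expect_identical(filter_models_by_restraints(models, NULL), models)
  expect_warning(out <- filter_models_by_restraints(models, rs, min_fsat = 2),
                 "violate")
  expect_equal(nrow(out), 0)
  # filter-then-rank equals rank-then-filter
  refiltered <- filter_models_by_restraints(models, rs, 0.5)
  direct <- rank_models(models[models$f_sat >= 0.5,
                               setdiff(names(models), "rank")])
  expect_equal(refiltered$glowworm_id, direct$glowworm_id)
})

test_that("reports contain every model and the top-n PDB files", {
  rec <- toy_chain(6, chain = "A")
  lig <- toy_chain(3, chain = "B")
  cen <- centroid(lig)
  n <- 8
  models <- data.frame(swarm_id = 1, glowworm_id = seq_len(n),
                       score = rev(seq_len(n)), f_sat = 1, cluster_id = 1)
  models$pose <- I(lapply(seq_len(n), function(i) Pose(cen + c(0, 0, 6 + i))))
  models <- rank_models(models)
  dir5 <- withr::local_tempdir()
  write_report(models, rec, lig, dir5, top_n = 5)
  tsv <- read.delim(file.path(dir5, "rank.tsv"))
  expect_equal(nrow(tsv), n)
  expect_equal(tsv$rank, 1:n)
  expect_length(list.files(dir5, pattern = "^model_\\d+\\.pdb$"), 5)
  m1 <- read_pdb(file.path(dir5, "model_1.pdb"))
  expect_equal(length(unique(m1$atoms$chain)), 2)
  expect_equal(nrow(m1$atoms), nrow(rec$atoms) + nrow(lig$atoms))

  dir10 <- withr::local_tempdir()
  write_report(models, rec, lig, dir10, top_n = 10)
  expect_length(list.files(dir10, pattern = "^model_\\d+\\.pdb$"), n)

  # truncation below top_n
  small <- models[1:3, ]
  dir3 <- withr::local_tempdir()
  write_report(small, rec, lig, dir3, top_n = 5)
  expect_length(list.files(dir3, pattern = "^model_\\d+\\.pdb$"), 3)
})

test_that("the relaxation hook defaults to the identity and accepts plug-ins", {
  models <- data.frame(swarm_id = 1, glowworm_id = 1, score = 1, f_sat = 1,
                       cluster_id = 1)
  expect_identical(relax_models(models, NULL, NULL), models)
  bump <- function(m, rec, lig) { m$score <- m$score + 1; m }
  expect_equal(relax_models(models, NULL, NULL, relaxer = bump)$score, 2)
})
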