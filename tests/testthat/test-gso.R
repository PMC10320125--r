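test_that("luciferin update follows the decay-plus-gain recurrence", {
  p <- gso_parameters(rho = 0.4, gamma = 0.6)
  expect_equal(luciferin_update(5, 2, p), 4.2)
  expect_equal(luciferin_update(99, 7, gso_parameters(rho = 1, gamma = 1)), 7)
  # fixed point gamma J / rho under constant J, approached monotonically
  ell <- 0; J <- 4
  trail <- numeric(200)
  for (i in 1:200) { ell <- luciferin_update(ell, J, p); trail[i] <- ell }
  expect_equal(ell, p$gamma * J / p$rho, tolerance = 1e-10)
  expect_true(all(diff(trail) >= -1e-12))
})

test_that("find_neighbors matches an exhaustive double-loop oracle", {
  mk <- function(x, ell, rd) list(pose = Pose(c(x, 0, 0)), luciferin = ell,
                                  vision_range = rd)
  pop <- list(mk(0, 5, 3), mk(1, 6, 3), mk(2, 4, 10), mk(2.5, 8, 1),
              mk(-2, 7, 4), mk(10, 9, 5))
  oracle <- function(i) {
    out <- integer(0)
    for (j in seq_along(pop)) {
      if (j == i) next
      d <- sqrt(sum((pop[[i]]$pose$translation - pop[[j]]$pose$translation)^2))
      if (d < pop[[i]]$vision_range && pop[[j]]$luciferin > pop[[i]]$luciferin)
        out <- c(out, j)
    }
    out
  }
  for (i in seq_along(pop)) expect_equal(find_neighbors(i, pop), oracle(i))

  # equal luciferin everywhere: strict inequality empties every neighborhood
  flat <- lapply(1:5, function(i) mk(i, 5, 100))
  for (i in 1:5) expect_length(find_neighbors(i, flat), 0)

  # brighter agent just outside the vision range is excluded
  edge <- list(mk(0, 1, 2), mk(2, 9, 5))
  expect_length(find_neighbors(1, edge), 0)
})

test_that("select_target reproduces the luciferin-excess roulette", {
  mk <- function(ell) list(pose = Pose(c(0, 0, 0)), luciferin = ell,
                           vision_range = 1)
  pop <- list(mk(1), mk(2), mk(3))
  draws <- withr::with_seed(1, replicate(1e5, select_target(1, c(2, 3), pop)))
  expect_equal(mean(draws == 3), 2 / 3, tolerance = 0.01)
  expect_equal(mean(draws == 2), 1 / 3, tolerance = 0.01)
  expect_equal(select_target(1, 2, pop), 2)          # single neighbor
  pop2 <- list(mk(1), mk(4), mk(4))
  d2 <- withr::with_seed(2, replicate(1e5, select_target(1, c(2, 3), pop2)))
  expect_equal(mean(d2 == 2), 0.5, tolerance = 0.01)  # symmetric excess
  expect_error(select_target(1, integer(0), pop), "empty")
})

test_that("movement steps the fixed distance along the pose-space line", {
  p <- gso_parameters(step_size = 0.5)
  a <- Pose(c(0, 0, 0)); b <- Pose(c(3, 4, 0))
  moved <- move_glowworm(a, b, p)
  expect_equal(pose_distance(a, moved), 0.5, tolerance = 1e-12)
  expect_equal(pose_distance(moved, b), 4.5, tolerance = 1e-12)
  # landing exactly on the target when s equals the distance
  land <- move_glowworm(a, b, gso_parameters(step_size = 5))
  expect_equal(land$translation, b$translation, tolerance = 1e-6)
  # s = 0 and zero distance are no-ops
  expect_equal(move_glowworm(a, b, gso_parameters(step_size = 0)), a)
  expect_equal(move_glowworm(a, a, p), a)
})

test_that("vision range adapts toward the desired neighbor count with clamping", {
  p <- gso_parameters(beta = 0.08, n_t = 5)
  expect_equal(update_vision_range(2.0, 7, p, r_s = 3), 1.84)
  expect_equal(update_vision_range(2.9, 0, p, r_s = 3), 3)     # clamp high
  expect_equal(update_vision_range(0.05, 30, p, r_s = 3), 0)   # clamp low
})

# surrogate objective: sum of three Gaussian peaks in the xy-plane,
# exercised through the same Pose machinery as docking
three_peak_objective <- function(pose) {
  xy <- pose$translation[1:2]
  peaks <- list(c(-1.5, 1.5), c(1.5, 1.5), c(0, -1.5))
  S <- sum(vapply(peaks, function(p0)
    exp(-sum((xy - p0)^2) / (2 * 0.4^2)), numeric(1)))
  list(S = S, f_sat = NA_real_, J = S)
}

make_plane_swarm <- function(n, radius = 3, seed = 42) {
  swarm <- structure(list(id = 0, center = c(0, 0, 0), radius = radius,
                          glowworms = NULL), class = "Swarm")
  swarm$glowworms <- withr::with_seed(seed, lapply(seq_len(n), function(i) {
    ang <- runif(1, 0, 2 * pi); r <- radius * sqrt(runif(1))
    list(id = i, pose = Pose(c(r * cos(ang), r * sin(ang), 0)),
         luciferin = 5, vision_range = 2, score = NA_real_,
         f_sat = NA_real_, J = NA_real_)
  }))
  swarm
}

test_that("GSO localizes multiple optima of a multimodal surrogate", {
  swarm <- make_plane_swarm(50)
  t0 <- Sys.time()
  out <- run_swarm(swarm, three_peak_objective,
                   gso_parameters(r_s = 2), seed = 42)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(elapsed, 5)
  pos <- t(vapply(out$glowworms, function(g) g$pose$translation[1:2],
                  numeric(2)))
  peaks <- list(c(-1.5, 1.5), c(1.5, 1.5), c(0, -1.5))
  found <- vapply(peaks, function(p0)
    any(sqrt(colSums((t(pos) - p0)^2)) < 0.5), logical(1))
  expect_gte(sum(found), 2)
  # default parameters run exactly 100 iterations
  expect_length(attr(out, "trace"), 100)
  expect_true(all(diff(attr(out, "best_trace")) >= 0))
})

test_that("a constant objective freezes the population after the first step", {
  swarm <- make_plane_swarm(20)
  flat <- function(pose) list(S = 1, f_sat = NA_real_, J = 1)
  out <- run_swarm(swarm, flat, gso_parameters(steps = 10, r_s = 2), seed = 1)
  before <- t(vapply(swarm$glowworms, function(g) g$pose$translation, numeric(3)))
  after <- t(vapply(out$glowworms, function(g) g$pose$translation, numeric(3)))
  expect_equal(before, after)
})

test_that("GSO trajectories are reproducible and ignore non-finite scores", {
  swarm <- make_plane_swarm(15)
  spiky <- function(pose) {
    if (abs(pose$translation[1]) > 2) return(list(S = NaN, f_sat = NA, J = NaN))
    three_peak_objective(pose)
  }
  p <- gso_parameters(steps = 20, r_s = 2)
  o1 <- run_swarm(swarm, spiky, p, seed = 7)
  o2 <- run_swarm(swarm, spiky, p, seed = 7)
  expect_identical(lapply(o1$glowworms, `[[`, "pose"),
                   lapply(o2$glowworms, `[[`, "pose"))
  # non-finite agents carry -Inf luciferin and never attract anyone
  lucs <- vapply(o1$glowworms, `[[`, numeric(1), "luciferin")
  expect_true(all(is.finite(lucs) | lucs == -Inf))
})
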