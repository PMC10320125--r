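#' Glowworm Swarm Optimization parameters
#'
#' Canonical GSO constants. Each agent (glowworm) carries luciferin that
#' tracks its objective value; brighter agents attract dimmer ones within
#' an adaptive vision range, so the population splits over multiple local
#' optima of the pose-score landscape instead of collapsing onto one.
#'
#' @param rho luciferin decay in `(0, 1]` (default 0.4).
#' @param gamma luciferin enhancement (default 0.6).
#' @param beta vision-range adjustment rate (default 0.08).
#' @param n_t desired neighbor count (default 5).
#' @param step_size movement step in pose-space units (default 0.03;
#'   translations in angstrom, quaternions weighted by `w_q`).
#' @param r_s maximum vision range; `NULL` means twice the swarm radius.
#' @param ell0 initial luciferin (default 5).
#' @param steps optimization steps (default 100).
#' @param w_q quaternion weight of the pose metric (default 10).
#' @param amplitude_bound clamp on normal-mode amplitudes (default 3).
#' @return list of class `"GSOParameters"`.
#' @export
gso_parameters <- function(rho = 0.4, gamma = 0.6, beta = 0.08, n_t = 5,
                           step_size = 0.03, r_s = NULL, ell0 = 5,
                           steps = 100, w_q = 10, amplitude_bound = 3) {
  stopifnot(rho > 0, rho <= 1, gamma > 0, beta > 0, n_t > 0,
            step_size >= 0, ell0 > 0, steps >= 1)
  structure(list(rho = rho, gamma = gamma, beta = beta, n_t = n_t,
                 step_size = step_size, r_s = r_s, ell0 = ell0,
                 steps = as.integer(steps), w_q = w_q,
                 amplitude_bound = amplitude_bound),
            class = "GSOParameters")
}

#' Luciferin update rule
#'
#' `ell <- (1 - rho) * ell + gamma * J`: exponential decay toward the
#' fixed point `gamma * J / rho` for a constant objective `J`.
#'
#' @param ell current luciferin.
#' @param J objective value at the agent's pose.
#' @param params [gso_parameters()].
#' @return updated luciferin.
#' @export
luciferin_update <- function(ell, J, params = gso_parameters()) {
  (1 - params$rho) * ell + params$gamma * J
}

#' Neighbors of a glowworm
#'
#' The neighbor set of agent `i` is every agent strictly brighter than `i`
#' within `i`'s current vision range: `{j != i : d(i, j) < r_d_i and
#' ell_j > ell_i}`.
#'
#' @param i index of the agent in `population`.
#' @param population list of glowworms (`pose`, `luciferin`,
#'   `vision_range`).
#' @param w_q quaternion weight of [pose_distance()].
#' @return integer indices of the neighbors.
#' @export
find_neighbors <- function(i, population, w_q = 10) {
  gi <- population[[i]]
  which(vapply(seq_along(population), function(j) {
    if (j == i) return(FALSE)
    gj <- population[[j]]
    gj$luciferin > gi$luciferin &&
      pose_distance(gi$pose, gj$pose, w_q) < gi$vision_range
  }, logical(1)))
}

#' Probabilistic pursuit target
#'
#' Roulette selection over the neighbor set: neighbor `j` is chosen with
#' probability proportional to its luciferin excess `ell_j - ell_i`. Uses
#' the current RNG stream.
#'
#' @param i index of the agent.
#' @param neighbors integer indices from [find_neighbors()] (non-empty).
#' @param population list of glowworms.
#' @return the chosen neighbor index.
#' @export
select_target <- function(i, neighbors, population) {
  if (!length(neighbors)) stop_gd("empty neighbor set")
  excess <- vapply(neighbors, function(j)
    population[[j]]$luciferin, numeric(1)) - population[[i]]$luciferin
  if (all(excess <= 0)) stop_gd("neighbors must be strictly brighter")
  neighbors[sample.int(length(neighbors), 1, prob = excess)]
}

#' Move a glowworm toward a target
#'
#' Takes a step of length `step_size` from `pose` toward `target_pose`
#' along the straight line in the concatenated pose coordinates of
#' [pose_distance()]; the quaternion is renormalized and
#' sign-canonicalized afterwards and mode amplitudes are clamped to
#' `amplitude_bound`. A zero pose distance is a no-op.
#'
#' @param pose,target_pose [Pose] objects.
#' @param params [gso_parameters()].
#' @return the new [Pose].
#' @export
move_glowworm <- function(pose, target_pose, params = gso_parameters()) {
  d <- pose_distance(pose, target_pose, params$w_q)
  if (d == 0 || params$step_size == 0) return(pose)
  f <- params$step_size / d
  tr <- pose$translation + f * (target_pose$translation - pose$translation)
  q <- pose$rotation + f * (target_pose$rotation - pose$rotation)
  nu <- pose$mode_amplitudes +
    f * (target_pose$mode_amplitudes - pose$mode_amplitudes)
  if (length(nu))
    nu <- pmin(pmax(nu, -params$amplitude_bound), params$amplitude_bound)
  Pose(tr, q, nu)
}

#' Adaptive vision-range update
#'
#' `r_d <- min(r_s, max(0, r_d + beta * (n_t - n_neighbors)))`.
#'
#' @param r_d current vision range.
#' @param n_neighbors neighbor count from the last step.
#' @param params [gso_parameters()].
#' @param r_s maximum vision range.
#' @return updated vision range in `[0, r_s]`.
#' @export
update_vision_range <- function(r_d, n_neighbors, params = gso_parameters(),
                                r_s = params$r_s) {
  min(r_s, max(0, r_d + params$beta * (params$n_t - n_neighbors)))
}

#' Run the GSO loop over one swarm
#'
#' Per step: every agent is scored by `objective` (a closure from
#' [make_objective()] or any function mapping a [Pose] to
#' `list(S, f_sat, J)`), luciferin is updated from `J`, then each agent
#' finds its brighter neighbors, picks a pursuit target by roulette and
#' steps toward it (agents with no brighter neighbor stay put), and
#' finally vision ranges adapt toward the desired neighbor count.
#' Movement uses the luciferin and pose snapshot taken at the start of
#' the phase, so the outcome does not depend on agent order. A non-finite
#' objective marks the agent with `-Inf` luciferin so it is never chosen
#' as a target.
#'
#' Each swarm consumes its own RNG stream seeded with `seed + swarm id`,
#' making swarms independent and their execution order irrelevant.
#'
#' @param swarm a populated `Swarm` (see [init_glowworms()]).
#' @param objective pose objective closure.
#' @param params [gso_parameters()].
#' @param seed base integer seed.
#' @param save_every write a `gso_<step>.out` snapshot every this many
#'   steps (`NULL`: none).
#' @param out_dir directory for snapshots.
#' @return the swarm with final glowworm states, plus attributes
#'   `trace` (per-step maximum raw score) and `best_trace` (its running
#'   maximum, non-decreasing).
#' @export
run_swarm <- function(swarm, objective, params = gso_parameters(), seed = 1,
                      save_every = NULL, out_dir = NULL) {
  if (is.null(swarm$glowworms) || !length(swarm$glowworms))
    stop_gd("swarm has no glowworms; call init_glowworms() first")
  r_s <- params$r_s %||% (2 * swarm$radius)
  pop <- swarm$glowworms
  n <- length(pop)
  for (k in seq_len(n)) pop[[k]]$vision_range <- min(pop[[k]]$vision_range, r_s)
  trace <- numeric(params$steps)
  with_seed(seed + swarm$id, {
    for (step in seq_len(params$steps)) {
      for (k in seq_len(n)) {
        res <- objective(pop[[k]]$pose)
        if (!is.finite(res$J)) { res$J <- -Inf; res$S <- -Inf }
        pop[[k]]$score <- res$S
        pop[[k]]$f_sat <- res$f_sat
        pop[[k]]$J <- res$J
        # an agent that recovers from a non-finite score restarts its
        # luciferin from zero rather than staying dark forever
        ell_prev <- if (is.finite(pop[[k]]$luciferin)) pop[[k]]$luciferin else 0
        pop[[k]]$luciferin <- if (is.finite(res$J))
          luciferin_update(ell_prev, res$J, params) else -Inf
      }
      scores <- vapply(pop, `[[`, numeric(1), "score")
      trace[step] <- if (any(is.finite(scores))) max(scores[is.finite(scores)]) else -Inf
      # movement phase on a snapshot of luciferin and poses
      ell <- vapply(pop, `[[`, numeric(1), "luciferin")
      pm <- pose_matrix(lapply(pop, `[[`, "pose"), params$w_q)
      dmat <- as.matrix(stats::dist(pm))
      poses <- lapply(pop, `[[`, "pose")
      new_poses <- poses
      n_nb <- integer(n)
      for (k in seq_len(n)) {
        nb <- which(dmat[k, ] < pop[[k]]$vision_range & ell > ell[k])
        n_nb[k] <- length(nb)
        if (!length(nb)) next
        excess <- ell[nb] - ell[k]
        if (any(!is.finite(excess))) excess <- rep(1, length(nb))
        tgt <- nb[sample.int(length(nb), 1, prob = excess)]
        new_poses[[k]] <- move_glowworm(poses[[k]], poses[[tgt]], params)
      }
      for (k in seq_len(n)) {
        pop[[k]]$pose <- new_poses[[k]]
        pop[[k]]$vision_range <-
          update_vision_range(pop[[k]]$vision_range, n_nb[k], params, r_s)
      }
      if (!is.null(save_every) && !is.null(out_dir) &&
          (step %% save_every == 0 || step == params$steps)) {
        tmp <- swarm; tmp$glowworms <- pop
        write_swarm_state(tmp, file.path(out_dir, sprintf("gso_%d.out", step)),
                          include_scores = TRUE)
      }
    }
  })
  # final rescoring so reported scores match final poses
  for (k in seq_len(n)) {
    res <- objective(pop[[k]]$pose)
    if (!is.finite(res$J)) { res$J <- -Inf; res$S <- -Inf }
    pop[[k]]$score <- res$S; pop[[k]]$f_sat <- res$f_sat; pop[[k]]$J <- res$J
  }
  swarm$glowworms <- pop
  attr(swarm, "trace") <- trace
  attr(swarm, "best_trace") <- cummax(trace)
  swarm
}
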