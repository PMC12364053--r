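#' Default 22-action priority-adjustment table
#'
#' Eleven tuning targets — the three CTVs individually plus eight OAR
#' groups (brainstem, spinal cord, mandible, larynx+pharynx, both parotids,
#' both cochleae, both submandibular glands, esophagus) — each with an
#' increase and a decrease action, giving the 22-action discrete space.
#' Bilateral organs are grouped so one action moves both weights.
#'
#' @param delta magnitude of every priority increment (default 0.1).
#' @return list of 22 entries, each `list(targets = <character>, delta = <num>)`;
#'   actions are ordered (+, -) per target.
#' @export
default_action_table <- function(delta = 0.1) {
  targets <- list("CTV1", "CTV2", "CTV3",
                  "BRS", "SC", "MAN",
                  c("LAR", "PHY"), c("PARL", "PARR"),
                  c("COCHL", "COCHR"), c("SMGL", "SMGR"),
                  "ESO")
  out <- list()
  for (tg in targets) {
    out[[length(out) + 1]] <- list(targets = tg, delta = +delta)
    out[[length(out) + 1]] <- list(targets = tg, delta = -delta)
  }
  out
}

#' Apply a priority-adjustment action
#'
#' Adds the action's signed increment to the targeted weight(s) and clips
#' the result into `[0, 1]`; all other weights are unchanged. Group actions
#' update every member weight.
#'
#' @param w named priority vector.
#' @param a action index in `1..length(table)`.
#' @param table an action table ([default_action_table()]).
#' @return Updated priority vector.
#' @export
apply_action <- function(w, a, table = default_action_table()) {
  if (!(is.numeric(a) && length(a) == 1 && a >= 1 && a <= length(table)))
    stop("action index out of range: ", a)
  act <- table[[a]]
  w[act$targets] <- pmin(pmax(w[act$targets] + act$delta, 0), 1)
  w
}

#' Priority-tuning planning environment
#'
#' The Markov decision process whose states are flattened DVH matrices,
#' whose 22 discrete actions nudge per-structure planning priorities, whose
#' transition re-optimizes the fluence (warm-started) under the updated
#' priorities, and whose reward is the change in the 150-point plan-quality
#' score. Episodes end at the step horizon or as soon as the terminal score
#' is reached.
#'
#' @param geom a `phantom`.
#' @param dinf its `dose_influence` (precomputed).
#' @param goals a [clinical_goals()] table (defaults from the phantom's
#'   prescriptions).
#' @param action_table a [default_action_table()].
#' @param horizon maximum priority-adjustment steps per episode (default 15).
#' @param w0 initial priorities (default [default_priorities()]).
#' @param terminal_score early-termination score (default the goal table's
#'   point sum, 150).
#' @param gamma discount factor exposed to agents, in `[0, 1)`.
#' @param settings [optimizer_settings()] for the transition engine.
#' @param rx_boost planning-margin factor: the optimization objective
#'   targets `rx_boost` x prescription so that converged plans cover the
#'   clinical prescription; scoring always uses the clinical prescription.
#' @param n_bins,dose_max DVH discretization (see [compute_dvh()]).
#' @return Object of class `planning_env` (a mutable environment) for use
#'   with [env_reset()] and [env_step()].
#' @export
planning_env <- function(geom, dinf,
                         goals = clinical_goals(geom$prescriptions),
                         action_table = default_action_table(),
                         horizon = 15L,
                         w0 = default_priorities(geom),
                         terminal_score = sum(goals$max_points),
                         gamma = 0.99,
                         settings = optimizer_settings(),
                         rx_boost = 1.08,
                         n_bins = 100L, dose_max = NULL) {
  stopifnot(inherits(geom, "phantom"), inherits(dinf, "dose_influence"),
            horizon >= 1, gamma >= 0, gamma < 1)
  e <- new.env(parent = emptyenv())
  e$geom <- geom; e$dinf <- dinf; e$goals <- goals
  e$action_table <- action_table; e$horizon <- as.integer(horizon)
  e$w0 <- w0; e$terminal_score <- terminal_score; e$gamma <- gamma
  e$settings <- settings; e$rx_boost <- rx_boost
  e$n_bins <- as.integer(n_bins)
  e$dose_max <- if (is.null(dose_max)) 1.2 * max(geom$prescriptions) else dose_max
  e$plan_rx <- geom$prescriptions * rx_boost
  e$ready <- FALSE
  class(e) <- "planning_env"
  e
}

#' Number of discrete actions of an environment
#' @param env an environment object.
#' @export
n_actions <- function(env) UseMethod("n_actions")
#' @export
n_actions.planning_env <- function(env) length(env$action_table)

#' Dimension of the flattened state vector
#' @param env an environment object.
#' @export
state_dim <- function(env) UseMethod("state_dim")
#' @export
state_dim.planning_env <- function(env) length(env$geom$masks) * env$n_bins

#' Flatten a DVH state into the agent's observation vector
#' @param s a `dvh_state`.
#' @return Numeric vector (structures x bins, row-major by structure).
#' @export
flatten_state <- function(s) as.vector(t(s$matrix))

#' Reset an environment
#'
#' Restores the initial priorities, optimizes the initial plan, and returns
#' its DVH state. Deterministic for a given anatomy: the transition engine
#' contains no randomness (`seed` is recorded for bookkeeping only).
#'
#' @param env a `planning_env`; @param seed optional integer, recorded in
#'   the episode trace.
#' @return The initial `dvh_state`.
#' @export
env_reset <- function(env, seed = NULL) UseMethod("env_reset")

#' @export
env_reset.planning_env <- function(env, seed = NULL) {
  env$w <- env$w0
  opt <- optimize_plan(env$dinf, env$w, env$plan_rx, env$settings, x0 = NULL)
  env$x <- opt$x
  env$dose <- compute_dose(env$dinf, env$x)
  env$score <- score_plan(env$dose, env$geom, env$goals)
  env$state <- compute_dvh(env$dose, env$geom, env$n_bins, env$dose_max)
  env$step_count <- 0L
  env$done <- FALSE
  env$initial_score <- env$score$total
  env$best <- list(score = env$score$total, w = env$w, x = env$x, step = 0L)
  env$trace <- list(list(step = 0L, action = NA_integer_, reward = NA_real_,
                         score = env$score$total, w = env$w, seed = seed))
  env$ready <- TRUE
  env$state
}

#' Take one priority-adjustment step
#'
#' Applies the action to the priorities (clipped into `[0, 1]`),
#' re-optimizes the plan warm-started from the current fluence, rescores,
#' and returns the transition. Reward is exactly the score difference; the
#' episode is done when the horizon is exhausted or the terminal score
#' reached. The best-scoring intermediate plan is tracked.
#'
#' @param env a `planning_env`; @param a action index (1-based).
#' @return A list of class `transition`: `state`, `action`, `reward`,
#'   `next_state`, `done`, `info` (priorities before/after, plan score,
#'   optimizer report).
#' @export
env_step <- function(env, a) UseMethod("env_step")

#' @export
env_step.planning_env <- function(env, a) {
  if (!isTRUE(env$ready)) stop("environment must be reset before stepping")
  if (isTRUE(env$done)) stop("episode is done; reset the environment")
  w_before <- env$w
  state <- env$state
  score_before <- env$score$total

  env$w <- apply_action(env$w, a, env$action_table)
  x0 <- if (env$settings$warm_start) env$x else NULL
  opt <- optimize_plan(env$dinf, env$w, env$plan_rx, env$settings, x0 = x0)
  env$x <- opt$x
  env$dose <- compute_dose(env$dinf, env$x)
  env$score <- score_plan(env$dose, env$geom, env$goals)
  env$state <- compute_dvh(env$dose, env$geom, env$n_bins, env$dose_max)
  env$step_count <- env$step_count + 1L

  reward <- env$score$total - score_before
  env$done <- env$step_count >= env$horizon ||
    env$score$total >= env$terminal_score
  if (env$score$total > env$best$score)
    env$best <- list(score = env$score$total, w = env$w, x = env$x,
                     step = env$step_count)
  env$trace[[length(env$trace) + 1]] <-
    list(step = env$step_count, action = as.integer(a), reward = reward,
         score = env$score$total, w = env$w)

  out <- list(state = state, action = as.integer(a), reward = reward,
              next_state = env$state, done = env$done,
              info = list(w_before = w_before, w_after = env$w,
                          score = env$score$total,
                          optimizer = opt$report))
  class(out) <- "transition"
  out
}

#' Episode trace as a data.frame
#'
#' @param env a `planning_env` after at least one reset.
#' @return data.frame with one row per step (step 0 = initial plan):
#'   action, reward, plan score, and one column per structure priority.
#' @export
episode_trace <- function(env) {
  stopifnot(isTRUE(env$ready))
  rows <- lapply(env$trace, function(t) {
    data.frame(step = t$step, action = t$action, reward = t$reward,
               score = t$score, t(t$w), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.planning_env <- function(x, ...) {
  cat("Priority-tuning planning environment\n")
  cat(sprintf("  %d actions, horizon %d, terminal score %.1f, gamma %.2f\n",
              n_actions(x), x$horizon, x$terminal_score, x$gamma))
  cat(sprintf("  state: %d structures x %d bins (%d-dim flattened)\n",
              length(x$geom$masks), x$n_bins, state_dim(x)))
  if (isTRUE(x$ready))
    cat(sprintf("  current score %.2f after %d step(s)\n",
                x$score$total, x$step_count))
  invisible(x)
}
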