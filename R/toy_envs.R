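# Tiny fully-known environments used to sanity-check the learners against
# exact solutions (exhaustive search / value iteration). They follow the same
# reset/step contract as the planning environment.

#' Deterministic multi-armed bandit environment
#'
#' One-step episodes: action k yields reward `rewards[k]` and terminates.
#' The optimal policy is known exactly, making this the smallest possible
#' check that an agent's update rule improves its policy.
#'
#' @param rewards numeric vector of per-arm rewards.
#' @return Object of class `bandit_env`.
#' @export
bandit_env <- function(rewards = c(0, 1)) {
  e <- new.env(parent = emptyenv())
  e$rewards <- rewards
  e$state <- 1
  class(e) <- "bandit_env"
  e
}

#' @export
n_actions.bandit_env <- function(env) length(env$rewards)
#' @export
state_dim.bandit_env <- function(env) 1L
#' @export
env_reset.bandit_env <- function(env, seed = NULL) { env$done <- FALSE; 1 }
#' @export
env_step.bandit_env <- function(env, a) {
  if (isTRUE(env$done)) stop("episode is done")
  env$done <- TRUE
  list(state = 1, action = a, reward = env$rewards[a], next_state = 1,
       done = TRUE, info = list())
}

#' Deterministic chain MDP environment
#'
#' A finite deterministic MDP over `n_states` states with 2 actions given by
#' explicit transition and reward tables; episodes run for `horizon` steps
#' from state 1. States are observed one-hot. The optimal return is
#' computable by exhaustive search over action sequences
#' ([optimal_return()]), giving an exact oracle for value-based learners.
#'
#' @param transitions integer matrix `n_states x n_actions`, next state.
#' @param rewards numeric matrix `n_states x n_actions`.
#' @param horizon episode length.
#' @return Object of class `chain_mdp_env`.
#' @export
chain_mdp_env <- function(transitions, rewards, horizon = 4L) {
  stopifnot(all(dim(transitions) == dim(rewards)))
  e <- new.env(parent = emptyenv())
  e$transitions <- transitions; e$rewards <- rewards
  e$horizon <- as.integer(horizon)
  e$n_states <- nrow(transitions)
  class(e) <- "chain_mdp_env"
  e
}

one_hot <- function(i, n) { v <- numeric(n); v[i] <- 1; v }

#' @export
n_actions.chain_mdp_env <- function(env) ncol(env$transitions)
#' @export
state_dim.chain_mdp_env <- function(env) env$n_states
#' @export
env_reset.chain_mdp_env <- function(env, seed = NULL) {
  env$s <- 1L; env$t <- 0L; env$done <- FALSE
  one_hot(1L, env$n_states)
}
#' @export
env_step.chain_mdp_env <- function(env, a) {
  if (isTRUE(env$done)) stop("episode is done")
  r <- env$rewards[env$s, a]
  s_was <- env$s
  env$s <- env$transitions[env$s, a]
  env$t <- env$t + 1L
  env$done <- env$t >= env$horizon
  list(state = one_hot(s_was, env$n_states), action = a, reward = r,
       next_state = one_hot(env$s, env$n_states), done = env$done,
       info = list())
}

#' Optimal undiscounted return of a deterministic finite MDP
#'
#' Exhaustive search over all action sequences of length `horizon` from
#' state 1 — the brute-force oracle for [chain_mdp_env()].
#'
#' @param env a `chain_mdp_env`.
#' @return list with `return` (best total reward) and `actions`.
#' @export
optimal_return <- function(env) {
  K <- n_actions(env)
  best <- -Inf; best_seq <- NULL
  recurse <- function(s, t, acc, seq) {
    if (t == env$horizon) {
      if (acc > best) { best <<- acc; best_seq <<- seq }
      return(invisible())
    }
    for (a in seq_len(K))
      recurse(env$transitions[s, a], t + 1L, acc + env$rewards[s, a], c(seq, a))
  }
  recurse(1L, 0L, 0, integer(0))
  list(return = best, actions = best_seq)
}
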