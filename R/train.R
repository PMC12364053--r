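#' Train an RL agent on one or more planning environments
#'
#' The episodic training loop: for each episode the environment is reset,
#' the agent acts for up to the environment horizon (terminating early at
#' the terminal score), and its update rule runs online (DQN: per-step
#' replay minibatches with a periodically synced target network; PPO:
#' clipped-surrogate updates on fixed-length rollouts with GAE). When a list
#' of environments is given — e.g. an original anatomy plus progression and
#' regression variants — episodes cycle over them round-robin, the
#' patient-specific training scheme; a pool of different phantoms gives the
#' population-trained baseline.
#'
#' Fully reproducible for a given config seed. With `episodes = 0` the
#' initialized, untrained agent is returned with an empty log.
#'
#' @param config a [dqn_config()] or [ppo_config()].
#' @param env a `planning_env` (or any object supporting [env_reset()],
#'   [env_step()], [n_actions()], [state_dim()]), or a list of them.
#' @param episodes number of training episodes.
#' @param verbose print per-episode progress.
#' @return A trained agent of class `dqn_agent` or `ppo_agent` (both
#'   `rl_agent`), with the network parameters, config, and a per-episode log
#'   (data.frame: episode, env index, steps, initial/final/best plan score,
#'   total reward).
#' @export
train_agent <- function(config, env, episodes = 100L, verbose = FALSE) {
  UseMethod("train_agent")
}

envs_as_list <- function(env) {
  if (inherits(env, "planning_env") || !is.list(env)) list(env) else env
}

empty_log <- function() {
  data.frame(episode = integer(), env = integer(), steps = integer(),
             initial_score = numeric(), final_score = numeric(),
             best_score = numeric(), total_reward = numeric())
}

log_row <- function(episode, ienv, steps, initial, final, best, total_reward) {
  data.frame(episode = episode, env = ienv, steps = steps,
             initial_score = initial, final_score = final,
             best_score = best, total_reward = total_reward)
}

# Final/best plan score of an episode; planning envs expose scores, toy envs
# fall back to accumulated reward.
episode_scores <- function(e, total_reward) {
  if (!is.null(e$score)) list(initial = e$initial_score,
                              final = e$score$total, best = e$best$score)
  else list(initial = 0, final = total_reward, best = total_reward)
}

#' @rdname train_agent
#' @export
train_agent.dqn_config <- function(config, env, episodes = 100L, verbose = FALSE) {
  envs <- envs_as_list(env)
  restore <- local_rng(config$seed); on.exit(restore(), add = TRUE)
  dim <- state_dim(envs[[1]])
  K <- n_actions(envs[[1]])
  net <- mlp_init(dim, config$hidden_sizes, K)
  target <- net
  adam <- adam_init(net)
  buf <- replay_init(config$replay_capacity, dim)
  log <- empty_log()
  gstep <- 0L; usteps <- 0L
  if (episodes >= 1) for (ep in seq_len(episodes)) {
    ienv <- ((ep - 1L) %% length(envs)) + 1L
    e <- envs[[ienv]]
    s <- as_state_vector(env_reset(e))
    done <- FALSE
    total_r <- 0; steps <- 0L
    while (!done) {
      gstep <- gstep + 1L
      epsv <- epsilon_at(config, gstep)
      a <- if (stats::runif(1) < epsv) sample.int(K, 1)
           else which.max(q_values(s, net))
      tr <- env_step(e, a)
      s2 <- as_state_vector(tr$next_state)
      replay_add(buf, s, a, tr$reward, s2, tr$done)
      total_r <- total_r + tr$reward; steps <- steps + 1L
      s <- s2; done <- tr$done
      if (buf$size >= config$batch_size) {
        upd <- dqn_update(replay_sample(buf, config$batch_size),
                          net, target, adam, config)
        net <- upd$net; adam <- upd$adam
        usteps <- usteps + 1L
        if (usteps %% config$target_sync_interval == 0L) target <- net
      }
    }
    sc <- episode_scores(e, total_r)
    log <- rbind(log, log_row(ep, ienv, steps, sc$initial, sc$final, sc$best, total_r))
    if (verbose)
      message(sprintf("episode %3d [env %d]: final %.2f best %.2f (eps %.2f)",
                      ep, ienv, sc$final, sc$best, epsv))
  }
  out <- list(net = net, target_net = target, config = config, log = log,
              n_actions = K, state_dim = dim)
  class(out) <- c("dqn_agent", "rl_agent")
  out
}

#' @rdname train_agent
#' @export
train_agent.ppo_config <- function(config, env, episodes = 100L, verbose = FALSE) {
  envs <- envs_as_list(env)
  restore <- local_rng(config$seed); on.exit(restore(), add = TRUE)
  dim <- state_dim(envs[[1]])
  K <- n_actions(envs[[1]])
  params <- list(policy = mlp_init(dim, config$hidden_sizes, K),
                 value = mlp_init(dim, config$hidden_sizes, 1))
  adams <- list(policy = adam_init(params$policy),
                value = adam_init(params$value))
  log <- empty_log()

  ep <- 0L
  e <- NULL; s <- NULL; done <- TRUE
  total_r <- 0; steps <- 0L; ienv <- 0L

  # rollout accumulators
  new_roll <- function() list(S = NULL, A = integer(0), R = numeric(0),
                              DONE = logical(0), V = numeric(0),
                              LOGP = numeric(0))
  roll <- new_roll()

  while (ep < episodes || (!done && episodes > 0)) {
    if (done) {
      if (ep >= episodes) break
      ep <- ep + 1L
      ienv <- ((ep - 1L) %% length(envs)) + 1L
      e <- envs[[ienv]]
      s <- as_state_vector(env_reset(e))
      done <- FALSE; total_r <- 0; steps <- 0L
    }
    logp_all <- policy_logp(params$policy, matrix(s, nrow = 1))[1, ]
    a <- sample.int(K, 1, prob = exp(logp_all))
    v <- mlp_forward(params$value, matrix(s, nrow = 1))$out[1, 1]
    tr <- env_step(e, a)
    roll$S <- rbind(roll$S, s)
    roll$A <- c(roll$A, a); roll$R <- c(roll$R, tr$reward)
    roll$DONE <- c(roll$DONE, tr$done)
    roll$V <- c(roll$V, v); roll$LOGP <- c(roll$LOGP, logp_all[a])
    total_r <- total_r + tr$reward; steps <- steps + 1L
    s <- as_state_vector(tr$next_state); done <- tr$done

    if (done) {
      sc <- episode_scores(e, total_r)
      log <- rbind(log, log_row(ep, ienv, steps, sc$initial, sc$final,
                                sc$best, total_r))
      if (verbose)
        message(sprintf("episode %3d [env %d]: final %.2f best %.2f",
                        ep, ienv, sc$final, sc$best))
    }

    if (length(roll$A) >= config$rollout_length) {
      bootstrap <- if (done) 0
                   else mlp_forward(params$value, matrix(s, nrow = 1))$out[1, 1]
      values <- c(roll$V, bootstrap)
      adv <- gae(roll$R, values, roll$DONE, config$gamma, config$gae_lambda)
      ret <- discounted_returns(roll$R, roll$DONE, config$gamma,
                                bootstrap = bootstrap)
      if (config$normalize_advantages && length(adv) > 1)
        adv <- (adv - mean(adv)) / (stats::sd(adv) + 1e-8)
      n <- length(roll$A)
      for (epoch in seq_len(config$epochs_per_update)) {
        ord <- sample.int(n)
        for (start in seq(1, n, by = config$minibatch_size)) {
          idx <- ord[start:min(start + config$minibatch_size - 1L, n)]
          mb <- list(S = roll$S[idx, , drop = FALSE], A = roll$A[idx],
                     ADV = adv[idx], RET = ret[idx],
                     LOGP_OLD = roll$LOGP[idx])
          upd <- ppo_update(mb, params, adams, config)
          params <- upd$params; adams <- upd$adams
        }
      }
      roll <- new_roll()
    }
  }
  out <- list(net = params$policy, value_net = params$value,
              config = config, log = log, n_actions = K, state_dim = dim)
  class(out) <- c("ppo_agent", "rl_agent")
  out
}

#' Greedy action of a trained agent
#'
#' @param object a trained `rl_agent`.
#' @param state an environment state.
#' @param type `"action"` (greedy action index), `"values"` (Q values or
#'   action probabilities).
#' @param ... unused.
#' @return Integer action or numeric vector, per `type`.
#' @export
predict.dqn_agent <- function(object, state, type = c("action", "values"), ...) {
  type <- match.arg(type)
  q <- q_values(state, object$net)
  if (type == "action") which.max(q) else q
}

#' @rdname predict.dqn_agent
#' @export
predict.ppo_agent <- function(object, state, type = c("action", "values"), ...) {
  type <- match.arg(type)
  p <- exp(policy_logp(object$net, matrix(as_state_vector(state), nrow = 1))[1, ])
  if (type == "action") which.max(p) else p
}

#' Evaluate a trained agent on an environment
#'
#' Runs one greedy (deterministic) episode and reports the best-scoring
#' intermediate plan as well as the final one; the evaluation horizon may
#' exceed the training horizon.
#'
#' @param agent a trained `rl_agent`.
#' @param env a `planning_env`.
#' @param horizon evaluation steps (default the environment's horizon).
#' @return list with `initial_score`, `best_score`, `best_step`,
#'   `final_score`, `actions`, `scores` (per-step trajectory), `best_w`
#'   (priorities of the best plan), and the episode `trace` data.frame.
#' @export
evaluate_agent <- function(agent, env, horizon = NULL) {
  stopifnot(inherits(agent, "rl_agent"))
  old_h <- env$horizon
  if (!is.null(horizon)) env$horizon <- as.integer(horizon)
  on.exit(env$horizon <- old_h, add = TRUE)
  s <- env_reset(env)
  scores <- env$initial_score
  actions <- integer(0)
  done <- FALSE
  while (!done) {
    a <- predict(agent, s)
    tr <- env_step(env, a)
    actions <- c(actions, a)
    scores <- c(scores, env$score$total)
    s <- tr$next_state; done <- tr$done
  }
  list(initial_score = env$initial_score, best_score = env$best$score,
       best_step = env$best$step, final_score = env$score$total,
       actions = actions, scores = scores, best_w = env$best$w,
       trace = episode_trace(env))
}

#' @export
print.rl_agent <- function(x, ...) {
  algo <- if (inherits(x, "dqn_agent")) "DQN" else "PPO"
  cat(sprintf("%s agent: %d-dim state -> %d actions, hidden [%s]\n", algo,
              x$state_dim, x$n_actions,
              paste(x$config$hidden_sizes, collapse = ", ")))
  if (nrow(x$log) > 0)
    cat(sprintf("  trained %d episodes; last-10 mean best score %.2f\n",
                nrow(x$log), mean(utils::tail(x$log$best_score, 10))))
  else cat("  untrained (no episodes)\n")
  invisible(x)
}

#' @export
summary.rl_agent <- function(object, ...) {
  print(object)
  if (nrow(object$log) > 0) {
    cat("Per-episode best plan score:\n")
    print(summary(object$log$best_score))
  }
  invisible(object)
}

#' Learning curve of a trained agent
#' @param x an `rl_agent`; @param ... passed to `plot`.
#' @export
plot.rl_agent <- function(x, ...) {
  if (nrow(x$log) == 0) stop("agent has no training log")
  graphics::plot(x$log$episode, x$log$best_score, type = "l",
                 xlab = "Episode", ylab = "Best plan score", ...)
  graphics::lines(x$log$episode, x$log$final_score, lty = 2, col = "grey40")
  graphics::legend("bottomright", c("best", "final"), lty = c(1, 2),
                   col = c("black", "grey40"), cex = 0.8)
  invisible(x)
}
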