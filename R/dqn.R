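#' DQN agent configuration
#'
#' Hyperparameters for the Deep Q-Network learner: a feed-forward value
#' network over flattened DVH states, an experience-replay buffer, a
#' periodically synchronized target network, and an epsilon-greedy
#' exploration schedule. Defaults are conventional desk-scale choices, all
#' overridable.
#'
#' @param hidden_sizes hidden-layer widths of the Q network.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size sampled from the replay buffer.
#' @param replay_capacity maximum stored transitions (>= batch_size).
#' @param target_sync_interval gradient steps between target-network copies.
#' @param epsilon_start,epsilon_end,epsilon_decay_steps linear exploration
#'   schedule: epsilon anneals from start to end over this many env steps.
#' @param gamma discount factor in `[0, 1)`.
#' @param seed RNG seed fixing initialization, exploration and sampling.
#' @return Object of class `dqn_config`.
#' @export
dqn_config <- function(hidden_sizes = c(256, 128),
                       learning_rate = 1e-3,
                       batch_size = 64L,
                       replay_capacity = 10000L,
                       target_sync_interval = 100L,
                       epsilon_start = 1.0, epsilon_end = 0.05,
                       epsilon_decay_steps = 1000L,
                       gamma = 0.99, seed = 1L) {
  stopifnot(gamma >= 0, gamma < 1,
            epsilon_start >= 0, epsilon_start <= 1,
            epsilon_end >= 0, epsilon_end <= 1,
            replay_capacity >= batch_size)
  out <- list(hidden_sizes = hidden_sizes, learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              replay_capacity = as.integer(replay_capacity),
              target_sync_interval = as.integer(target_sync_interval),
              epsilon_start = epsilon_start, epsilon_end = epsilon_end,
              epsilon_decay_steps = as.integer(epsilon_decay_steps),
              gamma = gamma, seed = as.integer(seed))
  class(out) <- "dqn_config"
  out
}

# Ring-buffer experience replay. States live in per-slot lists so inserts
# are O(state_dim), not a copy of the whole buffer.
replay_init <- function(capacity, state_dim) {
  capacity <- as.integer(capacity)
  e <- new.env(parent = emptyenv())
  e$S <- vector("list", capacity)
  e$S2 <- vector("list", capacity)
  e$A <- integer(capacity); e$R <- numeric(capacity); e$DONE <- logical(capacity)
  e$capacity <- capacity; e$ptr <- 0L; e$size <- 0L
  e$state_dim <- state_dim
  e
}

replay_add <- function(buf, s, a, r, s2, done) {
  buf$ptr <- (buf$ptr %% buf$capacity) + 1L
  buf$S[[buf$ptr]] <- s; buf$S2[[buf$ptr]] <- s2
  buf$A[buf$ptr] <- a; buf$R[buf$ptr] <- r; buf$DONE[buf$ptr] <- done
  buf$size <- min(buf$size + 1L, buf$capacity)
  invisible(buf)
}

replay_sample <- function(buf, n) {
  idx <- sample.int(buf$size, n, replace = buf$size < n)
  list(S = do.call(rbind, buf$S[idx]), A = buf$A[idx], R = buf$R[idx],
       S2 = do.call(rbind, buf$S2[idx]), DONE = buf$DONE[idx])
}

#' Action values of a state
#'
#' Evaluates the Q network on one state: a pure function of the parameters,
#' returning one finite value per action.
#'
#' @param state an environment state (`dvh_state` or numeric vector).
#' @param net Q-network parameters (as stored in a trained `dqn_agent`'s
#'   `$net`, or from `mlp_init`).
#' @return Numeric vector of length = action-space size.
#' @export
q_values <- function(state, net) {
  x <- as_state_vector(state)
  if (length(x) != net$sizes[1]) stop("state dimension mismatch")
  q <- mlp_forward(net, matrix(x, nrow = 1))$out[1, ]
  if (any(!is.finite(q))) stop("non-finite Q values")
  q
}

#' One-step TD target
#'
#' The Bellman backup target `r + gamma * max_a' Q_target(s', a')`, reducing
#' to `r` on terminal transitions.
#'
#' @param r reward; @param next_state next state; @param done terminal flag;
#' @param target_net target-network parameters; @param gamma discount.
#' @return Scalar target value.
#' @export
td_target <- function(r, next_state, done, target_net, gamma) {
  if (isTRUE(done) || gamma == 0) return(r)
  r + gamma * max(q_values(next_state, target_net))
}

# Batch TD targets (matrix inputs).
td_target_batch <- function(R, S2, DONE, target_net, gamma) {
  Q2 <- mlp_forward(target_net, S2)$out
  R + gamma * (!DONE) * apply(Q2, 1, max)
}

#' DQN temporal-difference loss
#'
#' Mean squared error between the online network's value of each taken
#' action and its target-network Bellman backup, over a batch of
#' transitions. Nonnegative, zero exactly when predictions equal targets.
#'
#' @param batch list with `S` (batch x dim), `A` (actions), `R`, `S2`,
#'   `DONE`.
#' @param net online Q-network parameters; @param target_net target network;
#' @param gamma discount.
#' @return Scalar loss.
#' @export
dqn_loss <- function(batch, net, target_net, gamma) {
  fw <- mlp_forward(net, batch$S)
  qsa <- fw$out[cbind(seq_along(batch$A), batch$A)]
  y <- td_target_batch(batch$R, batch$S2, batch$DONE, target_net, gamma)
  mean((qsa - y)^2)
}

# One gradient step on the TD loss; returns updated net/adam state and loss.
dqn_update <- function(batch, net, target_net, adam, cfg) {
  fw <- mlp_forward(net, batch$S)
  n <- length(batch$A)
  qsa <- fw$out[cbind(seq_len(n), batch$A)]
  y <- td_target_batch(batch$R, batch$S2, batch$DONE, target_net, cfg$gamma)
  dOut <- matrix(0, n, ncol(fw$out))
  dOut[cbind(seq_len(n), batch$A)] <- 2 * (qsa - y) / n
  grads <- mlp_backward(net, fw, dOut)
  st <- adam_step(net, grads, adam, cfg$learning_rate)
  list(net = st$net, adam = st$state, loss = mean((qsa - y)^2))
}

epsilon_at <- function(cfg, step) {
  frac <- min(1, step / max(1, cfg$epsilon_decay_steps))
  cfg$epsilon_start + frac * (cfg$epsilon_end - cfg$epsilon_start)
}
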