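#' PPO agent configuration
#'
#' Hyperparameters for the Proximal Policy Optimization learner: a softmax
#' policy network and a separate value network over flattened DVH states,
#' updated on fixed-length rollouts with the clipped surrogate objective and
#' generalized advantage estimation. Defaults are conventional desk-scale
#' choices, all overridable.
#'
#' @param hidden_sizes hidden-layer widths (policy and value networks).
#' @param learning_rate Adam learning rate (both networks).
#' @param rollout_length env steps collected per policy update.
#' @param epochs_per_update optimization epochs over each rollout.
#' @param minibatch_size minibatch size within an epoch.
#' @param clip_epsilon surrogate clipping range (> 0).
#' @param gae_lambda GAE bias-variance parameter in `[0, 1]`.
#' @param gamma discount factor in `[0, 1)`.
#' @param value_coef,entropy_coef combined-loss coefficients c1 (value loss)
#'   and c2 (entropy bonus), both >= 0.
#' @param normalize_advantages center/scale advantages within each rollout.
#' @param seed RNG seed.
#' @return Object of class `ppo_config`.
#' @export
ppo_config <- function(hidden_sizes = c(256, 128),
                       learning_rate = 3e-4,
                       rollout_length = 60L,
                       epochs_per_update = 4L,
                       minibatch_size = 32L,
                       clip_epsilon = 0.2,
                       gae_lambda = 0.95,
                       gamma = 0.99,
                       value_coef = 0.5,
                       entropy_coef = 0.01,
                       normalize_advantages = TRUE,
                       seed = 1L) {
  stopifnot(gamma >= 0, gamma < 1, gae_lambda >= 0, gae_lambda <= 1,
            clip_epsilon > 0, value_coef >= 0, entropy_coef >= 0)
  out <- list(hidden_sizes = hidden_sizes, learning_rate = learning_rate,
              rollout_length = as.integer(rollout_length),
              epochs_per_update = as.integer(epochs_per_update),
              minibatch_size = as.integer(minibatch_size),
              clip_epsilon = clip_epsilon, gae_lambda = gae_lambda,
              gamma = gamma, value_coef = value_coef,
              entropy_coef = entropy_coef,
              normalize_advantages = isTRUE(normalize_advantages),
              seed = as.integer(seed))
  class(out) <- "ppo_config"
  out
}

#' Generalized advantage estimation
#'
#' Exponentially weighted sum of one-step TD errors,
#' `A_t = sum_l (gamma*lambda)^l * delta_{t+l}` with
#' `delta_t = r_t + gamma*V(s_{t+1}) - V(s_t)`, truncated at episode ends
#' (`dones`). With `lambda = 0` this is the one-step advantage; with
#' `lambda = 1`, `gamma = 1` and zero values it is the return-to-go.
#'
#' @param rewards length-T reward vector.
#' @param values length-(T+1) state-value vector `V(s_0), ..., V(s_T)`; the
#'   final entry bootstraps the last transition and is ignored past a
#'   terminal step.
#' @param dones length-T logical; `TRUE` where the episode terminated.
#' @param gamma discount in `[0, 1)`; @param lambda GAE parameter in `[0, 1]`.
#' @return Length-T advantage estimates.
#' @export
gae <- function(rewards, values, dones, gamma, lambda) {
  T_ <- length(rewards)
  stopifnot(length(values) == T_ + 1L, length(dones) == T_)
  adv <- numeric(T_)
  acc <- 0
  for (t in rev(seq_len(T_))) {
    nonterm <- !dones[t]
    delta <- rewards[t] + gamma * nonterm * values[t + 1] - values[t]
    acc <- delta + gamma * lambda * nonterm * acc
    adv[t] <- acc
  }
  adv
}

# Discounted return-to-go, truncated at episode ends; bootstraps the value
# of the state following a non-terminal rollout end.
discounted_returns <- function(rewards, dones, gamma, bootstrap = 0) {
  T_ <- length(rewards)
  ret <- numeric(T_)
  acc <- bootstrap
  for (t in rev(seq_len(T_))) {
    if (dones[t]) acc <- 0
    acc <- rewards[t] + gamma * acc
    ret[t] <- acc
  }
  ret
}

policy_logp <- function(policy_net, S) {
  Z <- mlp_forward(policy_net, S)$out
  Z <- Z - apply(Z, 1, max)
  Z - log(rowSums(exp(Z)))
}

#' PPO loss components
#'
#' Evaluates the actor (clipped-surrogate), critic (squared value error
#' against the discounted return), entropy, and the combined loss
#' `-actor + c1 * critic - c2 * entropy` on a rollout.
#'
#' @param rollout list with `S` (T x dim states), `A` (actions), `ADV`
#'   (advantages), `RET` (discounted returns), `LOGP_OLD` (behavior-policy
#'   log-probabilities of the taken actions).
#' @param params list with `policy` and `value` network parameters (the
#'   networks being optimized).
#' @param config a [ppo_config()].
#' @return list with `actor`, `critic`, `entropy`, `combined`.
#' @export
ppo_losses <- function(rollout, params, config) {
  logp_all <- policy_logp(params$policy, rollout$S)
  n <- length(rollout$A)
  logp <- logp_all[cbind(seq_len(n), rollout$A)]
  ratio <- exp(logp - rollout$LOGP_OLD)
  if (any(!is.finite(ratio)))
    stop("non-finite policy ratio; max |logp - logp_old| = ",
         max(abs(logp - rollout$LOGP_OLD)))
  eps <- config$clip_epsilon
  surr1 <- ratio * rollout$ADV
  surr2 <- pmin(pmax(ratio, 1 - eps), 1 + eps) * rollout$ADV
  actor <- mean(pmin(surr1, surr2))
  V <- mlp_forward(params$value, rollout$S)$out[, 1]
  critic <- mean((V - rollout$RET)^2)
  p <- exp(logp_all)
  entropy <- mean(-rowSums(p * logp_all))
  list(actor = actor, critic = critic, entropy = entropy,
       combined = -actor + config$value_coef * critic -
         config$entropy_coef * entropy)
}

# One minibatch gradient step on the combined PPO loss (policy and value
# networks updated jointly). Returns updated params/adam states.
ppo_update <- function(mb, params, adams, config) {
  n <- length(mb$A)
  eps <- config$clip_epsilon

  fw_p <- mlp_forward(params$policy, mb$S)
  Z <- fw_p$out
  Zs <- Z - apply(Z, 1, max)
  logp_all <- Zs - log(rowSums(exp(Zs)))
  p <- exp(logp_all)
  logp <- logp_all[cbind(seq_len(n), mb$A)]
  ratio <- exp(logp - mb$LOGP_OLD)
  if (any(!is.finite(ratio))) stop("non-finite policy ratio in update")

  surr1 <- ratio * mb$ADV
  surr2 <- pmin(pmax(ratio, 1 - eps), 1 + eps) * mb$ADV
  # gradient of the min: the unclipped branch when it is the smaller (or
  # when the clip is inactive, where both branches coincide); zero otherwise
  active <- surr1 <= surr2 | (ratio >= 1 - eps & ratio <= 1 + eps)
  gcoef <- ifelse(active, ratio * mb$ADV, 0)

  H <- -rowSums(p * logp_all)
  # d(-actor)/dlogits and d(-c2*entropy)/dlogits, averaged over the batch
  onehot <- matrix(0, n, ncol(Z))
  onehot[cbind(seq_len(n), mb$A)] <- 1
  dlogits <- (-gcoef / n) * (onehot - p)
  dlogits <- dlogits + (config$entropy_coef / n) * (p * (logp_all + H))
  grads_p <- mlp_backward(params$policy, fw_p, dlogits)

  fw_v <- mlp_forward(params$value, mb$S)
  V <- fw_v$out[, 1]
  dV <- matrix(config$value_coef * 2 * (V - mb$RET) / n, ncol = 1)
  grads_v <- mlp_backward(params$value, fw_v, dV)

  st_p <- adam_step(params$policy, grads_p, adams$policy, config$learning_rate)
  st_v <- adam_step(params$value, grads_v, adams$value, config$learning_rate)
  list(params = list(policy = st_p$net, value = st_v$net),
       adams = list(policy = st_p$state, value = st_v$state))
}
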