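test_that("network gradients match finite differences", {
  set.seed(31)
  net <- replanRL:::mlp_init(6, c(5), 3)
  X <- matrix(rnorm(12), 2, 6)
  Y <- matrix(rnorm(6), 2, 3)
  loss <- function(nn) mean((replanRL:::mlp_forward(nn, X)$out - Y)^2)
  fw <- replanRL:::mlp_forward(net, X)
  grads <- replanRL:::mlp_backward(net, fw, 2 * (fw$out - Y) / length(Y))
  h <- 1e-6
  for (l in 1:2) for (k in 1:3) {
    i <- sample(length(net$W[[l]]), 1)
    np <- net; np$W[[l]][i] <- np$W[[l]][i] + h
    nm <- net; nm$W[[l]][i] <- nm$W[[l]][i] - h
    fd <- (loss(np) - loss(nm)) / (2 * h)
    expect_equal(grads$W[[l]][i], fd, tolerance = 1e-4)
  }
})

test_that("Q values are a pure finite function of the parameters", {
  env <- fixture_env()
  s <- env_reset(env)
  set.seed(32)
  net <- replanRL:::mlp_init(state_dim(env), c(32, 16), n_actions(env))
  q1 <- q_values(s, net)
  expect_length(q1, 22L)
  expect_true(all(is.finite(q1)))
  expect_identical(q1, q_values(s, net))
  expect_error(q_values(rnorm(10), net), "dimension")
})

test_that("TD targets reduce to the reward at gamma = 0 and at terminal steps", {
  set.seed(33)
  net <- replanRL:::mlp_init(3, c(8), 2)
  s2 <- c(0, 1, 0)
  expect_identical(td_target(1.5, s2, FALSE, net, 0), 1.5)
  expect_identical(td_target(-2, s2, TRUE, net, 0.9), -2)
  expect_equal(td_target(1, s2, FALSE, net, 0.9),
               1 + 0.9 * max(q_values(s2, net)))
})

test_that("TD targets match a hand Bellman backup on a 2-state chain", {
  # states one-hot; target net crafted so Q_target(s, a) is known exactly:
  # zero weights, bias = (q per action)
  net <- replanRL:::mlp_init(2, c(4), 2)
  for (l in 1:2) net$W[[l]][] <- 0
  net$b[[1]][] <- 0
  net$b[[2]] <- c(3, 7)
  # Q_target(s', .) = (3, 7) for every s'; backup r + gamma * 7
  expect_equal(td_target(2, c(1, 0), FALSE, net, 0.5), 2 + 0.5 * 7)
  expect_equal(td_target(0, c(0, 1), FALSE, net, 0.9), 0.9 * 7)
})

test_that("DQN loss is the mean squared TD error, zero at the fixed point", {
  set.seed(34)
  net <- replanRL:::mlp_init(3, c(8), 2)
  S <- diag(3)[1:2, ]
  A <- c(1L, 2L)
  q <- replanRL:::mlp_forward(net, S)$out
  # terminal transitions whose rewards equal the current predictions
  batch0 <- list(S = S, A = A, R = q[cbind(1:2, A)], S2 = S, DONE = c(TRUE, TRUE))
  expect_equal(dqn_loss(batch0, net, net, 0.9), 0)
  # single transition: squared TD error
  r <- 2.5
  batch1 <- list(S = S[1, , drop = FALSE], A = 1L, R = r,
                 S2 = S[2, , drop = FALSE], DONE = FALSE)
  y <- r + 0.9 * max(q_values(S[2, ], net))
  expect_equal(dqn_loss(batch1, net, net, 0.9), (q[1, 1] - y)^2)
})

test_that("the replay buffer respects capacity and samples reproducibly", {
  buf <- replanRL:::replay_init(5, 2)
  for (i in 1:12)
    replanRL:::replay_add(buf, c(i, i), 1L, i, c(i, i), FALSE)
  expect_identical(buf$size, 5L)
  # ring overwrite: only the 5 most recent rewards are retained
  expect_setequal(buf$R, 8:12)
  set.seed(40); s1 <- replanRL:::replay_sample(buf, 3)
  set.seed(40); s2 <- replanRL:::replay_sample(buf, 3)
  expect_identical(s1, s2)
})

test_that("GAE matches the brute-force double sum and its closed-form limits", {
  set.seed(35)
  for (i in 1:25) {
    T_ <- sample(3:10, 1)
    r <- rnorm(T_)
    v <- rnorm(T_ + 1)
    dn <- rep(FALSE, T_)
    if (runif(1) < 0.5) dn[sample(T_, 1)] <- TRUE
    dn[T_] <- TRUE
    gamma <- runif(1, 0.8, 0.999)
    lambda <- runif(1)
    expect_equal(gae(r, v, dn, gamma, lambda),
                 gae_double_sum(r, v, dn, gamma, lambda), tolerance = 1e-12)
  }
  # lambda = 0: the one-step advantage
  r <- c(1, 2, 3); v <- c(0.5, 1, 1.5, 2); dn <- c(FALSE, FALSE, TRUE)
  a0 <- gae(r, v, dn, 0.9, 0)
  expect_equal(a0, c(1 + 0.9 * 1 - 0.5, 2 + 0.9 * 1.5 - 1, 3 - 1.5))
  # lambda = 1, gamma = 1, V = 0: undiscounted return-to-go
  expect_equal(gae(r, rep(0, 4), dn, 1, 1), c(6, 5, 3))
})

test_that("PPO losses reduce to their analytic forms at the old parameters", {
  set.seed(36)
  dim <- 4; K <- 22
  policy <- replanRL:::mlp_init(dim, c(8), K)
  value <- replanRL:::mlp_init(dim, c(8), 1)
  S <- matrix(rnorm(3 * dim), 3, dim)
  A <- c(1L, 5L, 22L)
  logp_old <- replanRL:::policy_logp(policy, S)[cbind(1:3, A)]
  roll <- list(S = S, A = A, ADV = c(1, -2, 0.5), RET = c(1, 0, 2),
               LOGP_OLD = logp_old)
  cfg <- ppo_config(clip_epsilon = 0.2, value_coef = 0.5, entropy_coef = 0.01)
  L <- ppo_losses(roll, list(policy = policy, value = value), cfg)
  expect_equal(L$actor, mean(roll$ADV))             # all ratios are 1
  V <- replanRL:::mlp_forward(value, S)$out[, 1]
  expect_equal(L$critic, mean((V - roll$RET)^2))
  expect_equal(L$combined, -L$actor + 0.5 * L$critic - 0.01 * L$entropy)
  # uniform policy (zeroed output layer): entropy = log(22)
  policy0 <- policy
  policy0$W[[2]][] <- 0; policy0$b[[2]][] <- 0
  L0 <- ppo_losses(list(S = S, A = A, ADV = roll$ADV, RET = roll$RET,
                        LOGP_OLD = rep(-log(K), 3)),
                   list(policy = policy0, value = value), cfg)
  expect_equal(L0$entropy, log(22))
})

test_that("the clipped surrogate has zero policy gradient outside the trust region", {
  set.seed(37)
  dim <- 3; K <- 4
  policy <- replanRL:::mlp_init(dim, c(6), K)
  value <- replanRL:::mlp_init(dim, c(6), 1)
  S <- matrix(rnorm(dim), 1, dim)
  A <- 2L
  logp <- replanRL:::policy_logp(policy, S)[1, A]
  # behavior log-prob far below current: ratio >> 1 + eps, advantage favorable
  roll <- list(S = S, A = A, ADV = 3, RET = 0, LOGP_OLD = logp - 2)
  cfg <- ppo_config(clip_epsilon = 0.2, value_coef = 0, entropy_coef = 0)
  lossfun <- function(p) ppo_losses(roll, list(policy = p, value = value), cfg)$combined
  h <- 1e-6
  for (k in 1:3) {
    i <- sample(length(policy$W[[2]]), 1)
    pp <- policy; pp$W[[2]][i] <- pp$W[[2]][i] + h
    pm <- policy; pm$W[[2]][i] <- pm$W[[2]][i] - h
    expect_equal((lossfun(pp) - lossfun(pm)) / (2 * h), 0, tolerance = 1e-7)
  }
})

test_that("the PPO update follows the finite-difference gradient of the combined loss", {
  set.seed(38)
  dim <- 3; K <- 4
  params <- list(policy = replanRL:::mlp_init(dim, c(6), K),
                 value = replanRL:::mlp_init(dim, c(6), 1))
  S <- matrix(rnorm(2 * dim), 2, dim)
  A <- c(2L, 4L)
  logp_old <- replanRL:::policy_logp(params$policy, S)[cbind(1:2, A)] + c(0.05, -0.1)
  mb <- list(S = S, A = A, ADV = c(1.2, -0.7), RET = c(0.5, 1),
             LOGP_OLD = logp_old)
  cfg <- ppo_config(clip_epsilon = 0.5, value_coef = 0.5, entropy_coef = 0.02,
                    learning_rate = 1e-3)
  lossfun <- function(p) ppo_losses(mb, p, cfg)$combined
  adams <- list(policy = replanRL:::adam_init(params$policy),
                value = replanRL:::adam_init(params$value))
  upd <- replanRL:::ppo_update(mb, params, adams, cfg)
  expect_lt(lossfun(upd$params), lossfun(params))   # a small step descends
  h <- 1e-6
  for (k in 1:4) {
    l <- sample(1:2, 1)
    i <- sample(length(params$policy$W[[l]]), 1)
    pp <- params; pp$policy$W[[l]][i] <- pp$policy$W[[l]][i] + h
    pm <- params; pm$policy$W[[l]][i] <- pm$policy$W[[l]][i] - h
    fd <- (lossfun(pp) - lossfun(pm)) / (2 * h)
    # Adam's first step moves parameters opposite the raw gradient sign
    moved <- upd$params$policy$W[[l]][i] - params$policy$W[[l]][i]
    if (abs(fd) > 1e-8) expect_lt(moved * fd, 0)
  }
})

test_that("training determinism, empty training, and bandit convergence hold", {
  be <- bandit_env(c(0, 1))
  cfg <- dqn_config(hidden_sizes = 16, epsilon_decay_steps = 100,
                    batch_size = 8, replay_capacity = 200,
                    target_sync_interval = 10, seed = 3)
  ag0 <- train_agent(cfg, be, episodes = 0)
  expect_identical(nrow(ag0$log), 0L)
  a1 <- train_agent(cfg, be, episodes = 120)
  a2 <- train_agent(cfg, be, episodes = 120)
  expect_identical(a1$log, a2$log)
  expect_identical(a1$net, a2$net)
  expect_identical(predict(a1, 1), 2L)

  pcfg <- ppo_config(hidden_sizes = 16, rollout_length = 16,
                     minibatch_size = 8, learning_rate = 3e-3, seed = 3)
  p1 <- train_agent(pcfg, be, episodes = 250)
  p2 <- train_agent(pcfg, be, episodes = 250)
  expect_identical(p1$log, p2$log)
  expect_identical(predict(p1, 1), 2L)
  expect_gt(predict(p1, 1, type = "values")[2], 0.9)
})

test_that("the target network changes only at sync points", {
  be <- bandit_env(c(0, 1))
  # huge sync interval: the target net keeps its initial parameters
  cfg <- dqn_config(hidden_sizes = 8, batch_size = 4, replay_capacity = 50,
                    target_sync_interval = 100000L, seed = 9)
  ag <- train_agent(cfg, be, episodes = 40)
  restore <- replanRL:::local_rng(cfg$seed)
  net0 <- replanRL:::mlp_init(state_dim(be), cfg$hidden_sizes, n_actions(be))
  restore()
  expect_identical(ag$target_net, net0)
  expect_false(identical(ag$net, net0))
  # sync every step: target always equals the online network afterwards
  cfg2 <- dqn_config(hidden_sizes = 8, batch_size = 4, replay_capacity = 50,
                     target_sync_interval = 1L, seed = 9)
  ag2 <- train_agent(cfg2, be, episodes = 40)
  expect_identical(ag2$target_net, ag2$net)
})

test_that("epsilon-greedy at epsilon = 1 explores uniformly at random", {
  cfg <- dqn_config(epsilon_start = 1, epsilon_end = 1)
  expect_equal(replanRL:::epsilon_at(cfg, 1), 1)
  expect_equal(replanRL:::epsilon_at(cfg, 10000), 1)
  # with epsilon pinned at 1, chosen actions ignore the Q values entirely:
  # both arms of a bandit are pulled despite fixed Q preferences
  be <- bandit_env(c(0, 0))
  ag <- train_agent(dqn_config(hidden_sizes = 4, epsilon_start = 1,
                               epsilon_end = 1, batch_size = 4,
                               replay_capacity = 64, seed = 2),
                    be, episodes = 60)
  expect_identical(nrow(ag$log), 60L)
})

test_that("DQN recovers the optimum of a deterministic 3-state MDP", {
  tr <- matrix(c(2, 3,
                 3, 1,
                 1, 2), nrow = 3, byrow = TRUE)
  rw <- matrix(c(0, 1,
                 2, 0,
                 0, 5), nrow = 3, byrow = TRUE)
  ce <- chain_mdp_env(tr, rw, horizon = 4)
  opt <- optimal_return(ce)
  expect_identical(opt$return, 13)                 # exhaustive-search oracle
  ag <- train_agent(dqn_config(hidden_sizes = 32, epsilon_decay_steps = 600,
                               batch_size = 16, replay_capacity = 1000,
                               target_sync_interval = 25, seed = 5),
                    ce, episodes = 300)
  s <- env_reset(ce); total <- 0
  for (i in 1:4) {
    st <- env_step(ce, predict(ag, s))
    total <- total + st$reward
    s <- st$next_state
  }
  expect_identical(total, opt$return)
})
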