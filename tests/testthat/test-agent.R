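# a q_network whose online output is a fixed vector: zero weights, bias q
fixed_q_net <- function(q_online, q_target = q_online) {
  set.seed(1)
  net <- q_network(network_arch("feedforward"))
  for (nm in c("W1", "W2", "W3")) {
    net$theta[[nm]][] <- 0
    net$theta_target[[nm]][] <- 0
  }
  net$theta$b1[] <- 0; net$theta$b2[] <- 0
  net$theta_target$b1[] <- 0; net$theta_target$b2[] <- 0
  net$theta$b3 <- q_online
  net$theta_target$b3 <- q_target
  net
}

test_that("greedy selection takes the argmax with lowest-index tie-breaking", {
  net <- fixed_q_net(c(0.1, 0.9, 0.2, 0, 0, 0))
  expect_equal(select_action(net, random_obs(), epsilon = 0)$action, 2L)
  tie <- fixed_q_net(rep(0.5, 6))
  expect_equal(select_action(tie, random_obs(), epsilon = 0)$action, 1L)
  expect_error(select_action(net, random_obs(), epsilon = 2), "epsilon")
})

test_that("epsilon = 1 explores uniformly over the six actions", {
  set.seed(50)
  net <- fixed_q_net(c(1, 0, 0, 0, 0, 0))
  obs <- random_obs()
  draws <- vapply(1:6000, function(i)
    select_action(net, obs, epsilon = 1)$action, integer(1))
  counts <- tabulate(draws, 6)
  # binomial 5-sigma band around 1000
  sigma <- sqrt(6000 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - 1000) < 5 * sigma))
})

test_that("bootstrap targets reproduce the hand-evaluated DQN and Double-DQN values", {
  obs <- random_obs()
  tr <- make_transition(obs, 1L, reward = 1, next_obs = random_obs(),
                        done = FALSE)

  net <- fixed_q_net(q_online = c(0, 0, 0, 0, 0, 0),
                     q_target = c(0.5, 2.0, -1, 0, 0, 0))
  expect_equal(compute_targets(list(tr), net, gamma = 0.99, mode = "dqn"),
               1 + 0.99 * 2.0)          # = 2.98

  net2 <- fixed_q_net(q_online = c(1, 3, 2, 0, 0, 0),
                      q_target = c(0.5, 0.2, 0.9, 0, 0, 0))
  expect_equal(compute_targets(list(tr), net2, gamma = 0.99,
                               mode = "double_dqn"),
               1 + 0.99 * 0.2)          # = 1.198

  done_tr <- make_transition(obs, 2L, reward = 11)
  expect_equal(compute_targets(list(done_tr), net2, 0.99, "dqn"), 11)
  expect_equal(compute_targets(list(done_tr), net2, 0.99, "double_dqn"), 11)
  expect_error(compute_targets(list(), net2, 0.99, "dqn"), "nonempty")
})

test_that("double-DQN equals DQN when theta = theta_minus and never exceeds it", {
  set.seed(51)
  for (i in 1:40) {
    net <- q_network(network_arch("feedforward"))
    batch <- lapply(1:8, function(j)
      make_transition(random_obs(), sample.int(6L, 1L), rnorm(1),
                      next_obs = random_obs(), done = FALSE))
    same <- net
    same$theta_target <- same$theta
    expect_equal(compute_targets(batch, same, 0.99, "double_dqn"),
                 compute_targets(batch, same, 0.99, "dqn"))

    # distinct target net: evaluated action cannot beat the target-net max
    net$theta_target <- emgq:::init_theta(net$arch)
    ydd <- compute_targets(batch, net, 0.99, "double_dqn")
    ydq <- compute_targets(batch, net, 0.99, "dqn")
    expect_true(all(ydd <= ydq + 1e-12))
  }
})

test_that("learn_step reduces the loss on a fixed batch and is a no-op at a fixed point", {
  set.seed(52)
  net <- q_network(network_arch("feedforward"))
  cfg <- agent_config(alpha = 1e-3, l2 = 1e-4)
  batch <- lapply(1:32, function(j)
    make_transition(random_obs(), sample.int(6L, 1L), rnorm(1)))
  y <- vapply(batch, `[[`, numeric(1), "reward")

  first <- learn_step(net, batch, y, cfg)
  losses <- numeric(50)
  cur <- first$params
  for (i in 1:50) {
    st <- learn_step(cur, batch, y, cfg)
    cur <- st$params
    losses[i] <- st$loss
  }
  expect_lt(losses[50], first$loss)
  expect_lt(mean(tail(losses, 10)), mean(head(losses, 10)))

  # targets equal to current Q-values, no regularisation: zero gradient
  cfg0 <- agent_config(alpha = 1e-3, l2 = 0)
  X <- t(vapply(batch, `[[`, numeric(40), "obs"))
  qs <- emgq:::mlp_forward(net$theta, X)$Q
  a <- vapply(batch, `[[`, integer(1), "action")
  stat <- learn_step(net, batch, qs[cbind(seq_along(a), a)], cfg0)
  expect_equal(stat$loss, 0)
  for (nm in names(net$theta))
    expect_lt(max(abs(stat$params$theta[[nm]] - net$theta[[nm]])), 1e-8)

  # alpha -> 0 leaves the parameters untouched but still reports the loss
  cfg_tiny <- agent_config(alpha = 1e-300)
  z <- learn_step(net, batch, y, cfg_tiny)
  expect_equal(z$params$theta, net$theta, tolerance = 1e-12)
  expect_gte(z$loss, 0)
})

test_that("target maintenance follows the soft-update schedule", {
  set.seed(53)
  net <- q_network(network_arch("feedforward"))
  net$theta_target <- emgq:::init_theta(net$arch)

  cfg5 <- agent_config(target_update_freq = 5L, smooth_factor = 5e-3)
  before <- net$theta_target
  expect_identical(update_target(net, cfg5, 7L)$theta_target, before)

  after <- update_target(net, cfg5, 10L)$theta_target
  for (nm in names(before))
    expect_equal(after[[nm]],
                 5e-3 * net$theta[[nm]] + (1 - 5e-3) * before[[nm]])

  # tau_s = 1 on an update step is a hard copy
  cfg_hard <- agent_config(target_update_freq = 1L, smooth_factor = 1)
  expect_equal(update_target(net, cfg_hard, 3L)$theta_target, net$theta)

  # scalar convex-combination value: 0.005 * 1 + 0.995 * 0
  one <- net
  one$theta$b3[] <- 1
  one$theta_target$b3[] <- 0
  expect_equal(update_target(one, cfg5, 5L)$theta_target$b3,
               rep(0.005, 6))
})

test_that("replay buffer is FIFO at capacity and samples uniformly", {
  buf <- replay_buffer(2)
  trs <- lapply(1:3, function(i) make_transition(rep(i, 40), 1L, i))
  replay_push_sample(buf, trs, 0L)
  expect_equal(length(buf), 2L)
  held <- sort(vapply(buf$data[1:2], `[[`, numeric(1), "reward"))
  expect_equal(held, c(2, 3))   # the two newest survive

  expect_error(replay_push_sample(replay_buffer(4), list(), 1L), "empty")

  # exhaustive draw is a permutation
  buf64 <- replay_buffer(100)
  replay_push_sample(buf64, lapply(1:64, function(i)
    make_transition(rep(i, 40), 1L, i)), 0L)
  got <- replay_push_sample(buf64, list(), 64L)
  expect_setequal(vapply(got, `[[`, numeric(1), "reward"), 1:64)

  # uniformity: 1e4 draws of k = 1 from 4 elements, 5-sigma band
  set.seed(54)
  buf4 <- replay_buffer(4)
  replay_push_sample(buf4, lapply(1:4, function(i)
    make_transition(rep(i, 40), 1L, i)), 0L)
  draws <- vapply(1:10000, function(i)
    replay_push_sample(buf4, list(), 1L)[[1]]$reward, numeric(1))
  counts <- tabulate(draws, 4)
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) < 5 * sigma))
})
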