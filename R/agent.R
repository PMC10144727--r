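#' Agent hyperparameter configuration
#'
#' Defaults follow the tuned value-network setup: Adam with learning rate
#' `alpha`, discount `gamma = 0.99`, epsilon-greedy exploration starting at
#' 1 with multiplicative decay `1 - 5e-3` per learn step down to
#' `epsilon_min`, soft target-network updates (`theta_minus <-
#' tau_s * theta + (1 - tau_s) * theta_minus` with `tau_s = 5e-3`) every
#' `target_update_freq` learn steps, a FIFO replay buffer of capacity 1e6
#' sampled in minibatches of 64, L2 weight penalty 1e-4, Adam first-moment
#' decay 0.9, and 15 passes over the training set.
#'
#' @param alpha Learning rate (default 3e-4, the best tuned value).
#' @param gamma Discount factor in \[0, 1\].
#' @param epsilon_init,epsilon_decay,epsilon_min Exploration schedule.
#' @param smooth_factor Soft-update coefficient `tau_s`.
#' @param target_update_freq Learn steps between target updates (1, 5, 20
#'   or 50 in the tuning grid).
#' @param buffer_capacity Replay capacity.
#' @param minibatch Minibatch size.
#' @param l2 L2 regularisation factor on weights.
#' @param grad_decay,squared_grad_decay Adam moment decays (beta1, beta2).
#' @param epochs Passes over the user's training set.
#' @param mode `"dqn"` or `"double_dqn"` bootstrap target.
#' @param variant Policy network variant, see [network_arch()].
#' @param seed Integer seed controlling the whole training run.
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(alpha = 3e-4, gamma = 0.99, epsilon_init = 1,
                         epsilon_decay = 5e-3, epsilon_min = 0.01,
                         smooth_factor = 5e-3, target_update_freq = 1L,
                         buffer_capacity = 1e6, minibatch = 64L, l2 = 1e-4,
                         grad_decay = 0.9, squared_grad_decay = 0.999,
                         epochs = 15L, mode = c("dqn", "double_dqn"),
                         variant = c("feedforward", "recurrent"),
                         seed = 1L) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  if (alpha <= 0) stop("alpha must be positive")
  if (target_update_freq < 1L) stop("target_update_freq must be >= 1")
  structure(list(alpha = alpha, gamma = gamma, epsilon_init = epsilon_init,
                 epsilon_decay = epsilon_decay, epsilon_min = epsilon_min,
                 smooth_factor = smooth_factor,
                 target_update_freq = as.integer(target_update_freq),
                 buffer_capacity = buffer_capacity,
                 minibatch = as.integer(minibatch), l2 = l2,
                 grad_decay = grad_decay,
                 squared_grad_decay = squared_grad_decay,
                 epochs = as.integer(epochs), mode = mode,
                 variant = variant, seed = as.integer(seed)),
            class = "agent_config")
}

#' Initialise a Q-network parameter pair
#'
#' Creates seeded online parameters `theta` (Glorot-uniform weights, zero
#' biases) and an identical target copy `theta_minus`, plus fresh Adam
#' state. Uses R's global RNG.
#'
#' @param arch A [network_arch()].
#' @return An object of class `q_network` with fields `theta`,
#'   `theta_target`, `arch`, `opt`.
#' @export
q_network <- function(arch = network_arch()) {
  theta <- init_theta(arch)
  structure(list(theta = theta, theta_target = theta, arch = arch,
                 opt = init_adam(theta)),
            class = "q_network")
}

# Q-values of the online (or target) net for a matrix of observations
q_values <- function(params, X, target = FALSE) {
  th <- if (target) params$theta_target else params$theta
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (params$arch$variant == "feedforward") mlp_forward(th, X)$Q
  else lstm_forward_seq(th, X, params$arch)$Q  # fresh hidden state
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random action index in 1..6;
#' otherwise the argmax of the online network's Q-values for the
#' observation, ties broken towards the lowest index. For the recurrent
#' variant a hidden `state` is threaded through the episode.
#'
#' @param params A [q_network()].
#' @param obs Numeric observation vector (length 40).
#' @param epsilon Exploration probability in \[0, 1\].
#' @param state Recurrent hidden state from the previous call, or `NULL`
#'   at the start of an episode.
#' @return List with `action` (integer in 1..6) and `state`.
#' @export
select_action <- function(params, obs, epsilon = 0, state = NULL) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  if (params$arch$variant == "recurrent") {
    cell <- lstm_cell(params$theta, obs, params$arch, state)
    q <- cell$q
    state <- cell$state
  } else {
    q <- as.numeric(q_values(params, obs))
  }
  a <- if (epsilon > 0 && runif(1) < epsilon) sample.int(N_ACTIONS, 1L)
       else which.max(q)
  list(action = a, state = state, q = q)
}

#' Bootstrap targets for a minibatch
#'
#' For each transition: terminal transitions use `Y = R`; the DQN target is
#' `Y = R + gamma * max_a Q(O', a; theta_minus)`; the Double-DQN target
#' evaluates the online network's greedy action under the target network,
#' `Y = R + gamma * Q(O', argmax_a Q(O', a; theta); theta_minus)`, which
#' decouples action selection from evaluation and so curbs the max
#' operator's overestimation.
#'
#' @param batch List of transitions, each with `obs`, `action`, `reward`,
#'   `next_obs` (or `NULL`), `done`.
#' @param params A [q_network()].
#' @param gamma Discount factor.
#' @param mode `"dqn"` or `"double_dqn"`.
#' @return Numeric vector of targets, one per transition.
#' @export
compute_targets <- function(batch, params, gamma,
                            mode = c("dqn", "double_dqn")) {
  mode <- match.arg(mode)
  if (length(batch) == 0L) stop("batch must be nonempty")
  y <- vapply(batch, `[[`, numeric(1), "reward")
  live <- which(!vapply(batch, `[[`, logical(1), "done"))
  if (length(live) > 0L) {
    Xn <- t(vapply(batch[live], `[[`, numeric(FEATURE_DIM), "next_obs"))
    Qt <- q_values(params, Xn, target = TRUE)
    boot <- if (mode == "dqn") {
      apply(Qt, 1L, max)
    } else {
      Qo <- q_values(params, Xn, target = FALSE)
      sel <- max.col(Qo, ties.method = "first")
      Qt[cbind(seq_along(live), sel)]
    }
    y[live] <- y[live] + gamma * boot
  }
  y
}

#' One gradient step on a minibatch
#'
#' Minimises the mean squared error between `Q(O_t, A_t; theta)` and the
#' fixed targets `Y` (only the taken action's output contributes), with an
#' L2 penalty on the weights, using one Adam step (first-moment decay
#' `grad_decay`, second-moment decay `squared_grad_decay`). The target
#' parameters are untouched.
#'
#' @param params A [q_network()] (feed-forward variant).
#' @param batch List of transitions as in [compute_targets()].
#' @param targets Numeric vector of bootstrap targets.
#' @param config An [agent_config()].
#' @return List with updated `params` and the pre-update `loss`.
#' @export
learn_step <- function(params, batch, targets, config) {
  n <- length(batch)
  if (n == 0L) stop("batch must be nonempty")
  X <- t(vapply(batch, `[[`, numeric(FEATURE_DIM), "obs"))
  a <- vapply(batch, `[[`, integer(1), "action")
  cache <- mlp_forward(params$theta, X)
  qa <- cache$Q[cbind(seq_len(n), a)]
  err <- qa - targets
  loss <- mean(err^2)
  dQ <- matrix(0, n, N_ACTIONS)
  dQ[cbind(seq_len(n), a)] <- 2 * err / n
  grads <- mlp_backward(params$theta, cache, dQ)
  upd <- adam_update(params$theta, grads, params$opt, alpha = config$alpha,
                     beta1 = config$grad_decay,
                     beta2 = config$squared_grad_decay, l2 = config$l2)
  params$theta <- upd$theta
  params$opt <- upd$opt
  list(params = params, loss = loss)
}

# episodic learning step for the recurrent variant: whole ordered episode
# sequences, per-step bootstrap targets, truncated-nowhere BPTT, one Adam
# step over the accumulated episode gradients
learn_step_recurrent <- function(params, episodes, config) {
  total <- lapply(params$theta, function(p) p * 0)
  loss <- 0; nsteps <- 0L
  keep <- 1 - params$arch$dropout
  for (epi in episodes) {
    N <- nrow(epi$obs)
    mask <- (runif(params$arch$lstm_units) < keep) / keep
    cache <- lstm_forward_seq(params$theta, epi$obs, params$arch, mask)
    Qt <- lstm_forward_seq(params$theta_target, epi$obs, params$arch)$Q
    y <- epi$rewards
    if (N > 1L) {
      idx <- seq_len(N - 1L)
      boot <- if (config$mode == "dqn") {
        apply(Qt[-1L, , drop = FALSE], 1L, max)
      } else {
        sel <- max.col(cache$Q[-1L, , drop = FALSE], ties.method = "first")
        Qt[cbind(idx + 1L, sel)]
      }
      y[idx] <- y[idx] + config$gamma * boot
    }
    qa <- cache$Q[cbind(seq_len(N), epi$actions)]
    err <- qa - y
    loss <- loss + sum(err^2); nsteps <- nsteps + N
    dQ <- matrix(0, N, N_ACTIONS)
    dQ[cbind(seq_len(N), epi$actions)] <- 2 * err
    g <- lstm_backward_seq(params$theta, cache, dQ, params$arch)
    for (nm in names(total)) total[[nm]] <- total[[nm]] + g[[nm]]
  }
  for (nm in names(total)) total[[nm]] <- total[[nm]] / nsteps
  upd <- adam_update(params$theta, total, params$opt, alpha = config$alpha,
                     beta1 = config$grad_decay,
                     beta2 = config$squared_grad_decay, l2 = config$l2)
  params$theta <- upd$theta
  params$opt <- upd$opt
  list(params = params, loss = loss / nsteps)
}

#' Soft target-network maintenance
#'
#' Every `target_update_freq` learn steps the target parameters move
#' towards the online parameters by the smooth factor:
#' `theta_minus <- tau_s * theta + (1 - tau_s) * theta_minus`; on other
#' steps they are unchanged.
#'
#' @param params A [q_network()].
#' @param config An [agent_config()].
#' @param learn_step_count Number of learn steps taken so far (>= 1).
#' @return The (possibly updated) `params`.
#' @export
update_target <- function(params, config, learn_step_count) {
  if (learn_step_count %% config$target_update_freq != 0L) return(params)
  ts <- config$smooth_factor
  for (nm in names(params$theta))
    params$theta_target[[nm]] <-
      ts * params$theta[[nm]] + (1 - ts) * params$theta_target[[nm]]
  params
}

## ---- replay buffer -------------------------------------------------------

#' Create a FIFO experience-replay buffer
#'
#' Stores transitions up to `capacity`; once full, the oldest transition is
#' evicted first. The buffer has reference semantics (an environment), so
#' pushes mutate it in place.
#'
#' @param capacity Maximum number of stored transitions.
#' @return An object of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity = 1e6) {
  e <- new.env(parent = emptyenv())
  e$capacity <- as.integer(min(capacity, .Machine$integer.max))
  e$data <- vector("list", 0L)
  e$head <- 0L   # index of the most recent write once at capacity
  e$n <- 0L
  class(e) <- "replay_buffer"
  e
}

#' @export
length.replay_buffer <- function(x) x$n

#' Push new transitions and draw a uniform minibatch
#'
#' Appends the transitions in FIFO order (evicting the oldest at capacity),
#' then samples `min(k, size)` stored transitions uniformly without
#' replacement.
#'
#' @param buffer A [replay_buffer()].
#' @param new List of transitions to push (possibly empty).
#' @param k Requested minibatch size.
#' @return List of sampled transitions.
#' @export
replay_push_sample <- function(buffer, new, k) {
  for (tr in new) {
    if (buffer$n < buffer$capacity) {
      buffer$n <- buffer$n + 1L
      buffer$head <- buffer$n
      buffer$data[[buffer$head]] <- tr
    } else {
      buffer$head <- (buffer$head %% buffer$capacity) + 1L
      buffer$data[[buffer$head]] <- tr
    }
  }
  if (buffer$n == 0L) stop("cannot sample from an empty replay buffer")
  idx <- sample.int(buffer$n, min(k, buffer$n))
  buffer$data[idx]
}

## ---- checkpoints ---------------------------------------------------------

#' Save / load a training checkpoint
#'
#' The checkpoint holds everything needed to resume training
#' bit-compatibly at an epoch boundary: online and target parameters,
#' optimizer moments, epsilon, step counters, replay contents, the agent
#' configuration, the feature scaler, the reward log, and the RNG state.
#'
#' @param model An `emgq_model` (see [train_user_model()]).
#' @param path File path (RDS serialisation).
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the `emgq_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint '", path, "' does not exist")
  model <- readRDS(path)
  if (!inherits(model, "emgq_model")) stop("'", path, "' is not an emgq checkpoint")
  model
}
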