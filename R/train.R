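#' Train a user-specific gesture-recognition agent
#'
#' Fits a Deep Q-Network (or Double-DQN) agent to one user's recordings.
#' The dataset is first orientation-corrected from its "waveOut"
#' synchronization samples; every training recording then becomes an
#' episode. For each of `agent$epochs` passes the training recordings are
#' visited in a seeded random order; at every window the agent picks an
#' epsilon-greedy action, the transition is pushed to the replay buffer,
#' and — once the buffer holds one minibatch — a single gradient step on a
#' uniformly drawn minibatch is taken, the target network is softly
#' updated on its schedule, and epsilon decays. Network inputs are
#' standardised with feature means/sds estimated from the training set's
#' energy-gated windows (stored in the model and reapplied at prediction
#' time). The recurrent variant instead performs one episodic
#' backpropagation-through-time update (a batch of 4 stored episodes)
#' after each finished episode, so its hidden state always starts fresh at
#' an episode boundary.
#'
#' The whole run is driven by `agent$seed`, so identical inputs give
#' bit-identical models and logs.
#'
#' @param user A [user_dataset()] with at least one training sample.
#' @param window A [window_spec()].
#' @param agent An [agent_config()].
#' @param reward A [reward_spec()].
#' @param verbose Print a line per episode.
#' @param resume An `emgq_model` checkpoint to continue from (the run
#'   restarts at the next epoch boundary with identical state, so
#'   training k epochs, checkpointing, and resuming to n epochs equals a
#'   single n-epoch run).
#' @return An object of class `emgq_model` with the trained network, the
#'   feature scaler, the applied channel rotation, the configuration, and
#'   a per-episode log (`episode`, `reward`, `trailing_mean5`, `v0` — the
#'   initial-observation value estimate `max_a Q(O_1, a)` — and
#'   `epsilon`).
#' @seealso [predict.emgq_model()], [evaluate_user()], [save_checkpoint()]
#' @export
train_user_model <- function(user, window = window_spec(),
                             agent = agent_config(), reward = reward_spec(),
                             verbose = FALSE, resume = NULL) {
  if (length(user$training) == 0L)
    stop("training requires at least one training sample")
  if (window$length < 2L) stop("invalid window specification")

  if (is.null(resume)) {
    set.seed(agent$seed)
    sync_e <- channel_energies(user$sync)
    rotation_k <- if (length(user$sync) > 0L) which.max(sync_e) - 1L else 0L
  } else {
    agent <- resume$agent
    window <- resume$window
    reward <- resume$reward
    rotation_k <- resume$rotation_k
  }
  ds <- user
  if (rotation_k > 0L)
    for (fld in c("training", "testing", "sync"))
      ds[[fld]] <- lapply(ds[[fld]], rotate_channels, k = rotation_k)

  # one episode per training recording; features are static, so build once
  episodes <- lapply(ds$training, make_episode, spec = window, reward = reward)
  n_train <- length(episodes)

  if (is.null(resume)) {
    feats <- do.call(rbind, lapply(episodes, `[[`, "obs"))
    act <- unlist(lapply(episodes, `[[`, "active"))
    ref <- if (any(act)) feats[act, , drop = FALSE] else feats
    mu <- colMeans(ref)
    sigma <- apply(ref, 2L, stats::sd)
    sigma[!is.finite(sigma) | sigma < 1e-8] <- 1
    scaler <- list(mean = mu, sd = sigma)
    arch <- network_arch(agent$variant)
    params <- q_network(arch)
    buffer <- replay_buffer(agent$buffer_capacity)
    eps <- agent$epsilon_init
    learn_count <- 0L
    log <- NULL
    epoch_start <- 1L
    episode_idx <- 0L
  } else {
    scaler <- resume$scaler
    params <- resume$params
    buffer <- replay_buffer(agent$buffer_capacity)
    if (length(resume$buffer_data) > 0L) {
      buffer$data <- resume$buffer_data
      buffer$n <- length(resume$buffer_data)
      buffer$head <- buffer$n
    }
    eps <- resume$epsilon
    learn_count <- resume$learn_count
    log <- resume$log
    epoch_start <- resume$epochs_done + 1L
    episode_idx <- resume$epochs_done * n_train
    assign(".Random.seed", resume$rng_state, envir = globalenv())
  }

  scale_mat <- function(X)   # base::sweep: the package exports its own sweep()
    base::sweep(base::sweep(X, 2L, scaler$mean), 2L, scaler$sd, "/")
  scaled <- lapply(episodes, function(e) scale_mat(e$obs))

  rows <- vector("list", max(0L, agent$epochs - epoch_start + 1L) * n_train)
  ri <- 0L
  recent <- if (is.null(log)) numeric(0) else utils::tail(log$reward, 4L)

  if (agent$epochs >= epoch_start) for (epoch in epoch_start:agent$epochs) {
    order_ <- sample.int(n_train)
    for (si in order_) {
      ep <- episodes[[si]]
      S <- scaled[[si]]
      ep$t <- 1L; ep$actions <- character(0)
      obs <- S[1L, ]
      state <- NULL
      v0 <- max(if (agent$variant == "recurrent")
                  lstm_cell(params$theta, obs, params$arch)$q
                else as.numeric(q_values(params, obs)))
      total <- 0
      epi_obs <- S; epi_actions <- integer(ep$N); epi_rewards <- numeric(ep$N)
      repeat {
        sa <- select_action(params, obs, eps, state)
        state <- sa$state
        res <- env_step(ep, sa$action)
        total <- total + res$reward
        t_prev <- ep$t
        ep <- res$episode
        epi_actions[t_prev] <- sa$action
        epi_rewards[t_prev] <- res$reward
        if (agent$variant == "feedforward") {
          trans <- list(obs = obs, action = sa$action, reward = res$reward,
                        next_obs = if (res$done) NULL else S[ep$t, ],
                        done = res$done)
          batch <- replay_push_sample(buffer, list(trans), agent$minibatch)
          if (length(buffer) >= agent$minibatch) {
            y <- compute_targets(batch, params, agent$gamma, agent$mode)
            ls <- learn_step(params, batch, y, agent)
            params <- ls$params
            learn_count <- learn_count + 1L
            params <- update_target(params, agent, learn_count)
            eps <- max(agent$epsilon_min, eps * (1 - agent$epsilon_decay))
          }
        }
        if (res$done) break
        obs <- S[ep$t, ]
      }
      if (agent$variant == "recurrent") {
        epi <- list(obs = epi_obs, actions = epi_actions, rewards = epi_rewards)
        picked <- replay_push_sample(buffer, list(epi), 4L)
        ls <- learn_step_recurrent(params, picked, agent)
        params <- ls$params
        learn_count <- learn_count + 1L
        params <- update_target(params, agent, learn_count)
        eps <- max(agent$epsilon_min, eps * (1 - agent$epsilon_decay))
      }
      episode_idx <- episode_idx + 1L
      recent <- c(utils::tail(recent, 4L), total)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(episode = episode_idx, reward = total,
                               trailing_mean5 = mean(recent), v0 = v0,
                               epsilon = eps)
      if (verbose)
        message(sprintf("episode %d  reward %+.1f  mean5 %+.2f  v0 %.2f  eps %.3f",
                        episode_idx, total, mean(recent), v0, eps))
    }
  }
  log <- rbind(log, do.call(rbind, rows[seq_len(ri)]))

  structure(list(params = params, agent = agent, window = window,
                 reward = reward, scaler = scaler, rotation_k = rotation_k,
                 user_id = user$user_id, log = log,
                 epochs_done = agent$epochs, learn_count = learn_count,
                 epsilon = eps, buffer_data = buffer$data[seq_len(buffer$n)],
                 rng_state = get(".Random.seed", envir = globalenv()),
                 classes = GESTURES),
            class = "emgq_model")
}

#' Greedy prediction for one recording
#'
#' Runs one recording through the trained agent with epsilon = 0 (applying
#' the model's stored channel rotation and feature scaler), post-processes
#' the window labels by majority vote, and scores the outcome.
#'
#' @param model An `emgq_model`.
#' @param sample An [emg_sample()].
#' @return List of class `emgq_prediction`: `window_labels`,
#'   `point_labels`, `dominant`, `rho`, `classified_ok`, `recognized_ok`.
#' @export
predict_sample <- function(model, sample) {
  sample <- rotate_channels(sample, model$rotation_k)
  ep <- make_episode(sample, model$window, model$reward)
  S <- base::sweep(base::sweep(ep$obs, 2L, model$scaler$mean),
                   2L, model$scaler$sd, "/")
  state <- NULL
  labels <- character(ep$N)
  for (t in seq_len(ep$N)) {
    sa <- select_action(model$params, S[t, ], epsilon = 0, state = state)
    state <- sa$state
    labels[t] <- GESTURES[sa$action]
  }
  pp <- postprocess_labels(labels, ep$active, model$window, sample)
  classified <- pp$dominant == sample$gesture
  structure(list(window_labels = labels, point_labels = pp$point_labels,
                 dominant = pp$dominant, rho = pp$rho,
                 classified_ok = classified,
                 recognized_ok = classified &&
                   pp$rho > model$reward$overlap_threshold),
            class = "emgq_prediction")
}

#' @export
print.emgq_model <- function(x, ...) {
  cat(sprintf("<emgq_model user '%s'> %s/%s agent, %d epochs, %d learn steps\n",
              x$user_id, x$agent$mode, x$agent$variant, x$epochs_done,
              x$learn_count))
  cat(sprintf("  alpha %g, gamma %g, target freq %d, epsilon now %.3f, rotation k=%d\n",
              x$agent$alpha, x$agent$gamma, x$agent$target_update_freq,
              x$epsilon, x$rotation_k))
  invisible(x)
}

#' @export
summary.emgq_model <- function(object, ...) {
  lg <- object$log
  cat(sprintf("User-specific %s agent (%s policy) for user '%s'\n",
              toupper(gsub("_", "-", object$agent$mode)),
              object$agent$variant, object$user_id))
  if (!is.null(lg) && nrow(lg) > 0L) {
    n <- nrow(lg)
    cat(sprintf("  %d episodes; reward first 10: %.2f, last 10: %.2f; final v0 %.2f\n",
                n, mean(utils::head(lg$reward, 10L)),
                mean(utils::tail(lg$reward, 10L)),
                utils::tail(lg$v0, 1L)))
  }
  invisible(object)
}

#' @describeIn train_user_model Network parameters of the online (`"theta"`)
#'   or target (`"theta_target"`) net.
#' @param object,... Method arguments.
#' @param which Which parameter set to return.
#' @export
coef.emgq_model <- function(object, which = c("theta", "theta_target"), ...) {
  object$params[[match.arg(which)]]
}

#' Predict gesture labels for new recordings
#'
#' @param object An `emgq_model`.
#' @param newdata An [emg_sample()], a list of them, or a [user_dataset()]
#'   (its testing split is used).
#' @param ... Unused.
#' @return For a single sample, an `emgq_prediction`; otherwise a data
#'   frame with one row per recording (`sample_id`, `truth`, `dominant`,
#'   `rho`, `classified`, `recognized`).
#' @export
predict.emgq_model <- function(object, newdata, ...) {
  if (inherits(newdata, "emg_sample")) return(predict_sample(object, newdata))
  if (inherits(newdata, "user_dataset")) newdata <- newdata$testing
  evaluate_user(object, newdata)$per_sample
}

#' Plot the training curves of a fitted agent
#'
#' The three per-episode curves logged during training: episode reward,
#' its trailing 5-episode mean, and the initial-observation value estimate
#' `max_a Q(O_1, a)`.
#'
#' @param x An `emgq_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.emgq_model <- function(x, ...) {
  lg <- x$log
  if (is.null(lg) || nrow(lg) == 0L) stop("model has no training log")
  graphics::matplot(lg$episode, cbind(lg$reward, lg$trailing_mean5, lg$v0),
                    type = "l", lty = 1, col = c("grey60", "red", "orange"),
                    xlab = "episode", ylab = "reward / value", ...)
  graphics::legend("bottomright",
                   legend = c("episode reward", "trailing mean (5)",
                              expression(max[a] * " Q(O1, a)")),
                   col = c("grey60", "red", "orange"), lty = 1, bty = "n")
  invisible(x)
}

#' Hyperparameter sweep over users
#'
#' Trains and evaluates every (user, configuration) pair and summarises
#' both accuracies as mean and standard deviation across users. User `i`
#' is trained with seed `config$seed + i - 1`.
#'
#' @param users Nonempty list of [user_dataset()] objects.
#' @param grid Nonempty list of [agent_config()] objects.
#' @param window A [window_spec()].
#' @param reward A [reward_spec()].
#' @return Data frame with one row per configuration: `alpha`,
#'   `target_update_freq`, `mode`, `variant`, `classification_mean`,
#'   `classification_sd`, `recognition_mean`, `recognition_sd`.
#' @export
sweep <- function(users, grid, window = window_spec(),
                  reward = reward_spec()) {
  if (length(users) == 0L || length(grid) == 0L)
    stop("sweep requires at least one user and one configuration")
  rows <- lapply(grid, function(cfg) {
    cls <- numeric(length(users)); rec <- numeric(length(users))
    for (i in seq_along(users)) {
      cfg_i <- cfg
      cfg_i$seed <- cfg$seed + i - 1L
      m <- train_user_model(users[[i]], window, cfg_i, reward)
      ev <- evaluate_user(m, users[[i]]$testing)
      cls[i] <- ev$classification_accuracy
      rec[i] <- ev$recognition_accuracy
    }
    data.frame(alpha = cfg$alpha, target_update_freq = cfg$target_update_freq,
               mode = cfg$mode, variant = cfg$variant,
               classification_mean = mean(cls),
               classification_sd = if (length(cls) > 1L) stats::sd(cls) else 0,
               recognition_mean = mean(rec),
               recognition_sd = if (length(rec) > 1L) stats::sd(rec) else 0)
  })
  do.call(rbind, rows)
}
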