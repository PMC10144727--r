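# shared fixtures, built in code

# recording with a constant value on every channel (mask optional)
const_sample <- function(value = 1, T = 1000L, gesture = "fist",
                         mask = NULL, id = "const") {
  if (is.null(mask)) mask <- rep(1L, T)
  if (gesture == "relax") mask <- integer(T)
  emg_sample(matrix(value, 8, T), gesture, mask, sample_id = id)
}

# recording whose mask covers [from, to) (0-based, half-open), signal
# nonzero only there (amplitude `amp` on all channels)
burst_sample <- function(from, to, T = 1000L, gesture = "fist", amp = 1,
                         id = "burst") {
  sig <- matrix(0, 8, T)
  sig[, (from + 1L):to] <- amp
  mask <- integer(T)
  mask[(from + 1L):to] <- 1L
  emg_sample(sig, gesture, mask, sample_id = id)
}

# a transition for agent-level tests
make_transition <- function(obs, action, reward, next_obs = NULL,
                            done = is.null(next_obs)) {
  list(obs = obs, action = as.integer(action), reward = reward,
       next_obs = next_obs, done = done)
}

random_obs <- function() rnorm(40)

# small, fast synthetic user for pipeline tests
quick_user <- function(seed = 1L, n_train = 12L, n_test = 6L, T = 600L) {
  generate_user(config = synth_config(T = T, n_train = n_train,
                                      n_test = n_test, seed = seed))
}

# numerical gradient of scalar-valued f at theta[[name]][i]
numeric_grad <- function(f, theta, name, i, h = 1e-6) {
  tp <- theta; tp[[name]][i] <- tp[[name]][i] + h
  tm <- theta; tm[[name]][i] <- tm[[name]][i] - h
  (f(tp) - f(tm)) / (2 * h)
}
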