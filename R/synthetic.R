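#' Gesture amplitude profile for the synthetic generator
#'
#' Describes how one gesture class expresses across the 8 armband channels:
#' a nonnegative per-channel activation strength, the range of burst lengths
#' (as a fraction of the recording), and feasible burst onsets. Surface EMG
#' is modelled as amplitude-modulated Gaussian noise, so the profile scales
#' a white-noise carrier inside the burst.
#'
#' @param class_name One of [GESTURES].
#' @param channel_amplitudes Nonnegative numeric vector of length 8. Must be
#'   all zero for "relax".
#' @param burst_fraction_range Length-2 vector `(lo, hi)` in (0, 1]: burst
#'   length as a fraction of the recording length.
#' @param onset_range Optional length-2 vector of feasible 0-based burst
#'   start positions; default anywhere the burst fits.
#' @return An object of class `gesture_profile`.
#' @export
gesture_profile <- function(class_name, channel_amplitudes,
                            burst_fraction_range = c(0.75, 0.90),
                            onset_range = NULL) {
  if (!is_gesture(class_name)) stop("unknown gesture '", class_name, "'")
  if (length(channel_amplitudes) != N_CHANNELS || any(channel_amplitudes < 0))
    stop("channel_amplitudes must be 8 nonnegative values")
  if (class_name == "relax" && any(channel_amplitudes != 0))
    stop("relax profile must have all-zero channel amplitudes")
  if (length(burst_fraction_range) != 2L ||
      burst_fraction_range[1] <= 0 || burst_fraction_range[2] > 1 ||
      burst_fraction_range[1] > burst_fraction_range[2])
    stop("burst_fraction_range must be (lo, hi) within (0, 1]")
  structure(list(class_name = class_name,
                 channel_amplitudes = as.numeric(channel_amplitudes),
                 burst_fraction_range = as.numeric(burst_fraction_range),
                 onset_range = onset_range),
            class = "gesture_profile")
}

# circular channel distance on the 8-pod ring
ring_dist <- function(i, j) pmin(abs(i - j), N_CHANNELS - abs(i - j))

#' Default gesture profiles
#'
#' Five pairwise-distinct activation patterns on the 8-channel ring: a
#' Gaussian bump (s.d. one channel) centred on a class-specific channel for
#' fist (ch 1), waveIn (ch 3), open (ch 5) and waveOut (ch 7), and a
#' two-peak pattern (ch 2 and ch 6) for pinch; relax is all-zero. Amplitudes
#' are in carrier-noise standard-deviation units.
#'
#' @inheritParams gesture_profile
#' @return Named list of six [gesture_profile()] objects, one per class.
#' @export
default_gesture_profiles <- function(burst_fraction_range = c(0.75, 0.90)) {
  bump <- function(centre, height = 1) height * exp(-0.5 * ring_dist(1:8, centre)^2)
  amps <- list(
    fist    = bump(1),
    waveIn  = bump(3),
    open    = bump(5),
    waveOut = bump(7),
    pinch   = 0.8 * (bump(2) + bump(6)),
    relax   = numeric(8))
  profiles <- lapply(names(amps), function(g)
    gesture_profile(g, amps[[g]], burst_fraction_range = burst_fraction_range))
  names(profiles) <- names(amps)
  profiles
}

#' Synthetic-cohort configuration
#'
#' @param T Recording length in points; default 1000 (5 s at 200 Hz). Must
#'   be at least 300 so one analysis window fits.
#' @param baseline_noise_sd Standard deviation of the zero-mean baseline
#'   noise present everywhere (default 0.05).
#' @param burst_noise_sd_scale Multiplier on the burst carrier noise
#'   standard deviation (default 1). Larger values increase class
#'   separability relative to the baseline.
#' @param n_train,n_test Recordings per user in each split, balanced across
#'   the six classes (defaults 60 and 30).
#' @param n_sync Number of "waveOut" synchronization recordings (default 2).
#' @param seed Integer seed for [generate_user()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(T = 1000L, baseline_noise_sd = 0.05,
                         burst_noise_sd_scale = 1, n_train = 60L,
                         n_test = 30L, n_sync = 2L, seed = 1L) {
  if (T < 300L)
    stop("T must be at least 300 so one analysis window fits (got ", T, ")")
  structure(list(T = as.integer(T), baseline_noise_sd = baseline_noise_sd,
                 burst_noise_sd_scale = burst_noise_sd_scale,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 n_sync = as.integer(n_sync), seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate one synthetic EMG recording
#'
#' The signal is zero-mean Gaussian baseline noise everywhere; inside the
#' burst window a white Gaussian carrier, scaled per channel by the
#' profile's amplitudes and shaped by a raised-cosine (Hann) on/off envelope
#' with ramps of 10% of the burst length, is added. The ground-truth mask is
#' 1 exactly on the burst window (all zero for relax). Draws from R's global
#' RNG, so results are deterministic under `set.seed()`.
#'
#' @param profile A [gesture_profile()].
#' @param config A [synth_config()].
#' @param sample_id Identifier for the new sample.
#' @return An [emg_sample()].
#' @export
generate_sample <- function(profile, config, sample_id = profile$class_name) {
  T <- config$T
  sig <- matrix(rnorm(N_CHANNELS * T, 0, config$baseline_noise_sd),
                nrow = N_CHANNELS)
  mask <- integer(T)
  if (profile$class_name != "relax") {
    fr <- profile$burst_fraction_range
    L <- max(1L, round(T * runif(1, fr[1], fr[2])))
    on_lo <- 0L
    on_hi <- T - L
    if (!is.null(profile$onset_range)) {
      on_lo <- max(on_lo, profile$onset_range[1])
      on_hi <- min(on_hi, profile$onset_range[2])
    }
    s <- if (on_hi > on_lo) on_lo + sample.int(on_hi - on_lo + 1L, 1L) - 1L else on_lo
    r <- max(1L, round(0.1 * L))
    env <- rep(1, L)
    ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- ramp
    env[L + 1L - seq_len(r)] <- ramp
    carrier <- matrix(rnorm(N_CHANNELS * L, 0, config$burst_noise_sd_scale),
                      nrow = N_CHANNELS)
    idx <- (s + 1L):(s + L)
    sig[, idx] <- sig[, idx] +
      (profile$channel_amplitudes * carrier) * rep(env, each = N_CHANNELS)
    mask[idx] <- 1L
  }
  emg_sample(sig, profile$class_name, mask, sample_id = sample_id)
}

#' Generate a synthetic user
#'
#' Produces a balanced training and testing split over the six classes plus
#' "waveOut" synchronization samples, with mild per-user variability
#' (log-normal per-channel amplitude jitter, s.d. 0.1 on the log scale).
#' Seeded by `config$seed`, so two users with different seeds differ and the
#' same seed reproduces the user exactly.
#'
#' @param profiles Named list with exactly one [gesture_profile()] per class
#'   (default [default_gesture_profiles()]).
#' @param config A [synth_config()].
#' @param user_id Identifier for the user.
#' @return A [user_dataset()].
#' @export
generate_user <- function(profiles = default_gesture_profiles(),
                          config = synth_config(), user_id = "synth_user") {
  if (!setequal(names(profiles), GESTURES))
    stop("profiles must contain exactly one profile per class: ",
         paste(GESTURES, collapse = ", "))
  set.seed(config$seed)
  # per-user variability: channel-wise multiplicative amplitude jitter
  profiles <- lapply(profiles, function(p) {
    if (p$class_name == "relax") return(p)
    p$channel_amplitudes <- p$channel_amplitudes * exp(rnorm(N_CHANNELS, 0, 0.1))
    p
  })
  gen_split <- function(n, tag) {
    classes <- rep(GESTURES, length.out = n)
    lapply(seq_len(n), function(i)
      generate_sample(profiles[[classes[i]]], config,
                      sample_id = sprintf("%s_%03d_%s", tag, i, classes[i])))
  }
  sync <- lapply(seq_len(config$n_sync), function(i)
    generate_sample(profiles[["waveOut"]], config,
                    sample_id = sprintf("sync_%03d_waveOut", i)))
  user_dataset(user_id,
               training = gen_split(config$n_train, "train"),
               testing = gen_split(config$n_test, "test"),
               sync = sync)
}

#' Generate and save a cohort of synthetic users
#'
#' @param n_users Number of users.
#' @param config A [synth_config()]; user `i` is seeded with
#'   `config$seed + i - 1`.
#' @param dir Output directory; one `user_<id>` subdirectory per user.
#' @param profiles As in [generate_user()].
#' @return Character vector of user directories, invisibly.
#' @export
generate_cohort <- function(n_users, config = synth_config(), dir = ".",
                            profiles = default_gesture_profiles()) {
  paths <- character(n_users)
  for (i in seq_len(n_users)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    uid <- sprintf("user_%03d", i)
    ds <- generate_user(profiles, cfg, user_id = uid)
    paths[i] <- file.path(dir, uid)
    save_user_dataset(ds, paths[i])
  }
  invisible(paths)
}

#' Circularly rotate the channels of a recording
#'
#' Channel `i` of the output is channel `(i + k) mod 8` of the input
#' (0-based); the label, mask and metadata are unchanged. Used to emulate a
#' rotated armband when testing orientation correction.
#'
#' @param sample An [emg_sample()].
#' @param k Integer rotation offset; reduced modulo 8.
#' @return The rotated [emg_sample()].
#' @export
rotate_channels <- function(sample, k) {
  k <- as.integer(k) %% N_CHANNELS
  if (k == 0L) return(sample)
  idx <- ((seq_len(N_CHANNELS) - 1L + k) %% N_CHANNELS) + 1L
  sample$signal <- sample$signal[idx, , drop = FALSE]
  sample
}
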