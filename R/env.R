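#' Reward specification for the labelling environment
#'
#' Per-window classification rewards and terminal recognition rewards: +1
#' for a correctly labelled window, -1 otherwise; at the end of an episode
#' +10 when the post-processed prediction overlaps the ground truth by
#' strictly more than the threshold (and the dominant label is the true
#' gesture), -10 otherwise.
#'
#' @param r_correct,r_wrong Per-window rewards (defaults +1, -1).
#' @param r_recog,r_norecog Terminal recognition rewards (defaults +10, -10).
#' @param overlap_threshold Strict lower bound on the overlap factor for
#'   the recognition bonus (default 0.75).
#' @return An object of class `reward_spec`.
#' @export
reward_spec <- function(r_correct = 1, r_wrong = -1, r_recog = 10,
                        r_norecog = -10, overlap_threshold = 0.75) {
  if (overlap_threshold <= 0 || overlap_threshold >= 1)
    stop("overlap_threshold must be in (0, 1)")
  structure(list(r_correct = r_correct, r_wrong = r_wrong, r_recog = r_recog,
                 r_norecog = r_norecog, overlap_threshold = overlap_threshold),
            class = "reward_spec")
}

#' Build an episode from one recording
#'
#' One recording is one episode of the partially observable decision
#' process: the ordered observations are the window feature vectors; the
#' per-window true label is the recording's gesture when the window span
#' overlaps the ground-truth mask by more than half the window length, and
#' "relax" otherwise.
#'
#' @param sample An [emg_sample()].
#' @param spec A [window_spec()].
#' @param reward A [reward_spec()].
#' @return An object of class `emgq_episode` with fields `obs` (N x 40),
#'   `active`, `starts`, `truth` (per-window labels), `N`, `t` (current
#'   step, starts at 1), `actions` (labels taken so far), and `sample`.
#' @export
make_episode <- function(sample, spec = window_spec(), reward = reward_spec()) {
  fs <- feature_stream(sample, spec)
  cs <- c(0L, cumsum(sample$ground_truth))
  in_mask <- cs[fs$starts + spec$length + 1L] - cs[fs$starts + 1L]
  truth <- ifelse(in_mask > spec$length / 2, sample$gesture, "relax")
  structure(list(obs = fs$features, active = fs$active, starts = fs$starts,
                 truth = truth, N = nrow(fs$features), t = 1L,
                 actions = character(0), sample = sample, spec = spec,
                 reward = reward),
            class = "emgq_episode")
}

#' Current observation of an episode
#'
#' @param ep An `emgq_episode`.
#' @return Numeric feature vector of length 40.
#' @export
episode_obs <- function(ep) ep$obs[ep$t, ]

# terminal post-processing shared by training reward and evaluation:
# window labels -> per-point labels -> majority vote -> dominant/rho
postprocess_labels <- function(window_labels, active, spec, sample) {
  T <- ncol(sample$signal)
  pts <- expand_windows(window_labels, spec, T, active)
  activity <- activity_from_windows(spec, T, active)
  cleaned <- majority_vote(pts, activity)
  truth_pts <- ifelse(sample$ground_truth == 1L, sample$gesture, "relax")
  list(point_labels = cleaned, dominant = label_mode(cleaned),
       rho = overlap_factor(cleaned, truth_pts))
}

#' Advance an episode by one action
#'
#' The classification reward is `r_correct` when `action` matches the
#' window's true label and `r_wrong` otherwise. Before the last window the
#' next observation is returned with that reward. On the last window the
#' full action sequence is post-processed ([expand_windows()] then
#' [majority_vote()]), the overlap factor against the ground truth is
#' computed, and the terminal reward adds the recognition bonus
#' (`r_recog` when `rho` strictly exceeds the threshold *and* the dominant
#' predicted label equals the true gesture, `r_norecog` otherwise) to the
#' last window's classification reward.
#'
#' @param ep An `emgq_episode` that is not finished.
#' @param action A gesture label (one of [GESTURES]) or its index in 1..6.
#' @return List with `episode` (updated), `obs` (next observation or
#'   `NULL`), `reward`, `done`, and on the terminal step `rho` and
#'   `dominant`.
#' @export
env_step <- function(ep, action) {
  if (ep$t > ep$N) stop("episode is finished; no further steps allowed")
  if (is.numeric(action)) action <- GESTURES[as.integer(action)]
  if (!is_gesture(action)) stop("unknown action '", action, "'")
  r <- if (action == ep$truth[ep$t]) ep$reward$r_correct else ep$reward$r_wrong
  ep$actions <- c(ep$actions, action)
  if (ep$t < ep$N) {
    ep$t <- ep$t + 1L
    return(list(episode = ep, obs = ep$obs[ep$t, ], reward = r, done = FALSE))
  }
  ep$t <- ep$t + 1L
  pp <- postprocess_labels(ep$actions, ep$active, ep$spec, ep$sample)
  recognized <- pp$rho > ep$reward$overlap_threshold &&
    pp$dominant == ep$sample$gesture
  r <- r + if (recognized) ep$reward$r_recog else ep$reward$r_norecog
  list(episode = ep, obs = NULL, reward = r, done = TRUE,
       rho = pp$rho, dominant = pp$dominant)
}
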