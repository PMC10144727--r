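# centred moving average of width `w` with truncated edges:
# out[i] = mean(x[max(1, i-h) : min(n, i+h)]), h = floor(w/2)
moving_average_trunc <- function(x, w = 25L) {
  n <- length(x)
  h <- w %/% 2L
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# the five time-domain features of one channel vector
channel_features <- function(x) {
  L <- length(x)
  ax <- abs(x)
  c(AE  = mean(moving_average_trunc(ax, 25L)),
    E   = sum(x^2),
    RMS = sqrt(mean(x^2)),
    STD = stats::sd(x),          # unbiased, denominator L - 1
    MAV = mean(ax))
}

#' Compute the 40-dimensional feature vector of one window
#'
#' For each of the 8 channels, five time-domain features are computed from
#' the raw window slice: absolute envelope (AE, the mean of the rectified
#' signal smoothed by a centred 25-point moving average with truncated
#' edges), energy (E, sum of squares), root mean square (RMS), sample
#' standard deviation (STD, denominator L - 1) and mean absolute value
#' (MAV). The output is ordered channel-major: `(AE, E, RMS, STD, MAV)` for
#' channel 1, then channel 2, and so on — 40 values matching the network
#' input layer. Windows that failed the energy gate yield the zero vector.
#'
#' @param window One window as produced by [segment_sample()] (a list with
#'   `data` (8 x L, L >= 2) and `active`).
#' @return Numeric vector of length 40 with an `active` attribute.
#' @export
compute_features <- function(window) {
  d <- window$data
  if (!is.matrix(d) || nrow(d) != N_CHANNELS || ncol(d) < 2L)
    stop("window data must be an 8 x L matrix with L >= 2")
  v <- if (isTRUE(window$active)) as.vector(apply(d, 1L, channel_features))
       else numeric(FEATURE_DIM)
  names(v) <- paste0("ch", rep(seq_len(N_CHANNELS), each = N_FEATURES_PER_CHANNEL),
                     "_", rep(FEATURE_NAMES, N_CHANNELS))
  attr(v, "active") <- isTRUE(window$active)
  v
}

#' Feature stream of a whole recording
#'
#' Segments a recording and computes the per-window feature vectors.
#'
#' @param sample An [emg_sample()].
#' @param spec A [window_spec()].
#' @return List with `features` (N x 40 matrix), `active` (logical N),
#'   `starts` (integer N, 0-based).
#' @export
feature_stream <- function(sample, spec = window_spec()) {
  wins <- segment_sample(sample, spec)
  feats <- t(vapply(wins, function(w) as.numeric(compute_features(w)),
                    numeric(FEATURE_DIM)))
  list(features = feats,
       active = vapply(wins, `[[`, logical(1), "active"),
       starts = vapply(wins, `[[`, integer(1), "start"))
}
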