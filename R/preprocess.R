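#' Sliding-window specification
#'
#' Window length, stride and relative energy threshold used to segment a
#' recording. A window is "active" when its energy (sum of squared samples
#' over all channels and points) is at least `energy_threshold` times the
#' maximum window energy of the same recording; inactive windows are later
#' replaced by zero feature vectors.
#'
#' @param length Window length in points (default 300, i.e. 1.5 s at 200 Hz).
#' @param stride Hop between consecutive window starts in points (default 40).
#' @param energy_threshold Fraction in \[0, 1\] (default 0.18). The
#'   comparison is inclusive: a window exactly at the threshold passes.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length = 300L, stride = 40L, energy_threshold = 0.18) {
  if (length < 1L || stride < 1L) stop("length and stride must be >= 1")
  if (energy_threshold < 0 || energy_threshold > 1)
    stop("energy_threshold must be in [0, 1]")
  structure(list(length = as.integer(length), stride = as.integer(stride),
                 energy_threshold = energy_threshold),
            class = "window_spec")
}

#' Segment a recording into sliding windows
#'
#' Windows start at 0, stride, 2*stride, ... (0-based, half-open spans
#' `[start, start + length)`) while they fit, giving
#' `floor((T - length) / stride) + 1` windows in temporal order. Each window
#' carries its 8 x length data slice, its start, its energy, and the active
#' flag from the relative-energy gate. If every window has zero energy all
#' windows are inactive.
#'
#' @param sample An [emg_sample()] with at least `spec$length` points.
#' @param spec A [window_spec()].
#' @return List of windows, each a list with elements `data`, `start`,
#'   `energy`, `active`.
#' @export
segment_sample <- function(sample, spec = window_spec()) {
  T <- ncol(sample$signal)
  L <- spec$length
  if (T < L)
    stop("sample '", sample$sample_id, "' has ", T,
         " points, shorter than the window length ", L)
  starts <- seq.int(0L, T - L, by = spec$stride)
  cs <- c(0, cumsum(colSums(sample$signal^2)))
  energies <- cs[starts + L + 1L] - cs[starts + 1L]
  emax <- max(energies)
  active <- if (emax <= 0) rep(FALSE, length(starts))
            else energies / emax >= spec$energy_threshold
  lapply(seq_along(starts), function(i)
    list(data = sample$signal[, (starts[i] + 1L):(starts[i] + L), drop = FALSE],
         start = starts[i], energy = energies[i], active = active[i]))
}

# per-channel energies (sum of squares) accumulated over a list of samples
channel_energies <- function(samples) {
  e <- numeric(N_CHANNELS)
  for (s in samples) e <- e + rowSums(s$signal^2)
  e
}

#' Correct armband orientation from synchronization samples
#'
#' Sums per-channel energies over all "waveOut" synchronization samples and
#' circularly rotates every recording in the dataset so the maximum-energy
#' channel sits at canonical channel 1 (ties broken towards the lowest
#' channel index). This makes the downstream feature stream invariant to
#' how the armband was rotated on the forearm.
#'
#' @param dataset A [user_dataset()] with nonempty `sync`.
#' @return The corrected [user_dataset()].
#' @export
correct_orientation <- function(dataset) {
  if (length(dataset$sync) == 0L)
    stop("orientation correction requires at least one 'waveOut' sync sample")
  e <- channel_energies(dataset$sync)
  k <- which.max(e) - 1L       # rotate so that channel (1 + k) maps to 1
  if (k == 0L) return(dataset)
  for (fld in c("training", "testing", "sync"))
    dataset[[fld]] <- lapply(dataset[[fld]], rotate_channels, k = k)
  dataset
}
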