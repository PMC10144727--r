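#' Construct a single EMG recording
#'
#' Bundles one gesture recording: an 8 x T signal matrix (channels x time),
#' its gesture label, and a per-point ground-truth activity mask (1 inside
#' the muscle-activity region, 0 elsewhere; all zero for "relax").
#'
#' @param signal Numeric matrix with exactly 8 rows (channels) and T >= 1
#'   columns (time points), arbitrary amplitude units.
#' @param gesture One of [GESTURES].
#' @param ground_truth Integer/numeric 0-1 vector of length T. Defaults to
#'   all zeros (required for "relax").
#' @param fs Sampling rate in Hz (default 200).
#' @param sample_id Identifier string used in error messages and filenames.
#' @return An object of class `emg_sample`.
#' @seealso [validate_emg_sample()], [user_dataset()]
#' @export
emg_sample <- function(signal, gesture, ground_truth = NULL, fs = 200,
                       sample_id = "sample") {
  if (is.null(ground_truth)) ground_truth <- integer(ncol(signal))
  x <- structure(
    list(signal = signal, gesture = gesture,
         ground_truth = as.integer(ground_truth),
         fs = fs, sample_id = as.character(sample_id)),
    class = "emg_sample")
  validate_emg_sample(x)
}

#' Validate an EMG recording
#'
#' Checks the `emg_sample` invariants: 8 channel rows, T >= 1, mask length
#' equal to T with values in \{0, 1\}, a known gesture label, and an all-zero
#' mask for "relax". Errors name the offending `sample_id`.
#'
#' @param x An `emg_sample`.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_emg_sample <- function(x) {
  id <- x$sample_id %||% "<unnamed>"
  if (!is.matrix(x$signal) || !is.numeric(x$signal))
    stop("sample '", id, "': signal must be a numeric matrix")
  if (nrow(x$signal) != N_CHANNELS)
    stop("sample '", id, "': signal must have exactly ", N_CHANNELS,
         " channel rows, found ", nrow(x$signal))
  if (ncol(x$signal) < 1L)
    stop("sample '", id, "': signal must have at least one time point")
  if (!is_gesture(x$gesture))
    stop("sample '", id, "': unknown gesture '", x$gesture, "'")
  if (length(x$ground_truth) != ncol(x$signal))
    stop("sample '", id, "': ground_truth length ", length(x$ground_truth),
         " does not match signal length ", ncol(x$signal))
  if (!all(x$ground_truth %in% c(0L, 1L)))
    stop("sample '", id, "': ground_truth must be a 0/1 vector")
  if (x$gesture == "relax" && any(x$ground_truth != 0L))
    stop("sample '", id, "': relax samples must have an all-zero mask")
  invisible(x)
}

#' @export
print.emg_sample <- function(x, ...) {
  cat(sprintf("<emg_sample '%s'> gesture=%s, %d ch x %d pts @ %g Hz, activity %d pts\n",
              x$sample_id, x$gesture, nrow(x$signal), ncol(x$signal),
              x$fs, sum(x$ground_truth)))
  invisible(x)
}

#' Construct a per-user dataset
#'
#' A user's recordings split into training and testing lists, plus
#' "waveOut" synchronization samples used only for sensor-orientation
#' correction (see [correct_orientation()]).
#'
#' @param user_id Identifier string.
#' @param training,testing Lists of [emg_sample()] objects.
#' @param sync List of [emg_sample()] objects, all with gesture "waveOut".
#' @return An object of class `user_dataset`.
#' @export
user_dataset <- function(user_id, training, testing = list(), sync = list()) {
  ds <- structure(list(user_id = as.character(user_id), training = training,
                       testing = testing, sync = sync),
                  class = "user_dataset")
  validate_user_dataset(ds)
}

#' @rdname user_dataset
#' @param x A `user_dataset`.
#' @export
validate_user_dataset <- function(x) {
  for (s in c(x$training, x$testing, x$sync)) validate_emg_sample(s)
  for (s in x$sync)
    if (s$gesture != "waveOut")
      stop("sync sample '", s$sample_id, "' must have gesture 'waveOut', has '",
           s$gesture, "'")
  invisible(x)
}

#' @export
print.user_dataset <- function(x, ...) {
  cat(sprintf("<user_dataset '%s'> %d training, %d testing, %d sync samples\n",
              x$user_id, length(x$training), length(x$testing), length(x$sync)))
  invisible(x)
}

## ---- plain-text on-disk layout -------------------------------------------
## user directory:
##   meta                 DCF: user_id, fs, classes
##   train/<sample_id>    one recording per file (format below)
##   test/<sample_id>
##   sync/<sample_id>
## recording file: "key value" header lines (sample_id, gesture, fs,
## channels, T), a "mask" line of T 0/1 characters, then 8 "ch<i>" lines of
## T space-separated numbers. Numeric encoding is IEEE 754 binary32 printed
## with 9 significant digits, so save -> load is bit-exact at float32
## precision and identical input yields byte-identical files.

write_sample_file <- function(sample, file) {
  sig <- sample$signal
  lines <- c(
    paste("sample_id", sample$sample_id),
    paste("gesture", sample$gesture),
    paste("fs", format(sample$fs)),
    paste("channels", nrow(sig)),
    paste("T", ncol(sig)),
    paste("mask", paste(sample$ground_truth, collapse = "")),
    vapply(seq_len(nrow(sig)), function(i) {
      paste0("ch", i, " ",
             paste(sprintf("%.9g", float32_snap(sig[i, ])), collapse = " "))
    }, character(1)))
  writeLines(lines, file)
}

read_sample_file <- function(file) {
  lines <- readLines(file)
  kv <- regmatches(lines, regexpr(" ", lines), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", character(1))
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("malformed sample file '", file, "': missing '", k, "'")
    vals[i]
  }
  id <- get("sample_id")
  n_ch <- as.integer(get("channels"))
  T <- as.integer(get("T"))
  if (n_ch != N_CHANNELS)
    stop("sample '", id, "': signal must have exactly ", N_CHANNELS,
         " channel rows, found ", n_ch)
  mask <- as.integer(strsplit(get("mask"), "")[[1]])
  sig <- matrix(0, nrow = n_ch, ncol = T)
  for (i in seq_len(n_ch)) {
    row <- as.numeric(strsplit(get(paste0("ch", i)), " ", fixed = TRUE)[[1]])
    if (length(row) != T)
      stop("sample '", id, "': channel ", i, " has ", length(row),
           " points, expected ", T)
    sig[i, ] <- float32_snap(row)
  }
  emg_sample(sig, get("gesture"), mask, fs = as.numeric(get("fs")),
             sample_id = id)
}

#' Save a user dataset to a directory
#'
#' Writes the documented plain-text per-user layout: a `meta` index file and
#' one file per recording under `train/`, `test/` and `sync/`. Signals are
#' encoded as 32-bit floats printed in full precision, so saving is
#' deterministic and [load_user_dataset()] recovers them bit-exactly.
#'
#' @param dataset A [user_dataset()].
#' @param path Directory to create/write (the user directory itself).
#' @return `path`, invisibly.
#' @export
save_user_dataset <- function(dataset, path) {
  validate_user_dataset(dataset)
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(path, 2L) != 0L)
    stop("cannot write to '", path, "'")
  writeLines(c(paste("user_id", dataset$user_id),
               "fs 200",
               paste("classes", paste(GESTURES, collapse = ","))),
             file.path(path, "meta"))
  for (sub in c("train", "test", "sync"))
    dir.create(file.path(path, sub), showWarnings = FALSE)
  split <- list(train = dataset$training, test = dataset$testing,
                sync = dataset$sync)
  for (sub in names(split))
    for (s in split[[sub]])
      write_sample_file(s, file.path(path, sub, s$sample_id))
  invisible(path)
}

#' Load a user dataset from a directory
#'
#' Reads the layout written by [save_user_dataset()] and validates every
#' sample; violations (wrong channel count, mask/signal length mismatch,
#' unknown gesture) raise errors naming the offending sample id.
#'
#' @param path User directory containing `meta`, `train/`, `test/`, `sync/`.
#' @return A [user_dataset()].
#' @export
load_user_dataset <- function(path) {
  meta_file <- file.path(path, "meta")
  if (!file.exists(meta_file))
    stop("no dataset at '", path, "': missing meta file")
  meta <- readLines(meta_file)
  uid <- sub("^user_id ", "", grep("^user_id ", meta, value = TRUE)[1])
  read_dir <- function(sub) {
    d <- file.path(path, sub)
    if (!dir.exists(d)) return(list())
    files <- sort(list.files(d, full.names = TRUE))
    lapply(files, read_sample_file)
  }
  user_dataset(uid, training = read_dir("train"), testing = read_dir("test"),
               sync = read_dir("sync"))
}
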