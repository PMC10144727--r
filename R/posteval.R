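#' Expand window labels to a per-point label vector
#'
#' Each point takes the label of the last *active* window covering it
#' (later windows overwrite earlier ones); points covered by no active
#' window are "relax". Window spans are half-open `[start, start+length)`.
#'
#' @param window_labels Character vector of per-window gesture labels.
#' @param spec The [window_spec()] used for segmentation.
#' @param T Recording length in points.
#' @param active Logical vector flagging the windows that passed the energy
#'   gate (same length as `window_labels`).
#' @return Character vector of length `T`.
#' @export
expand_windows <- function(window_labels, spec, T, active) {
  n <- length(window_labels)
  if (length(active) != n)
    stop("window_labels and active must have the same length")
  starts <- seq.int(0L, by = spec$stride, length.out = n)
  if (n > 0L && starts[n] + spec$length > T)
    stop("window layout exceeds the recording length T = ", T)
  out <- rep("relax", T)
  for (i in seq_len(n)) {
    if (!active[i]) next
    out[(starts[i] + 1L):(starts[i] + spec$length)] <- window_labels[i]
  }
  out
}

# union of the spans of active windows, as a logical mask of length T
activity_from_windows <- function(spec, T, active) {
  n <- length(active)
  starts <- seq.int(0L, by = spec$stride, length.out = n)
  m <- logical(T)
  for (i in seq_len(n))
    if (active[i]) m[(starts[i] + 1L):(starts[i] + spec$length)] <- TRUE
  m
}

#' Majority-vote cleaning of a per-point label vector
#'
#' Removes spurious labels: the most frequent non-relax label inside the
#' muscle-activity region replaces every label there, and every point
#' outside the activity region becomes "relax". If no non-relax label
#' exists the whole vector is "relax". Count ties are broken by the label
#' whose first occurrence in the vector is earliest. The operation is
#' idempotent and leaves at most one non-relax label.
#'
#' @param point_labels Character vector of per-point labels.
#' @param activity Logical vector of the same length marking the
#'   muscle-activity region (union of active window spans).
#' @return Cleaned character vector of the same length.
#' @export
majority_vote <- function(point_labels, activity) {
  if (length(point_labels) != length(activity))
    stop("point_labels and activity must have the same length")
  out <- rep("relax", length(point_labels))
  dom <- label_mode(point_labels[activity])
  if (dom != "relax") out[activity] <- dom
  out
}

#' Overlap factor between labelled point vectors
#'
#' Soerensen-Dice overlap between the predicted and true gesture regions:
#' `A` is the set of points carrying the dominant non-relax predicted
#' label, `B` the set of non-relax true points, and
#' `rho = 2|A intersect B| / (|A| + |B|)`. When both sets are empty
#' `rho = 1`; when exactly one is empty `rho = 0`.
#'
#' @param pred,truth Character label vectors of equal length.
#' @return `rho` in \[0, 1\].
#' @export
overlap_factor <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  dom <- label_mode(pred)
  A <- if (dom == "relax") logical(length(pred)) else pred == dom
  B <- truth != "relax"
  na <- sum(A); nb <- sum(B)
  if (na == 0L && nb == 0L) return(1)
  if (na == 0L || nb == 0L) return(0)
  2 * sum(A & B) / (na + nb)
}

#' Evaluate a trained model on a set of recordings
#'
#' Runs each recording as a greedy episode (epsilon = 0), applies
#' majority-vote post-processing, and scores two metrics: classification
#' accuracy (dominant predicted label equals the true gesture) and
#' recognition accuracy (classified correctly *and* overlap factor above
#' the recognition threshold). Also accumulates a 6 x 6 confusion matrix of
#' true class versus dominant prediction.
#'
#' @param model An `emgq_model` from [train_user_model()].
#' @param samples Nonempty list of [emg_sample()] recordings (or a
#'   [user_dataset()], whose `testing` split is used).
#' @return List of class `emgq_evaluation`: `classification_accuracy`,
#'   `recognition_accuracy`, `confusion`, and `per_sample` (a data frame
#'   with one row per recording).
#' @export
evaluate_user <- function(model, samples) {
  if (inherits(samples, "user_dataset")) samples <- samples$testing
  if (length(samples) == 0L) stop("evaluation requires at least one sample")
  per <- lapply(samples, function(s) predict_sample(model, s))
  confusion <- matrix(0L, N_ACTIONS, N_ACTIONS,
                      dimnames = list(truth = GESTURES, predicted = GESTURES))
  for (i in seq_along(samples))
    confusion[samples[[i]]$gesture, per[[i]]$dominant] <-
      confusion[samples[[i]]$gesture, per[[i]]$dominant] + 1L
  df <- data.frame(
    sample_id = vapply(samples, `[[`, character(1), "sample_id"),
    truth = vapply(samples, `[[`, character(1), "gesture"),
    dominant = vapply(per, `[[`, character(1), "dominant"),
    rho = vapply(per, `[[`, numeric(1), "rho"),
    classified = vapply(per, `[[`, logical(1), "classified_ok"),
    recognized = vapply(per, `[[`, logical(1), "recognized_ok"),
    stringsAsFactors = FALSE)
  structure(list(classification_accuracy = mean(df$classified),
                 recognition_accuracy = mean(df$recognized),
                 confusion = confusion, per_sample = df),
            class = "emgq_evaluation")
}

#' @export
print.emgq_evaluation <- function(x, ...) {
  cat(sprintf("<emgq_evaluation> %d samples: classification %.3f, recognition %.3f\n",
              nrow(x$per_sample), x$classification_accuracy,
              x$recognition_accuracy))
  invisible(x)
}

#' Write per-user evaluation summaries as a delimited table
#'
#' @param results Named list of `emgq_evaluation` objects (names are user ids).
#' @param file Output path (tab-separated; columns user_id, classification,
#'   recognition).
#' @return The summary data frame, invisibly.
#' @export
write_evaluation_table <- function(results, file) {
  df <- data.frame(
    user_id = names(results),
    classification = vapply(results, `[[`, numeric(1), "classification_accuracy"),
    recognition = vapply(results, `[[`, numeric(1), "recognition_accuracy"),
    row.names = NULL, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
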