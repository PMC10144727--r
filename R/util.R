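# internal helpers shared across modules

gesture_id <- function(g) {
  i <- match(g, GESTURES)
  if (anyNA(i)) stop("unknown gesture label(s): ", paste(unique(g[is.na(i)]), collapse = ", "))
  i
}

is_gesture <- function(g) g %in% GESTURES

# Mode of the non-relax labels; ties broken by earliest first occurrence.
# Returns "relax" when no non-relax label exists.
label_mode <- function(labels) {
  x <- labels[labels != "relax"]
  if (length(x) == 0L) return("relax")
  u <- unique(x)                      # order of first occurrence
  u[which.max(tabulate(match(x, u)))] # which.max keeps the earliest on ties
}

# Round-trip a double vector through IEEE 754 binary32. The on-disk dataset
# encoding is float32; snapping makes save -> load the identity.
float32_snap <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L),
          what = "numeric", n = length(x), size = 4L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
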