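#' Epoch a continuous recording into fixed-length segments
#'
#' Cuts the recording into consecutive, non-overlapping epochs of
#' `epoch_length_s` seconds. A trailing partial epoch is discarded.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_length_s Epoch length in seconds (default 2 s).
#'
#' @return An [epoched_eeg()].
#' @export
epoch_recording <- function(rec, epoch_length_s = 2.0) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_per <- as.integer(round(rec$fs * epoch_length_s))
  n_total <- ncol(rec$data)
  n_ep <- n_total %/% n_per
  if (n_ep < 1L) {
    abort(sprintf(
      "Recording too short to epoch: %d samples available, %d needed per epoch.",
      n_total, n_per
    ))
  }
  used <- rec$data[, seq_len(n_ep * n_per), drop = FALSE]
  ep <- aperm(array(used, dim = c(nrow(used), n_per, n_ep)), c(3, 1, 2))
  epoched_eeg(ep, rec$fs, epoch_length_s,
    channel_names = rec$channel_names,
    positions = rec$positions, reference = rec$reference
  )
}

#' Reject epochs exceeding an absolute amplitude threshold
#'
#' An epoch is rejected when any channel at any sample exceeds the threshold
#' in absolute value (strictly greater; a sample at exactly the threshold is
#' retained).
#'
#' @param ep An [epoched_eeg()].
#' @param threshold_uv Rejection threshold in microvolts (default 150).
#'
#' @return A list with `epochs` (the cleaned `epoched_eeg`) and `report`, a
#'   tibble of rejected epoch indices with their peak absolute voltage.
#' @export
reject_high_amplitude <- function(ep, threshold_uv = 150.0) {
  stopifnot(inherits(ep, "epoched_eeg"))
  if (n_epochs(ep) == 0L) abort("Empty epoched EEG.")
  peak <- apply(abs(ep$epochs), 1, max)
  bad <- which(peak > threshold_uv)
  if (length(bad) == n_epochs(ep)) {
    abort(sprintf(
      "All %d epochs exceed the %g uV amplitude threshold.",
      n_epochs(ep), threshold_uv
    ))
  }
  keep <- setdiff(seq_len(n_epochs(ep)), bad)
  out <- ep
  out$epochs <- ep$epochs[keep, , , drop = FALSE]
  list(
    epochs = out,
    report = tibble::tibble(epoch = bad, peak_abs_uv = peak[bad])
  )
}

#' Re-reference an epoched EEG to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample, so the
#' per-sample channel mean is zero. Idempotent; between-channel differences
#' are untouched.
#'
#' @param ep An [epoched_eeg()].
#' @return The average-referenced [epoched_eeg()].
#' @export
apply_average_reference <- function(ep) {
  stopifnot(inherits(ep, "epoched_eeg"))
  d <- dim(ep$epochs)
  if (d[2] < 2L) abort("Average referencing needs at least 2 channels.")
  means <- apply(ep$epochs, c(1, 3), mean)          # epochs x samples
  sweep_arr <- aperm(
    array(means, dim = c(d[1], d[3], d[2])), c(1, 3, 2)
  )
  out <- ep
  out$epochs <- ep$epochs - sweep_arr
  out$reference <- "average"
  out
}

#' Segment-retention gate
#'
#' A recording enters further analysis only when strictly more than
#' `min_segments` epochs survive cleaning (the default gate of 15 two-second
#' segments corresponds to 30 s of data).
#'
#' @param ep An [epoched_eeg()].
#' @param min_segments Retention minimum (default 15).
#'
#' @return A tibble with `n_segments`, `min_segments` and logical `pass`.
#' @export
check_retention <- function(ep, min_segments = 15L) {
  stopifnot(inherits(ep, "epoched_eeg"))
  n <- n_epochs(ep)
  tibble::tibble(
    n_segments = n,
    min_segments = as.integer(min_segments),
    pass = n > min_segments
  )
}
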