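#' Construct a continuous EEG recording
#'
#' A lightweight container for a multichannel voltage matrix plus the
#' metadata every downstream stage needs: sampling rate, channel names and
#' unit-sphere sensor positions. Voltages are in microvolts.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector, one name per channel. Defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param positions Numeric matrix, channels x 3, unit-norm sensor positions
#'   on the scalp sphere. When `NULL` a generic montage is substituted with a
#'   warning (positions only matter for simulation and plotting; GFP and
#'   spatial correlations are position-free).
#' @param reference Either `"common"` (recorded against a common electrode)
#'   or `"average"`.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL, positions = NULL,
                          reference = c("common", "average")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (!is.numeric(data)) abort("`data` must be a numeric channels x samples matrix.")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  n_ch <- nrow(data)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_ch))
  if (length(channel_names) != n_ch) {
    abort("`channel_names` length must equal the number of data rows.")
  }
  if (is.null(positions)) {
    warn("No channel positions supplied; substituting a generic spherical montage.")
    positions <- make_montage(max(n_ch, 4L), seed = 1L)[seq_len(n_ch), , drop = FALSE]
  }
  positions <- as.matrix(positions)
  if (nrow(positions) != n_ch || ncol(positions) != 3L) {
    abort("`positions` must be a channels x 3 matrix.")
  }
  norms <- sqrt(rowSums(positions^2))
  if (any(abs(norms - 1) > 1e-6)) {
    abort("Channel positions must have unit norm.")
  }
  structure(
    list(
      data = data, fs = fs, channel_names = as.character(channel_names),
      positions = positions, reference = reference
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference
  ))
  invisible(x)
}

#' Construct an epoched EEG object
#'
#' @param epochs Numeric array, epochs x channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param epoch_length_s Epoch length in seconds; every epoch must hold
#'   exactly `round(fs * epoch_length_s)` samples.
#' @param channel_names,positions,reference As in [eeg_recording()].
#'
#' @return An object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(epochs, fs, epoch_length_s, channel_names = NULL,
                        positions = NULL, reference = c("common", "average")) {
  reference <- match.arg(reference)
  if (length(dim(epochs)) != 3L) {
    abort("`epochs` must be a 3-d array: epochs x channels x samples.")
  }
  expected <- as.integer(round(fs * epoch_length_s))
  if (dim(epochs)[3] != expected) {
    abort(sprintf(
      "Each epoch must have round(fs * epoch_length_s) = %d samples, got %d.",
      expected, dim(epochs)[3]
    ))
  }
  n_ch <- dim(epochs)[2]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_ch))
  if (is.null(positions)) {
    warn("No channel positions supplied; substituting a generic spherical montage.")
    positions <- make_montage(max(n_ch, 4L), seed = 1L)[seq_len(n_ch), , drop = FALSE]
  }
  structure(
    list(
      epochs = epochs, fs = fs, epoch_length_s = epoch_length_s,
      channel_names = as.character(channel_names),
      positions = as.matrix(positions), reference = reference
    ),
    class = "epoched_eeg"
  )
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf(
    "<epoched_eeg> %d epochs x %d channels x %d samples (%g s @ %g Hz), %s reference\n",
    d[1], d[2], d[3], x$epoch_length_s, x$fs, x$reference
  ))
  invisible(x)
}

#' Number of epochs in an epoched EEG object
#' @param ep An `epoched_eeg`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(ep) {
  stopifnot(inherits(ep, "epoched_eeg"))
  dim(ep$epochs)[1]
}

#' Construct a prototype (microstate template) set
#'
#' Prototype maps are zero-mean across channels and unit Euclidean norm;
#' each map is defined only up to a global sign flip (polarity invariance).
#'
#' @param maps Numeric matrix, K x channels.
#' @param channel_names Optional channel names.
#' @param normalize Center and rescale the rows to zero mean / unit norm.
#'
#' @return An object of class `prototype_set`.
#' @export
prototype_set <- function(maps, channel_names = NULL, normalize = TRUE) {
  maps <- as.matrix(maps)
  if (normalize) {
    maps <- maps - rowMeans(maps)
    nrm <- sqrt(rowSums(maps^2))
    if (any(nrm < 1e-12)) abort("A prototype map is numerically zero.")
    maps <- maps / nrm
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(maps)))
  structure(
    list(maps = maps, K = nrow(maps), channel_names = as.character(channel_names)),
    class = "prototype_set"
  )
}

#' @export
print.prototype_set <- function(x, ...) {
  cat(sprintf("<prototype_set> K = %d maps, %d channels\n", x$K, ncol(x$maps)))
  invisible(x)
}

# Flatten epochs x channels x samples into channels x (epochs*samples),
# epoch-major in time. Used wherever per-sample maps are needed.
flatten_epochs <- function(ep) {
  d <- dim(ep$epochs)
  out <- matrix(aperm(ep$epochs, c(2, 3, 1)), nrow = d[2])
  out
}
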