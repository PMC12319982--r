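#' Generate a generic spherical montage
#'
#' Places `n_channels` sensors near-uniformly on the unit sphere using a
#' golden-spiral construction biased toward the upper hemisphere (scalp
#' coverage), with a small seeded jitter so distinct seeds give distinct but
#' equally regular montages. Deterministic for a given seed.
#'
#' @param n_channels Number of sensors (>= 4).
#' @param seed Integer seed.
#'
#' @return An `n_channels` x 3 matrix of unit-norm positions. Axis
#'   convention: x right, y anterior, z superior.
#' @export
make_montage <- function(n_channels, seed = 1L) {
  if (n_channels < 4L) abort("A montage needs at least 4 channels.")
  withr::with_seed(as.integer(seed), {
    i <- seq_len(n_channels)
    # golden-spiral z limited to [-0.35, 1]: upper-hemisphere biased
    z <- 1 - (i - 0.5) / n_channels * 1.35
    golden <- pi * (3 - sqrt(5))
    theta <- golden * (i - 1)
    jitter <- matrix(rnorm(3L * n_channels, sd = 0.01), ncol = 3L)
    r <- sqrt(pmax(0, 1 - z^2))
    pos <- cbind(r * cos(theta), r * sin(theta), z) + jitter
    pos / sqrt(rowSums(pos^2))
  })
}

#' Spatial Pearson correlation between two scalp maps
#'
#' Topographic similarity across channels; for average-referenced (zero-mean)
#' unit-norm maps this is the plain dot product.
#'
#' @param a,b Numeric vectors (one value per channel).
#' @return Correlation in `[-1, 1]`.
#' @export
spatial_corr <- function(a, b) {
  a <- a - mean(a)
  b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-15 || nb < 1e-15) return(0)
  sum(a * b) / (na * nb)
}

#' Draw smooth dipolar prototype maps
#'
#' Each prototype is the projection of the sensor positions onto a random
#' dipole orientation (a rank-1 linear field), centered and normalized.
#' Orientations are rejection-sampled until all pairwise absolute spatial
#' correlations stay at or below `max_abs_corr`, which guarantees separable
#' planted classes.
#'
#' @param positions Channels x 3 montage matrix (see [make_montage()]).
#' @param K Number of prototypes (>= 2).
#' @param seed Integer seed.
#' @param max_abs_corr Separation bound on pairwise |spatial correlation|.
#' @param max_draws Rejection-sampling budget per map.
#'
#' @return A [prototype_set()] of K maps.
#' @export
make_prototype_maps <- function(positions, K, seed = 1L, max_abs_corr = 0.7,
                                max_draws = 500L) {
  if (K < 2L) abort("`K` must be at least 2.")
  positions <- as.matrix(positions)
  withr::with_seed(as.integer(seed), {
    maps <- matrix(NA_real_, nrow = K, ncol = nrow(positions))
    k <- 1L
    draws <- 0L
    total_draws <- 0L
    while (k <= K) {
      if (draws >= max_draws) {
        # an unlucky partial set can block the remaining slots entirely;
        # discard it and restart the draw rather than hammering one slot
        k <- 1L
        draws <- 0L
      }
      if (total_draws >= 50L * max_draws) {
        abort(paste0(
          "Could not draw ", K, " maps with pairwise |corr| <= ", max_abs_corr,
          " in ", total_draws, " tries; use a larger montage or relax the bound."
        ))
      }
      o <- rnorm(3L)
      o <- o / sqrt(sum(o^2))
      m <- drop(positions %*% o)
      m <- m - mean(m)
      m <- m / sqrt(sum(m^2))
      draws <- draws + 1L
      total_draws <- total_draws + 1L
      ok <- k == 1L ||
        all(abs(maps[seq_len(k - 1L), , drop = FALSE] %*% m) <= max_abs_corr)
      if (ok) {
        maps[k, ] <- m
        k <- k + 1L
      }
    }
    prototype_set(maps, normalize = FALSE)
  })
}

#' Simulate a microstate label sequence
#'
#' Semi-Markov chain: dwell times are geometric with the requested per-state
#' mean (in ms), and the next state is uniform over the other `K - 1` states
#' (no self-transitions), mirroring the quasi-stable ~60-120 ms alternation
#' of scalp topographies.
#'
#' @param K Number of states.
#' @param mean_durations_ms Scalar or length-K vector of mean dwell times (ms).
#' @param fs Sampling rate (Hz).
#' @param n_samples Total sequence length in samples.
#' @param seed Integer seed.
#'
#' @return Integer vector of length `n_samples` with labels in `1:K`.
#' @export
simulate_state_sequence <- function(K, mean_durations_ms, fs, n_samples,
                                    seed = 1L) {
  mean_durations_ms <- rep_len(mean_durations_ms, K)
  mean_samples <- mean_durations_ms * fs / 1000
  if (any(mean_samples < 2)) {
    abort("Every mean duration must be at least 2 samples at this sampling rate.")
  }
  if (K == 1L) return(rep(1L, n_samples))
  withr::with_seed(as.integer(seed), {
    labels <- integer(n_samples)
    pos <- 1L
    state <- sample.int(K, 1L)
    while (pos <= n_samples) {
      dwell <- stats::rgeom(1L, prob = 1 / mean_samples[state]) + 1L
      end <- min(pos + dwell - 1L, n_samples)
      labels[pos:end] <- state
      pos <- end + 1L
      state <- sample(setdiff(seq_len(K), state), 1L)
    }
    labels
  })
}

#' Simulate EEG with planted microstate structure
#'
#' Each sample is the active prototype scaled by a rectified-sine amplitude
#' envelope, plus spatially white Gaussian sensor noise:
#' `v(t) = amplitude * |sin(2 pi f_env t)| * map[label(t)] + noise(t)`.
#' The envelope maxima create GFP peaks every half cycle (50 ms at 10 Hz).
#' Noise is average-referenced and scaled so that the RMS of the noiseless
#' signal divided by the noise RMS equals `snr` (both measured after average
#' referencing). `snr = Inf` disables noise.
#'
#' @param prototypes A [prototype_set()].
#' @param labels Integer labels per sample (values in `1:K`); the length must
#'   divide evenly into 2-s epochs at `fs`.
#' @param fs Sampling rate (Hz).
#' @param snr Signal-to-noise ratio (> 0; `Inf` for noise-free).
#' @param env_freq_hz Envelope frequency (default 10 Hz, the dominant
#'   oscillation whose half-cycles produce GFP maxima).
#' @param amplitude_uv Envelope peak amplitude in microvolts (default 15).
#' @param seed Integer seed.
#'
#' @return A list: `epochs` (average-referenced [epoched_eeg()]) and `truth`
#'   (prototypes, per-sample labels, snr, envelope parameters, seed).
#' @export
simulate_microstate_eeg <- function(prototypes, labels, fs, snr = 4,
                                    env_freq_hz = 10, amplitude_uv = 15,
                                    seed = 1L) {
  stopifnot(inherits(prototypes, "prototype_set"))
  if (!is.infinite(snr) && snr <= 0) abort("`snr` must be positive.")
  n <- length(labels)
  n_per <- as.integer(round(2 * fs))
  if (n %% n_per != 0L) {
    abort("`labels` length must divide evenly into 2-second epochs.")
  }
  t_sec <- (seq_len(n) - 1L) / fs
  env <- amplitude_uv * abs(sin(2 * pi * env_freq_hz * t_sec))
  signal <- prototypes$maps[labels, , drop = FALSE] * env   # n x C
  signal <- t(signal)                                       # C x n
  if (is.infinite(snr)) {
    data <- signal
  } else {
    withr::with_seed(as.integer(seed), {
      noise <- matrix(rnorm(length(signal)), nrow = nrow(signal))
    })
    noise <- sweep(noise, 2, colMeans(noise))   # average-reference the noise
    sig_rms <- sqrt(mean(signal^2))
    noise_rms <- sqrt(mean(noise^2))
    noise <- noise * (sig_rms / snr / noise_rms)
    data <- signal + noise
  }
  rec <- eeg_recording(
    data, fs,
    channel_names = prototypes$channel_names,
    positions = make_montage(max(nrow(data), 4L), seed = 1L)[seq_len(nrow(data)), ],
    reference = "average"
  )
  ep <- epoch_recording(rec, 2.0)
  ep <- apply_average_reference(ep)
  list(
    epochs = ep,
    truth = list(
      prototypes = prototypes, labels = labels, snr = snr,
      env_freq_hz = env_freq_hz, amplitude_uv = amplitude_uv,
      fs = fs, seed = as.integer(seed)
    )
  )
}

#' One-call synthetic microstate subject
#'
#' Convenience wrapper bundling montage, prototype, label-sequence and EEG
#' generation with the package's default study conditions: 64 channels,
#' 500 Hz, 120 s, K = 5 planted maps with pairwise |corr| <= 0.6 and 80 ms
#' mean dwell.
#'
#' @param n_channels,fs,duration_s,K,mean_durations_ms,snr,max_abs_corr
#'   Simulation parameters; see the underlying generators.
#' @param seed Integer seed controlling every random draw.
#' @return As [simulate_microstate_eeg()], with `truth$mean_durations_ms` set.
#' @export
simulate_subject_eeg <- function(n_channels = 64L, fs = 500, duration_s = 120,
                                 K = 5L, mean_durations_ms = 80, snr = 4,
                                 max_abs_corr = 0.6, seed = 1L) {
  seed <- as.integer(seed)
  pos <- make_montage(n_channels, seed = seed)
  protos <- make_prototype_maps(pos, K, seed = seed + 1L,
                                max_abs_corr = max_abs_corr)
  n <- as.integer(round(fs * duration_s))
  labels <- simulate_state_sequence(K, mean_durations_ms, fs, n, seed = seed + 2L)
  out <- simulate_microstate_eeg(protos, labels, fs, snr = snr, seed = seed + 3L)
  out$epochs$positions <- pos
  out$truth$mean_durations_ms <- rep_len(mean_durations_ms, K)
  out
}

# maps serialized as a list of channel-ordered vectors may come back from
# jsonlite as an already-simplified K x C matrix
maps_from_json <- function(x) {
  if (is.matrix(x)) return(unname(as.matrix(x)))
  do.call(rbind, lapply(x, as.numeric))
}

#' Planted dynamics under the measurement convention
#'
#' The minimum-duration smoothing rule is part of the measurement: with
#' geometric dwell times a sizeable share of true runs falls below the
#' threshold, so the post-smoothing duration/occurrence statistics estimate
#' the smoothed planted sequence, not the raw dwell parameter. This helper
#' computes those reference values by backfitting the noise-free signal with
#' the true prototypes and applying the identical smoothing, giving the
#' ground truth that a noisy-pipeline estimate should be compared against.
#'
#' @param truth The `truth` element from [simulate_microstate_eeg()] /
#'   [simulate_subject_eeg()].
#' @param smooth_min_duration_ms Smoothing threshold used by the pipeline
#'   under test (default 30 ms; 0 gives raw planted dynamics).
#'
#' @return The per-class statistics tibble of [compute_microstate_stats()]
#'   for the planted sequence.
#' @export
planted_dynamics <- function(truth, smooth_min_duration_ms = 30) {
  sim <- simulate_microstate_eeg(
    truth$prototypes, truth$labels, truth$fs, snr = Inf,
    env_freq_hz = truth$env_freq_hz, amplitude_uv = truth$amplitude_uv
  )
  seq_lab <- backfit_labels(sim$epochs, truth$prototypes)
  # noise-free backfit reproduces the planted labels except at exact
  # envelope zeros; stamp the planted labels to make the reference exact
  seq_lab$labels <- matrix(as.integer(truth$labels),
                           nrow = nrow(seq_lab$labels), byrow = TRUE)
  seq_lab <- smooth_short_segments(seq_lab, smooth_min_duration_ms)
  compute_microstate_stats(seq_lab, compute_gfp(sim$epochs), truth$prototypes)
}

#' Serialize ground truth to JSON
#'
#' Prototypes are written as channel-ordered value lists and labels as a
#' run-length encoding.
#'
#' @param truth The `truth` element from [simulate_microstate_eeg()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  rle_labels <- rle(as.integer(truth$labels))
  obj <- list(
    prototypes = apply(truth$prototypes$maps, 1, identity, simplify = FALSE),
    channel_names = truth$prototypes$channel_names,
    labels_rle = list(lengths = rle_labels$lengths, values = rle_labels$values),
    snr = truth$snr, env_freq_hz = truth$env_freq_hz,
    amplitude_uv = truth$amplitude_uv, fs = truth$fs, seed = truth$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth written by [write_ground_truth()]
#' @param path JSON path.
#' @return A ground-truth list with expanded labels.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  maps <- maps_from_json(obj$prototypes)
  list(
    prototypes = prototype_set(maps, channel_names = obj$channel_names,
                               normalize = FALSE),
    labels = inverse.rle(structure(
      list(lengths = as.integer(obj$labels_rle$lengths),
           values = as.integer(obj$labels_rle$values)),
      class = "rle"
    )),
    snr = obj$snr, env_freq_hz = obj$env_freq_hz,
    amplitude_uv = obj$amplitude_uv, fs = obj$fs, seed = obj$seed
  )
}
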