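#' Backfit prototypes to continuous epochs
#'
#' Labels every sample with the prototype of maximal absolute spatial
#' correlation (polarity-invariant). The full per-sample |correlation|
#' matrix is retained because minimum-duration smoothing needs the
#' next-best alternatives. Ties go to the lowest class index.
#'
#' @param ep An average-referenced [epoched_eeg()].
#' @param prototypes A [prototype_set()] with matching channel order.
#'
#' @return A `label_sequence`: list with `labels` (epochs x samples integer
#'   matrix), `corr` (epochs x samples x K array of |spatial correlation|)
#'   and `fs`.
#' @export
backfit_labels <- function(ep, prototypes) {
  stopifnot(inherits(ep, "epoched_eeg"), inherits(prototypes, "prototype_set"))
  d <- dim(ep$epochs)
  if (d[2] != ncol(prototypes$maps)) {
    abort(sprintf("Channel mismatch: data has %d channels, prototypes %d.",
                  d[2], ncol(prototypes$maps)))
  }
  X <- flatten_epochs(ep)                       # C x T (epoch-major)
  X <- sweep(X, 2, colMeans(X))
  norms <- sqrt(colSums(X^2))
  norms[norms < 1e-15] <- Inf
  R <- abs(t(prototypes$maps %*% X) / norms)    # T x K
  lab <- max.col(R, ties.method = "first")
  K <- prototypes$K
  T_per <- d[3]
  labels <- matrix(lab, nrow = d[1], ncol = T_per, byrow = TRUE)
  corr <- aperm(array(R, dim = c(T_per, d[1], K)), c(2, 1, 3))
  structure(list(labels = labels, corr = corr, fs = ep$fs),
            class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d epochs x %d samples, K = %d @ %g Hz\n",
              nrow(x$labels), ncol(x$labels), dim(x$corr)[3], x$fs))
  invisible(x)
}

# smooth one epoch; lab: labels, AC: samples x K |corr| matrix
smooth_epoch <- function(lab, AC, th_samples) {
  S <- length(lab)
  K <- ncol(AC)
  if (S < 1L || th_samples <= 1) return(lab)
  rejected <- matrix(FALSE, nrow = S, ncol = K)
  locked <- rep(FALSE, S)
  eps <- 1e-9
  max_rounds <- 10L * S
  for (round in seq_len(max_rounds)) {
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- which(r$lengths < th_samples - eps)
    if (!length(bad)) break
    # shortest sub-threshold run first (ties: leftmost)
    b <- bad[which.min(r$lengths[bad])]
    idx <- starts[b]:ends[b]
    if (all(locked[idx])) {
      # exhausted: merge into the neighbouring run with the higher boundary
      # correlation (mean |corr| of the run's samples under the neighbour label)
      left_lab <- if (b > 1L) r$values[b - 1L] else NA_integer_
      right_lab <- if (b < length(r$values)) r$values[b + 1L] else NA_integer_
      if (is.na(left_lab) && is.na(right_lab)) break
      score <- function(l) if (is.na(l)) -Inf else mean(AC[idx, l])
      lab[idx] <- if (score(left_lab) >= score(right_lab)) left_lab else right_lab
      next
    }
    movable <- idx[!locked[idx]]
    rejected[cbind(movable, lab[movable])] <- TRUE
    for (s in movable) {
      open <- which(!rejected[s, ])
      if (!length(open)) {
        locked[s] <- TRUE
        rejected[s, ] <- TRUE
        rejected[s, lab[s]] <- FALSE        # keep the current label
        next
      }
      lab[s] <- open[which.max(AC[s, open])]
    }
  }
  lab
}

#' Reject and relabel sub-threshold microstate segments
#'
#' Iteratively removes runs shorter than `min_duration_ms` within each epoch
#' (shortest first): each sample of a rejected run is reassigned to its
#' next-best prototype by absolute spatial correlation -- equivalently,
#' minimal global map dissimilarity `GMD = sqrt(2 (1 - |corr|))` -- excluding
#' labels already rejected for that sample. If every label is exhausted for a
#' run it is merged into the neighbouring run with the higher boundary
#' correlation. Epochs are smoothed independently; runs never span epochs.
#'
#' @param seq A `label_sequence` from [backfit_labels()].
#' @param min_duration_ms Minimum accepted run duration (default 30 ms).
#'
#' @return The smoothed `label_sequence`.
#' @export
smooth_short_segments <- function(seq, min_duration_ms = 30) {
  stopifnot(inherits(seq, "label_sequence"))
  if (min_duration_ms <= 0) return(seq)
  th <- min_duration_ms * seq$fs / 1000
  out <- seq
  for (e in seq_len(nrow(seq$labels))) {
    out$labels[e, ] <- smooth_epoch(seq$labels[e, ], seq$corr[e, , ], th)
  }
  out
}

#' Temporal microstate statistics
#'
#' Computes, per class: mean uninterrupted run duration (ms), occurrence
#' (runs per second of labeled data), coverage (fraction of samples) and the
#' per-class GEV. Runs are counted within epochs only. With
#' `count_truncated = TRUE` (default) runs touching an epoch boundary are
#' included, which keeps `occurrence * duration / 1000 = coverage` an exact
#' identity; `FALSE` drops boundary-truncated runs from duration/occurrence.
#'
#' @param seq A (smoothed) `label_sequence`.
#' @param gfp The matching `gfp_series` (for the GEV weighting).
#' @param prototypes The [prototype_set()] used for backfitting.
#' @param count_truncated Count epoch-boundary-truncated runs.
#'
#' @return A tibble with one row per class: `class_index`, `n_runs`,
#'   `duration_ms` (NA when the class never occurs), `occurrence_per_s`,
#'   `coverage`, `gev`. The epoch count is attached as attribute
#'   `retained_segments`.
#' @export
compute_microstate_stats <- function(seq, gfp, prototypes,
                                     count_truncated = TRUE) {
  stopifnot(inherits(seq, "label_sequence"), inherits(gfp, "gfp_series"))
  K <- dim(seq$corr)[3]
  n_ep <- nrow(seq$labels)
  S <- ncol(seq$labels)
  total_s <- n_ep * S / seq$fs
  run_values <- integer(0); run_lengths <- integer(0); run_interior <- logical(0)
  for (e in seq_len(n_ep)) {
    r <- rle(seq$labels[e, ])
    nr <- length(r$values)
    interior <- rep(TRUE, nr)
    interior[1L] <- FALSE
    interior[nr] <- FALSE
    run_values <- c(run_values, r$values)
    run_lengths <- c(run_lengths, r$lengths)
    run_interior <- c(run_interior, interior)
  }
  if (!count_truncated) {
    run_values <- run_values[run_interior]
    run_lengths <- run_lengths[run_interior]
  }
  # GEV weighting from the stored per-sample correlations
  gfp_flat <- as.vector(t(gfp$values))
  lab_flat <- as.vector(t(seq$labels))
  corr_flat <- matrix(aperm(seq$corr, c(2, 1, 3)), ncol = K)
  r_assigned <- corr_flat[cbind(seq_along(lab_flat), lab_flat)]
  denom <- sum(gfp_flat^2)
  stats <- purrr::map_dfr(seq_len(K), function(k) {
    runs_k <- run_lengths[run_values == k]
    n_runs <- length(runs_k)
    tibble::tibble(
      class_index = k,
      n_runs = n_runs,
      duration_ms = if (n_runs) mean(runs_k) * 1000 / seq$fs else NA_real_,
      occurrence_per_s = n_runs / total_s,
      coverage = sum(lab_flat == k) / length(lab_flat),
      gev = sum((gfp_flat[lab_flat == k] * r_assigned[lab_flat == k])^2) / denom
    )
  })
  attr(stats, "retained_segments") <- n_ep
  stats
}

#' ±z-SD outlier trimming of a feature table
#'
#' Within each (cohort, visit, class, feature) group, removes records whose
#' value lies more than `z` standard deviations from the group mean (mean and
#' SD computed on the full group including the candidate). Groups with fewer
#' than 3 records are skipped with a warning; zero-SD groups remove nothing.
#'
#' @param table A feature tibble (see [persist_features()] for columns).
#' @param z SD multiplier (default 3).
#'
#' @return List with `table` (trimmed tibble) and `report` (per-group removal
#'   counts).
#' @export
trim_feature_outliers <- function(table, z = 3) {
  validate_features(table)
  grouped <- table |>
    dplyr::group_by(.data$cohort, .data$visit, .data$class, .data$feature)
  small <- grouped |> dplyr::filter(dplyr::n() < 3L)
  if (nrow(small)) {
    warn(sprintf("%d group(s) with fewer than 3 records skipped by outlier trimming.",
                 nrow(dplyr::distinct(small |> dplyr::select(dplyr::group_cols())))))
  }
  flagged <- grouped |>
    dplyr::mutate(
      .n = dplyr::n(),
      .mu = mean(.data$value),
      .sd = sd(.data$value),
      .out = .data$.n >= 3L & .data$.sd > 0 &
        abs(.data$value - .data$.mu) > .env$z * .data$.sd
    ) |>
    dplyr::ungroup()
  report <- flagged |>
    dplyr::group_by(.data$cohort, .data$visit, .data$class, .data$feature) |>
    dplyr::summarise(n_removed = sum(.data$.out), n_total = dplyr::n(),
                     .groups = "drop")
  list(
    table = flagged |> dplyr::filter(!.data$.out) |>
      dplyr::select(-dplyr::all_of(c(".n", ".mu", ".sd", ".out"))),
    report = report
  )
}
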