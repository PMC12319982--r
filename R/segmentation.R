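#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the average-referenced scalp
#' map at sample t: `sqrt(mean((v_c - mean_c(v))^2))`. High-GFP samples carry
#' the cleanest topographies and are the input to clustering.
#'
#' @param ep An average-referenced [epoched_eeg()].
#' @return A `gfp_series`: list with `values` (epochs x samples matrix, in
#'   microvolts) and `fs`.
#' @export
compute_gfp <- function(ep) {
  stopifnot(inherits(ep, "epoched_eeg"))
  d <- dim(ep$epochs)
  if (d[2] < 2L) abort("GFP needs at least 2 channels.")
  means <- apply(ep$epochs, c(1, 3), mean)
  centered <- ep$epochs - aperm(array(means, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  values <- sqrt(apply(centered^2, c(1, 3), mean))
  structure(list(values = values, fs = ep$fs), class = "gfp_series")
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("<gfp_series> %d epochs x %d samples @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$fs))
  invisible(x)
}

# interior local maxima of a numeric vector: a (plateau of) value(s)
# strictly greater than both neighbouring values; the plateau's first sample
# is returned (exact ties occur when a smooth envelope straddles two samples)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  r <- rle(v)
  nr <- length(r$values)
  if (nr < 3L) return(integer(0))
  starts <- cumsum(r$lengths) - r$lengths + 1L
  j <- 2:(nr - 1L)
  peaks <- j[r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]]
  starts[peaks]
}

#' Extract topographies at GFP peaks
#'
#' Finds strict interior local maxima of the GFP within each epoch, greedily
#' thins them from the highest GFP downward so that surviving peaks in the
#' same epoch are at least `min_distance_ms` apart, and (if more survive than
#' requested) returns a seeded uniform subsample of `n_peaks`.
#'
#' @param gfp A `gfp_series` from [compute_gfp()].
#' @param ep The matching average-referenced [epoched_eeg()].
#' @param min_distance_ms Minimum separation between retained peaks (ms).
#' @param n_peaks Maximum number of peaks returned (default 1000).
#' @param seed Seed for the subsampling step.
#'
#' @return A `peak_set`: list with `maps` (n x channels), `gfp_at_peak`,
#'   `epoch`, `sample`, `channel_names`.
#' @export
pick_gfp_peaks <- function(gfp, ep, min_distance_ms = 10, n_peaks = 1000L,
                           seed = 1L) {
  stopifnot(inherits(gfp, "gfp_series"), inherits(ep, "epoched_eeg"))
  if (!all(dim(gfp$values) == dim(ep$epochs)[c(1, 3)])) {
    abort("GFP series is not aligned with the epoched EEG.")
  }
  min_dist <- min_distance_ms * gfp$fs / 1000
  epochs <- integer(0); samples <- integer(0)
  for (e in seq_len(nrow(gfp$values))) {
    cand <- local_maxima(gfp$values[e, ])
    if (!length(cand)) next
    ord <- cand[order(gfp$values[e, cand], decreasing = TRUE)]
    kept <- integer(0)
    for (s in ord) {
      if (!length(kept) || all(abs(kept - s) >= min_dist)) kept <- c(kept, s)
    }
    kept <- sort(kept)
    epochs <- c(epochs, rep.int(e, length(kept)))
    samples <- c(samples, kept)
  }
  if (!length(samples)) abort("No GFP peaks found.")
  if (length(samples) > n_peaks) {
    pick <- withr::with_seed(as.integer(seed),
                             sort(sample.int(length(samples), n_peaks)))
    epochs <- epochs[pick]; samples <- samples[pick]
  }
  maps <- t(vapply(seq_along(samples),
                   function(i) ep$epochs[epochs[i], , samples[i]],
                   numeric(dim(ep$epochs)[2])))
  structure(
    list(maps = maps, gfp_at_peak = gfp$values[cbind(epochs, samples)],
         epoch = epochs, sample = samples, channel_names = ep$channel_names),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak maps x %d channels\n",
              nrow(x$maps), ncol(x$maps)))
  invisible(x)
}

# one modified-k-means pass from a given initialization; V rows are maps
mkms_run <- function(V, K, init_idx, max_iter, tol) {
  n <- nrow(V); C <- ncol(V)
  A <- V[init_idx, , drop = FALSE]
  A <- A / sqrt(rowSums(A^2))
  total_sq <- sum(V^2)
  sigma2_prev <- Inf
  converged <- FALSE
  labels <- integer(n)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    proj <- V %*% t(A)                       # n x K
    labels <- max.col(proj^2, ties.method = "first")
    explained <- proj[cbind(seq_len(n), labels)]^2
    # empty clusters re-seeded from the worst-fit map
    resid <- rowSums(V^2) - explained
    for (k in seq_len(K)) {
      if (!any(labels == k)) {
        worst <- which.max(resid)
        labels[worst] <- k
        explained[worst] <- sum(V[worst, ] * A[k, ])^2
        resid[worst] <- 0
      }
    }
    sigma2 <- (total_sq - sum(explained)) / (n * (C - 1))
    trace <- c(trace, sigma2)
    if (is.finite(sigma2_prev) &&
        abs(sigma2_prev - sigma2) <= tol * max(sigma2_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    sigma2_prev <- sigma2
    for (k in seq_len(K)) {
      members <- which(labels == k)
      if (length(members) == 1L) {
        a <- V[members, ]
      } else {
        S <- crossprod(V[members, , drop = FALSE])
        a <- eigen(S, symmetric = TRUE)$vectors[, 1]
      }
      A[k, ] <- a / sqrt(sum(a^2))
    }
  }
  proj <- V %*% t(A)
  labels <- max.col(proj^2, ties.method = "first")
  explained <- proj[cbind(seq_len(n), labels)]^2
  sigma2 <- (total_sq - sum(explained)) / (n * (C - 1))
  list(A = A, labels = labels, sigma2 = sigma2, converged = converged,
       trace = trace)
}

#' Polarity-invariant modified k-means over peak topographies
#'
#' Clusters GFP-peak maps into K microstate prototypes. Assignment uses the
#' squared projection onto unit-norm prototypes (so a map and its sign flip
#' are equivalent) and each prototype update is the principal eigenvector of
#' its members' scatter matrix. Restarted stochastically; the restart with
#' the smallest residual noise variance wins.
#'
#' @param peaks A `peak_set` from [pick_gfp_peaks()].
#' @param K Number of microstate classes.
#' @param n_restarts Stochastic restarts (default 50).
#' @param max_iter Iteration cap per restart (default 1000).
#' @param tol Relative convergence tolerance on the residual variance.
#' @param seed Integer seed for the restart initializations.
#'
#' @return A `segmentation_fit`: prototypes, peak labels, `sigma2_hat`,
#'   per-class and total `gev`, `cv`, restart diagnostics.
#' @export
modified_kmeans <- function(peaks, K, n_restarts = 50L, max_iter = 1000L,
                            tol = 1e-7, seed = 1L) {
  stopifnot(inherits(peaks, "peak_set"))
  V <- peaks$maps
  n <- nrow(V); C <- ncol(V)
  if (K > n) abort(sprintf("K = %d exceeds the number of peak maps (%d).", K, n))
  inits <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_restarts), function(i) sample.int(n, K))
  })
  best <- NULL
  conv <- logical(n_restarts)
  for (r in seq_len(n_restarts)) {
    run <- mkms_run(V, K, inits[[r]], max_iter, tol)
    conv[r] <- run$converged
    if (is.null(best) || run$sigma2 < best$sigma2) best <- run
  }
  best$sigma2 <- max(0, best$sigma2)    # guard against -eps round-off
  protos <- prototype_set(best$A, channel_names = peaks$channel_names,
                          normalize = TRUE)
  gev <- compute_gev(V, protos, best$labels, gfp = peaks$gfp_at_peak)
  cv <- if (C - 1L > K) compute_cv_criterion(best$sigma2, C, K) else NA_real_
  structure(
    list(
      prototypes = protos, labels = best$labels, sigma2_hat = best$sigma2,
      gev = gev$total, gev_per_class = gev$per_class, cv = cv, K = K,
      n_restarts_used = n_restarts, converged = conv
    ),
    class = "segmentation_fit"
  )
}

#' @export
print.segmentation_fit <- function(x, ...) {
  cat(sprintf(
    "<segmentation_fit> K = %d | sigma2 = %.4g | GEV = %.3f | CV = %.4g (%d/%d restarts converged)\n",
    x$K, x$sigma2_hat, x$gev, x$cv, sum(x$converged), length(x$converged)
  ))
  invisible(x)
}

#' Global explained variance of a labeling
#'
#' `GEV_total = sum_t (GFP_t * r_t)^2 / sum_t GFP_t^2` where `r_t` is the
#' spatial Pearson correlation between map t and its assigned prototype;
#' the per-class GEV restricts the numerator to that class, so the class
#' values sum to the total.
#'
#' @param maps n x channels matrix of average-referenced maps (or a
#'   `peak_set`).
#' @param prototypes A [prototype_set()].
#' @param labels Integer assignment of each map to a prototype.
#' @param gfp Optional per-map GFP; computed from the maps when missing.
#'
#' @return List with `total` and `per_class` (length K).
#' @export
compute_gev <- function(maps, prototypes, labels, gfp = NULL) {
  if (inherits(maps, "peak_set")) {
    if (is.null(gfp)) gfp <- maps$gfp_at_peak
    maps <- maps$maps
  }
  stopifnot(inherits(prototypes, "prototype_set"))
  centered <- maps - rowMeans(maps)
  if (is.null(gfp)) gfp <- sqrt(rowMeans(centered^2))
  denom <- sum(gfp^2)
  if (denom <= 0) abort("Zero total GFP; GEV undefined.")
  norms <- sqrt(rowSums(centered^2))
  norms[norms < 1e-15] <- Inf
  r <- rowSums(centered * prototypes$maps[labels, , drop = FALSE]) / norms
  contrib <- (gfp * r)^2
  per_class <- vapply(seq_len(prototypes$K),
                      function(k) sum(contrib[labels == k]) / denom, numeric(1))
  list(total = sum(contrib) / denom, per_class = per_class)
}

#' Cross-validation criterion for the number of microstate classes
#'
#' `CV = sigma2_hat * ((C - 1) / (C - 1 - K))^2`; the penalty grows with K so
#' a lower CV marks the better trade-off between fit and complexity.
#'
#' @param sigma2_hat Residual noise variance from [modified_kmeans()].
#' @param C Number of channels.
#' @param K Number of classes.
#' @return The CV value.
#' @export
compute_cv_criterion <- function(sigma2_hat, C, K) {
  if (C - 1 <= K) abort("CV criterion undefined: C - 1 must exceed K.")
  sigma2_hat * ((C - 1) / (C - 1 - K))^2
}

#' Fit a range of cluster numbers
#'
#' Runs [modified_kmeans()] for each K in `k_range` on the same peak set and
#' tabulates the fit criteria. A single forced K (e.g. `k_range = 4`)
#' reproduces a fixed-class sensitivity analysis.
#'
#' @param peaks A `peak_set`.
#' @param k_range Integer vector of K values (default `2:8`).
#' @param n_restarts,max_iter,tol,seed Passed to [modified_kmeans()].
#'
#' @return A tibble with one row per K: `K`, `sigma2_hat`, `gev`, `cv`,
#'   `converged` fraction, and the full fit in the `fit` list-column.
#' @export
scan_k <- function(peaks, k_range = 2:8, n_restarts = 50L, max_iter = 1000L,
                   tol = 1e-7, seed = 1L) {
  stopifnot(inherits(peaks, "peak_set"))
  if (any(k_range < 2L) || any(k_range >= nrow(peaks$maps))) {
    abort("`k_range` must lie within [2, number of peak maps).")
  }
  fits <- lapply(seq_along(k_range), function(i) {
    modified_kmeans(peaks, k_range[i], n_restarts = n_restarts,
                    max_iter = max_iter, tol = tol, seed = seed + i - 1L)
  })
  tibble::tibble(
    K = as.integer(k_range),
    sigma2_hat = vapply(fits, `[[`, numeric(1), "sigma2_hat"),
    gev = vapply(fits, `[[`, numeric(1), "gev"),
    cv = vapply(fits, `[[`, numeric(1), "cv"),
    converged = vapply(fits, function(f) mean(f$converged), numeric(1)),
    fit = fits
  )
}
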