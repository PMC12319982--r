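test_that("GFP equals the spatial standard deviation", {
  const <- epoched_eeg(array(7, dim = c(1, 4, 10)), fs = 5, epoch_length_s = 2,
                       positions = make_montage(4, 1))
  expect_equal(compute_gfp(const)$values, matrix(0, 1, 10))

  two <- epoched_eeg(array(c(1, -1), dim = c(1, 2, 10)), fs = 5,
                     epoch_length_s = 2, positions = make_montage(4, 1)[1:2, ])
  expect_equal(compute_gfp(two)$values, matrix(1, 1, 10))

  ep <- apply_average_reference(epoch_recording(tiny_recording(n_ch = 5L), 2))
  gfp <- compute_gfp(ep)
  # brute-force formula at a handful of samples
  for (pick in list(c(1, 1), c(2, 500), c(3, 999))) {
    v <- ep$epochs[pick[1], , pick[2]]
    expect_equal(gfp$values[pick[1], pick[2]], sqrt(mean((v - mean(v))^2)))
  }
})

test_that("peak picking finds local maxima and thins like the brute-force oracle", {
  # monotone GFP within an epoch: no interior peaks
  mono <- epoched_eeg(
    array(rep(seq_len(100), each = 2) * c(1, -1), dim = c(1, 2, 100)),
    fs = 50, epoch_length_s = 2, positions = make_montage(4, 1)[1:2, ]
  )
  expect_error(pick_gfp_peaks(compute_gfp(mono), mono), "No GFP peaks")

  # |sin| envelope at 10 Hz, 500 Hz: peaks every ~25 samples
  sub <- simulate_subject_eeg(n_channels = 16, fs = 500, duration_s = 4,
                              K = 3, snr = Inf, seed = 5)
  gfp <- compute_gfp(sub$epochs)
  pk <- pick_gfp_peaks(gfp, sub$epochs, min_distance_ms = 10, n_peaks = 1e6)
  per_epoch <- split(pk$sample, pk$epoch)
  expect_true(all(unlist(lapply(per_epoch, function(s) diff(s) >= 5))))

  # greedy thinning equals an O(n^2) check: every dropped local maximum is
  # within min-distance of a kept, higher peak
  noisy <- simulate_subject_eeg(n_channels = 16, fs = 500, duration_s = 4,
                                K = 3, snr = 1, seed = 6)
  g2 <- compute_gfp(noisy$epochs)
  pk2 <- pick_gfp_peaks(g2, noisy$epochs, min_distance_ms = 10, n_peaks = 1e6)
  for (e in seq_len(nrow(g2$values))) {
    cand <- microdev:::local_maxima(g2$values[e, ])
    kept <- pk2$sample[pk2$epoch == e]
    dropped <- setdiff(cand, kept)
    for (s in dropped) {
      near <- kept[abs(kept - s) < 5]
      expect_true(any(g2$values[e, near] >= g2$values[e, s]))
    }
  }

  # subsampling to n_peaks is seeded and deterministic
  pk3 <- pick_gfp_peaks(g2, noisy$epochs, n_peaks = 50, seed = 42)
  pk4 <- pick_gfp_peaks(g2, noisy$epochs, n_peaks = 50, seed = 42)
  expect_equal(nrow(pk3$maps), 50L)
  expect_identical(pk3$sample, pk4$sample)
})

test_that("modified k-means nails noise-free two-class data", {
  pos <- make_montage(16, seed = 1)
  a1 <- drop(pos %*% c(1, 0, 0)); a1 <- a1 - mean(a1); a1 <- a1 / sqrt(sum(a1^2))
  a2 <- drop(pos %*% c(0, 1, 0)); a2 <- a2 - mean(a2); a2 <- a2 / sqrt(sum(a2^2))
  a2 <- a2 - sum(a2 * a1) * a1; a2 <- a2 / sqrt(sum(a2^2))   # exact orthogonality
  signs <- rep(c(1, -1), 10)
  V <- rbind(t(sapply(signs, function(s) s * 2 * a1)),
             t(sapply(signs, function(s) s * 3 * a2)))
  peaks <- structure(list(maps = V, gfp_at_peak = sqrt(rowMeans(V^2)),
                          epoch = rep(1L, 40), sample = seq_len(40),
                          channel_names = paste0("ch", 1:16)),
                     class = "peak_set")
  fit <- modified_kmeans(peaks, 2, n_restarts = 5, seed = 1)
  expect_lt(fit$sigma2_hat, 1e-20)
  expect_equal(fit$gev, 1, tolerance = 1e-12)
  m <- match_prototypes(fit$prototypes, prototype_set(rbind(a1, a2), normalize = FALSE))
  expect_equal(m$abs_corr, c(1, 1), tolerance = 1e-10)
})

test_that("restarted k-means attains the exhaustive-enumeration optimum", {
  withr::with_seed(33, {
    for (i in 1:20) {
      V <- matrix(rnorm(6 * 4), nrow = 6)
      V <- V - rowMeans(V)
      peaks <- structure(list(maps = V, gfp_at_peak = sqrt(rowMeans(V^2)),
                              epoch = rep(1L, 6), sample = 1:6,
                              channel_names = paste0("ch", 1:4)),
                         class = "peak_set")
      fit <- modified_kmeans(peaks, 2, n_restarts = 20, seed = i)
      oracle <- exhaustive_kmeans_sigma2(V, 2)
      expect_lt(abs(fit$sigma2_hat - oracle), 1e-8 + 1e-6 * oracle)
    }
  })
})

test_that("clustering is polarity invariant and scale equivariant", {
  sub <- simulate_subject_eeg(n_channels = 16, fs = 250, duration_s = 16,
                              K = 3, snr = 5, seed = 8)
  gfp <- compute_gfp(sub$epochs)
  peaks <- pick_gfp_peaks(gfp, sub$epochs, n_peaks = 200, seed = 1)
  fit <- modified_kmeans(peaks, 3, n_restarts = 10, seed = 2)

  flipped <- peaks
  sgn <- rep(c(1, -1), length.out = nrow(peaks$maps))
  flipped$maps <- peaks$maps * sgn
  fit_f <- modified_kmeans(flipped, 3, n_restarts = 10, seed = 2)
  expect_equal(fit_f$sigma2_hat, fit$sigma2_hat, tolerance = 1e-10)
  expect_identical(fit_f$labels, fit$labels)
  expect_equal(fit_f$gev, fit$gev, tolerance = 1e-10)

  scaled <- peaks
  scaled$maps <- peaks$maps * 3
  scaled$gfp_at_peak <- peaks$gfp_at_peak * 3
  fit_s <- modified_kmeans(scaled, 3, n_restarts = 10, seed = 2)
  expect_identical(fit_s$labels, fit$labels)
  expect_equal(fit_s$sigma2_hat, 9 * fit$sigma2_hat, tolerance = 1e-8)
  expect_equal(fit_s$gev, fit$gev, tolerance = 1e-10)
})

test_that("residual variance is non-increasing across iterations", {
  sub <- simulate_subject_eeg(n_channels = 16, fs = 250, duration_s = 16,
                              K = 4, snr = 3, seed = 13)
  peaks <- pick_gfp_peaks(compute_gfp(sub$epochs), sub$epochs,
                          n_peaks = 300, seed = 1)
  run <- microdev:::mkms_run(peaks$maps, 4, init_idx = c(1, 5, 9, 13),
                             max_iter = 200, tol = 0)
  expect_true(all(diff(run$trace) <= 1e-12))
})

test_that("GEV matches its definition and splits by class", {
  pos <- make_montage(8, seed = 2)
  protos <- make_prototype_maps(pos, 2, seed = 3)
  # three toy maps with known scalings/rotations
  V <- rbind(2 * protos$maps[1, ],
             -5 * protos$maps[2, ],
             3 * protos$maps[1, ] + 0.5 * protos$maps[2, ])
  labels <- c(1L, 2L, 1L)
  gev <- compute_gev(V, protos, labels)
  # hand expansion
  gfp <- sqrt(rowMeans((V - rowMeans(V))^2))
  r <- sapply(1:3, function(i) spatial_corr(V[i, ], protos$maps[labels[i], ]))
  expect_equal(gev$total, sum((gfp * r)^2) / sum(gfp^2), tolerance = 1e-12)
  expect_equal(sum(gev$per_class), gev$total, tolerance = 1e-12)

  # perfect fit and orthogonal fit
  expect_equal(compute_gev(rbind(protos$maps[1, ] * 4, -protos$maps[2, ]),
                           protos, c(1L, 2L))$total, 1, tolerance = 1e-12)
  orth <- protos$maps[2, ] - sum(protos$maps[2, ] * protos$maps[1, ]) * protos$maps[1, ]
  expect_equal(compute_gev(rbind(orth), prototype_set(rbind(protos$maps[1, ]),
                                                      normalize = FALSE),
                           1L)$total, 0, tolerance = 1e-12)
})

test_that("CV criterion follows the penalized-residual formula", {
  expect_equal(compute_cv_criterion(0, 10, 4), 0)
  expect_equal(compute_cv_criterion(1, 5, 2), 4)
  cvs <- sapply(2:8, function(k) compute_cv_criterion(1, 64, k))
  expect_true(all(diff(cvs) > 0))
  expect_error(compute_cv_criterion(1, 3, 2), "undefined")
})

test_that("scan_k supports a forced K and GEV grows with K", {
  sub <- simulate_subject_eeg(n_channels = 16, fs = 250, duration_s = 24,
                              K = 5, snr = 4, seed = 21)
  peaks <- pick_gfp_peaks(compute_gfp(sub$epochs), sub$epochs,
                          n_peaks = 300, seed = 1)
  forced <- scan_k(peaks, 4, n_restarts = 10, seed = 1)
  expect_equal(nrow(forced), 1L)
  expect_equal(forced$fit[[1]]$prototypes$K, 4L)

  scan <- scan_k(peaks, 2:6, n_restarts = 10, seed = 1)
  expect_true(all(diff(scan$gev) >= -1e-3))
})
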