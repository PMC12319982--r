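make_test_protos <- function(n_ch = 8L, K = 3L, seed = 2L) {
  make_prototype_maps(make_montage(n_ch, seed = 1), K, seed = seed,
                      max_abs_corr = 0.6)
}

ep_from_maps <- function(maps_by_sample, fs) {
  # maps_by_sample: samples x channels matrix -> one epoch
  arr <- array(t(maps_by_sample), dim = c(ncol(maps_by_sample),
                                          nrow(maps_by_sample), 1))
  arr <- aperm(arr, c(3, 1, 2))
  epoched_eeg(arr, fs = fs, epoch_length_s = nrow(maps_by_sample) / fs,
              positions = make_montage(max(ncol(maps_by_sample), 4), 1)[seq_len(ncol(maps_by_sample)), ],
              reference = "average")
}

test_that("backfitting is polarity- and scale-invariant with tie-breaks to the lowest index", {
  protos <- make_test_protos()
  # a sample equal to prototype 2 scaled by -3 gets label 2 with |corr| 1
  m <- rbind(-3 * protos$maps[2, ], 5 * protos$maps[1, ])
  ep <- ep_from_maps(m, fs = 1)
  seq_lab <- backfit_labels(ep, protos)
  expect_equal(seq_lab$labels[1, ], c(2L, 1L))
  expect_equal(seq_lab$corr[1, 1, 2], 1, tolerance = 1e-10)

  # a map orthogonal to every prototype records near-zero correlations
  orth <- qr.Q(qr(t(rbind(protos$maps, 1))), complete = TRUE)[, 5]
  ep0 <- ep_from_maps(rbind(orth, orth), fs = 1)
  s0 <- backfit_labels(ep0, protos)
  expect_lt(max(s0$corr[1, 1, ]), 1e-8)
  # an exactly degenerate (zero) sample ties every class: lowest index wins
  epz <- ep_from_maps(rbind(rep(0, 8), protos$maps[1, ]), fs = 1)
  sz <- backfit_labels(epz, protos)
  expect_equal(sz$labels[1, 1], 1L)

  expect_error(backfit_labels(ep, make_test_protos(n_ch = 6L)), "mismatch")
})

test_that("backfit labels equal the brute-force per-sample argmax", {
  protos <- make_test_protos(n_ch = 10L, K = 4L)
  withr::with_seed(7, {
    m <- matrix(rnorm(50 * 10), nrow = 50)
  })
  m <- m - rowMeans(m)
  ep <- ep_from_maps(m, fs = 25)
  seq_lab <- backfit_labels(ep, protos)
  brute <- apply(m, 1, function(v) {
    which.max(abs(apply(protos$maps, 1, function(a) spatial_corr(v, a))))
  })
  expect_equal(as.vector(seq_lab$labels[1, ]), as.integer(brute))

  # global sign and scale of the data leave labels unchanged
  ep2 <- ep_from_maps(-0.25 * m, fs = 25)
  expect_identical(backfit_labels(ep2, protos)$labels, seq_lab$labels)
})

test_that("smoothing rejects short runs to the next-best label", {
  fs <- 500
  protos <- make_test_protos(n_ch = 8L, K = 2L)
  labels <- c(rep(1L, 100), rep(2L, 2), rep(1L, 100))
  corr <- array(0, dim = c(1, 202, 2))
  corr[1, , 1] <- 0.8
  corr[1, , 2] <- 0.3
  corr[1, 101:102, 2] <- 0.9       # B wins there, but A is second best
  seq_lab <- structure(
    list(labels = matrix(labels, nrow = 1), corr = corr, fs = fs),
    class = "label_sequence"
  )
  sm <- smooth_short_segments(seq_lab, 30)
  expect_equal(as.vector(sm$labels), rep(1L, 202))

  # no-op cases: all runs already long enough, or a vacuous threshold
  long <- structure(
    list(labels = matrix(rep(c(1L, 2L), each = 101), nrow = 1),
         corr = corr, fs = fs),
    class = "label_sequence"
  )
  expect_identical(smooth_short_segments(long, 30)$labels, long$labels)
  expect_identical(smooth_short_segments(seq_lab, 0)$labels, seq_lab$labels)
})

test_that("after smoothing no within-epoch run is below the threshold", {
  fs <- 250
  th_samples <- 30 * fs / 1000
  for (seed in 1:25) {
    seq_lab <- random_label_sequence(n_epochs = 3, n_samples = 200, K = 4,
                                     fs = fs, seed = seed)
    sm <- smooth_short_segments(seq_lab, 30)
    for (e in 1:3) {
      runs <- rle(sm$labels[e, ])
      expect_true(all(runs$lengths >= th_samples))
    }
  }
})

test_that("microstate statistics follow the run-length definitions", {
  fs <- 500
  protos <- make_test_protos(n_ch = 8L, K = 2L)
  gfp1 <- structure(list(values = matrix(1, 1, 1000), fs = fs), class = "gfp_series")

  one_class <- structure(
    list(labels = matrix(1L, 1, 1000),
         corr = array(1, dim = c(1, 1000, 2)), fs = fs),
    class = "label_sequence"
  )
  st <- compute_microstate_stats(one_class, gfp1, protos)
  expect_equal(st$duration_ms[1], 2000)
  expect_equal(st$occurrence_per_s[1], 0.5)
  expect_equal(st$coverage[1], 1)
  # absent class: missing duration, zero occurrence/coverage
  expect_true(is.na(st$duration_ms[2]))
  expect_equal(st$occurrence_per_s[2], 0)
  expect_equal(st$coverage[2], 0)

  alternating <- structure(
    list(labels = matrix(rep(rep(c(1L, 2L), each = 125), 4), 1, 1000),
         corr = array(1, dim = c(1, 1000, 2)), fs = fs),
    class = "label_sequence"
  )
  st2 <- compute_microstate_stats(alternating, gfp1, protos)
  expect_equal(st2$duration_ms, c(250, 250))
  expect_equal(st2$occurrence_per_s, c(2, 2))
  expect_equal(st2$coverage, c(0.5, 0.5))
})

test_that("coverage and occurrence-duration identities hold for random sequences", {
  for (seed in 1:30) {
    seq_lab <- random_label_sequence(n_epochs = 4, n_samples = 150, K = 5,
                                     fs = 250, seed = 100 + seed)
    gfp <- structure(
      list(values = matrix(withr::with_seed(seed, runif(600, 0.5, 2)), 4, 150),
           fs = 250),
      class = "gfp_series"
    )
    protos <- make_test_protos(n_ch = 8L, K = 5L)
    st <- compute_microstate_stats(seq_lab, gfp, protos)
    expect_equal(sum(st$coverage), 1, tolerance = 1e-9)
    present <- !is.na(st$duration_ms)
    expect_equal(st$occurrence_per_s[present] * st$duration_ms[present] / 1000,
                 st$coverage[present], tolerance = 1e-12)
  }
})

test_that("boundary-truncated runs can be excluded on request", {
  seq_lab <- structure(
    list(labels = matrix(c(rep(1L, 10), rep(2L, 30), rep(1L, 10)), 1, 50),
         corr = array(1, dim = c(1, 50, 2)), fs = 50),
    class = "label_sequence"
  )
  gfp <- structure(list(values = matrix(1, 1, 50), fs = 50), class = "gfp_series")
  protos <- make_test_protos(n_ch = 8L, K = 2L)
  st_all <- compute_microstate_stats(seq_lab, gfp, protos)
  st_int <- compute_microstate_stats(seq_lab, gfp, protos, count_truncated = FALSE)
  expect_equal(st_all$n_runs, c(2L, 1L))
  expect_equal(st_int$n_runs, c(0L, 1L))
  expect_true(is.na(st_int$duration_ms[1]))
})
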