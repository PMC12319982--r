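# Independent oracles and small fixture builders used across test files.

# tiny deterministic recording: channels x samples sine mixtures
tiny_recording <- function(n_ch = 5L, fs = 500, duration_s = 10, seed = 11L,
                           amplitude = 20) {
  withr::with_seed(seed, {
    t_sec <- (seq_len(fs * duration_s) - 1) / fs
    data <- t(sapply(seq_len(n_ch), function(i) {
      amplitude * sin(2 * pi * (4 + i) * t_sec + runif(1, 0, 2 * pi)) +
        rnorm(length(t_sec))
    }))
  })
  eeg_recording(data, fs, positions = make_montage(max(n_ch, 4L), seed = 2L)[seq_len(n_ch), ])
}

# brute-force residual-variance oracle: best sigma2 over every labeling of
# the maps into K clusters, prototypes set to principal eigenvectors
exhaustive_kmeans_sigma2 <- function(V, K) {
  n <- nrow(V); C <- ncol(V)
  grid <- do.call(expand.grid, rep(list(seq_len(K)), n))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- as.integer(grid[g, ])
    if (length(unique(lab)) < K) next
    expl <- 0
    for (k in seq_len(K)) {
      Vk <- V[lab == k, , drop = FALSE]
      a <- eigen(crossprod(Vk), symmetric = TRUE)$vectors[, 1]
      expl <- expl + sum((Vk %*% a)^2)
    }
    s2 <- (sum(V^2) - expl) / (n * (C - 1))
    if (s2 < best) best <- s2
  }
  best
}

# exhaustive best one-to-one matching by total |corr| over all permutations
exhaustive_match <- function(found, reference) {
  A <- abs(found$maps %*% t(reference$maps))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_score <- -Inf
  for (p in perms(seq_len(nrow(A)))) {
    s <- sum(A[cbind(seq_len(nrow(A)), p)])
    if (s > best_score) { best_score <- s; best <- p }
  }
  list(assignment = best, score = best_score)
}

# direct marginal multivariate-normal log-likelihood of a random-intercept
# model: block-diagonal covariance sigma_u2 * J + sigma_e2 * I per subject
lmm_loglik_oracle <- function(table, beta, sigma_u2, sigma_e2, form) {
  X <- stats::model.matrix(form, data = table)
  resid <- table$value - drop(X %*% beta)
  ll <- 0
  for (s in unique(table$subject)) {
    idx <- which(table$subject == s)
    m <- length(idx)
    Sigma <- sigma_u2 * matrix(1, m, m) + sigma_e2 * diag(m)
    r <- resid[idx]
    ll <- ll - 0.5 * (m * log(2 * pi) + determinant(Sigma)$modulus +
                        drop(r %*% solve(Sigma, r)))
  }
  as.numeric(ll)
}

# random label-sequence fixture with a consistent |corr| array
random_label_sequence <- function(n_epochs, n_samples, K, fs, seed) {
  withr::with_seed(seed, {
    labels <- matrix(sample.int(K, n_epochs * n_samples, replace = TRUE),
                     nrow = n_epochs)
    corr <- array(runif(n_epochs * n_samples * K), dim = c(n_epochs, n_samples, K))
    # make the stored labels the argmax so backfit-consistency holds
    for (e in seq_len(n_epochs)) {
      idx <- cbind(seq_len(n_samples), labels[e, ])
      corr[e, , ][idx] <- 1
    }
  })
  structure(list(labels = labels, corr = corr, fs = fs),
            class = "label_sequence")
}

three_models <- c("linear", "quadratic", "log")

fit_three <- function(features, ...) {
  lapply(setNames(nm = three_models), function(m) {
    fit_random_intercept_lmm(features, age_model = m, ...)
  })
}
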