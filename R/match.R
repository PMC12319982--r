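# Compact O(n^3) Hungarian algorithm (shortest augmenting paths with
# potentials). `cost` must have nrow <= ncol; returns, for each row, the
# assigned column.
hungarian_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) abort("hungarian_assign() needs nrow(cost) <= ncol(cost).")
  u <- numeric(n); v <- numeric(m)
  p <- integer(m + 1L)     # p[j + 1]: row matched to column j (0 = virtual col)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          if (j > 0L) v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  assignment
}

#' Canonical microstate class templates
#'
#' Idealized dipolar scalp fields for the seven classes reported in infant
#' and adult microstate work, built by projecting the montage onto fixed
#' dipole orientations (x right, y anterior, z superior): A right-frontal to
#' left-posterior, B left-frontal to right-posterior, C anterior-posterior,
#' D fronto-central to occipital, E centro-parietal radial, F
#' left-lateralized, G right-lateralized. Matching against these templates is
#' advisory -- an automated surrogate for visual class labeling.
#'
#' @param positions Channels x 3 montage (see [make_montage()]).
#' @param classes Subset of `c("A","B","C","D","E","F","G")`.
#'
#' @return A [prototype_set()]; row names carry the class letters.
#' @export
canonical_templates <- function(positions,
                                classes = c("A", "B", "C", "D", "E", "F", "G")) {
  orientations <- rbind(
    A = c(1, 1, 0),
    B = c(-1, 1, 0),
    C = c(0, 1, 0.2),
    D = c(0, 1, 1),
    E = c(0, -0.3, 1),
    F = c(-1, 0, 0.3),
    G = c(1, 0, 0.3)
  )
  classes <- match.arg(classes, c("A", "B", "C", "D", "E", "F", "G"),
                       several.ok = TRUE)
  o <- orientations[classes, , drop = FALSE]
  o <- o / sqrt(rowSums(o^2))
  maps <- o %*% t(as.matrix(positions))
  ps <- prototype_set(maps, normalize = TRUE)
  rownames(ps$maps) <- classes
  ps$class_labels <- classes
  ps
}

#' Match found prototypes to a reference set
#'
#' Optimal one-to-one assignment between two prototype sets maximizing the
#' summed absolute spatial correlation (Hungarian algorithm on `1 - |corr|`
#' costs; polarity-invariant). When the sets differ in size, surplus maps are
#' reported as `"unclassified"`.
#'
#' @param found A [prototype_set()] (e.g. from [modified_kmeans()]).
#' @param reference A [prototype_set()]; if it carries `class_labels` (see
#'   [canonical_templates()]) those letters name the matches.
#'
#' @return A tibble: `found_map`, `reference_map` (index or NA), `label`,
#'   `abs_corr`, and the `sign` aligning the found map to the reference.
#' @export
match_prototypes <- function(found, reference) {
  stopifnot(inherits(found, "prototype_set"), inherits(reference, "prototype_set"))
  if (ncol(found$maps) != ncol(reference$maps)) {
    abort("Channel count mismatch between found and reference prototypes.")
  }
  R <- found$maps %*% t(reference$maps)        # signed correlations
  A <- abs(R)
  swap <- found$K > reference$K
  cost <- 1 - (if (swap) t(A) else A)
  assign_rows <- hungarian_assign(cost)
  ref_labels <- reference$class_labels %||% as.character(seq_len(reference$K))
  if (!swap) {
    ref_idx <- assign_rows
  } else {
    ref_idx <- rep(NA_integer_, found$K)
    ref_idx[assign_rows] <- seq_len(reference$K)
  }
  tibble::tibble(
    found_map = seq_len(found$K),
    reference_map = ref_idx,
    label = ifelse(is.na(ref_idx), "unclassified", ref_labels[ref_idx]),
    abs_corr = ifelse(is.na(ref_idx), NA_real_,
                      A[cbind(seq_len(found$K), ref_idx)]),
    sign = ifelse(is.na(ref_idx), NA_real_,
                  sign(R[cbind(seq_len(found$K), ref_idx)]))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
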