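# Run `fun()` under a seeded RNG, restoring the caller's RNG state after.
with_seed <- function(seed, fun) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

# Precompute FFT machinery shared by every assignment pass: padded FFTs of
# all beats (columns), their energies, and the row indices of valid linear
# lags within the circular length-nfft correlation.
sbd_precompute <- function(z) {
  m <- ncol(z)
  nfft <- stats::nextn(2L * m - 1L, 2L)
  fz <- stats::mvfft(rbind(t(z), matrix(0, nfft - m, nrow(z))))
  lag_rows <- c((nfft - m + 2L):nfft, 1L:m)     # lags -(m-1) .. (m-1)
  lags <- seq(-(m - 1L), m - 1L)
  list(m = m, nfft = nfft, fz = Conj(fz), energy = rowSums(z * z),
       lag_rows = lag_rows, lags = lags)
}

# SBD of every beat in `pre` against one centroid. Returns distances and the
# optimal shifts (tie rule: smallest |shift|, negative before positive).
sbd_batch <- function(centroid, pre, want_shift = FALSE) {
  fc <- stats::fft(c(centroid, rep(0, pre$nfft - pre$m)))
  cc <- Re(stats::mvfft(fc * pre$fz, inverse = TRUE)) / pre$nfft
  cc <- cc[pre$lag_rows, , drop = FALSE]        # (2m-1) x n, row = lag
  denom <- sqrt(sum(centroid^2) * pre$energy)
  best <- apply(cc, 2L, max)
  dist <- 1 - best / denom
  shift <- NULL
  if (want_shift) {
    ord <- order(abs(pre$lags), pre$lags)       # tie preference order
    shift <- integer(ncol(cc))
    for (b in seq_len(ncol(cc))) {
      cand <- which(cc[, b] >= best[b] - 1e-12 * max(1, abs(best[b])))
      shift[b] <- pre$lags[cand[which.min(match(cand, ord))]]
    }
  }
  list(distance = dist, shift = shift)
}

#' Initialize K-shape centroids
#'
#' Selects `k` distinct beats uniformly at random (without replacement)
#' under a seeded generator and copies them as the initial centroids, one
#' per cluster.
#'
#' @param z Matrix of z-normalized beats, one row per beat.
#' @param k Number of clusters.
#' @param seed Integer RNG seed.
#' @return `k x L` matrix of initial centroids.
#' @export
init_centroids <- function(z, k, seed) {
  if (nrow(z) < k) stop("fewer beats (", nrow(z), ") than clusters (", k, ")")
  idx <- with_seed(seed, function() sample.int(nrow(z), k))
  z[idx, , drop = FALSE]
}

#' Assign beats to the nearest centroid under SBD
#'
#' @param z Matrix of z-normalized beats (rows).
#' @param centroids `k x L` centroid matrix.
#' @return List with `labels` (1-based cluster index, ties to the lowest
#'   index) and `distance` (SBD to the assigned centroid).
#' @export
kshape_assign <- function(z, centroids) {
  pre <- sbd_precompute(z)
  k <- nrow(centroids)
  D <- matrix(0, nrow(z), k)
  for (j in seq_len(k)) D[, j] <- sbd_batch(centroids[j, ], pre)$distance
  labels <- max.col(-D, ties.method = "first")
  list(labels = labels, distance = D[cbind(seq_len(nrow(z)), labels)],
       dist_matrix = D)
}

#' Shape extraction: the centroid update of K-shape
#'
#' Computes the cluster shape that maximizes the summed squared normalized
#' cross-correlation to the members: members are aligned to the current
#' centroid at their optimal SBD shift, and the new centroid is the leading
#' eigenvector of the centered Gram matrix \eqn{M = Q^T S Q} (with `S` the
#' sum of outer products of aligned members and `Q` the centering
#' projector), solved by power iteration seeded at the current centroid with
#' a LAPACK fallback. The eigenvector's sign is chosen to minimize SBD to
#' the current centroid, and the result is z-normalized.
#'
#' @param members Matrix of member beats (rows, z-normalized).
#' @param current_centroid Current centroid vector (length L).
#' @return New centroid vector, zero mean and unit (population) SD.
#' @export
shape_extraction <- function(members, current_centroid) {
  if (is.null(dim(members))) members <- matrix(members, nrow = 1L)
  L <- ncol(members)
  pre <- sbd_precompute(members)
  sh <- sbd_batch(current_centroid, pre, want_shift = TRUE)
  A <- members
  for (i in seq_len(nrow(A))) {
    if (sh$shift[i] != 0L) A[i, ] <- align_to(members[i, ], sh$shift[i])
  }
  S <- crossprod(A)
  S <- sweep(S, 2L, colMeans(S))
  M <- sweep(S, 1L, rowMeans(S))

  v <- current_centroid - mean(current_centroid)
  nv <- sqrt(sum(v^2))
  v <- if (nv > 0) v / nv else {
    e <- numeric(L); e[1L] <- 1; e - mean(e)
  }
  converged <- FALSE
  for (it in seq_len(500L)) {
    w <- as.numeric(M %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- w / nw
    if (sum((w - v)^2) < 1e-24 || sum((w + v)^2) < 1e-24) {
      v <- w
      converged <- TRUE
      break
    }
    v <- w
  }
  if (!converged) v <- eigen(M, symmetric = TRUE)$vectors[, 1L]

  plus <- sbd(v, current_centroid)$distance
  minus <- sbd(-v, current_centroid)$distance
  if (minus < plus) v <- -v
  znormalize(v)$z
}

#' Fit a K-shape clustering model
#'
#' Runs the K-shape loop (random beat initialization, SBD assignment, shape
#' extraction, repeat until the label vector stops changing or `max_iter`
#' is reached) `n_init` times with sub-seeds `seed + r` for restart `r`, and
#' keeps the run with minimal inertia — the total squared SBD of each beat
#' to its cluster centroid. An empty cluster arising during iteration is
#' reseeded with the beat farthest from its own centroid (with a warning),
#' so `k` never shrinks silently.
#'
#' Production defaults follow the long-term ECG pipeline: `k = 12`,
#' `n_init = 100`, `max_iter = 100`.
#'
#' @param z Matrix of z-normalized beats, one row per beat.
#' @param k Number of clusters.
#' @param n_init Number of random restarts.
#' @param max_iter Maximum iterations per restart.
#' @param seed Integer seed; restart `r` uses `seed + r`.
#' @return A `"kshape_model"`: list with `k`, `centroids` (`k x L`),
#'   `labels` (1-based, per row of `z`), `distance` (SBD to own centroid),
#'   `inertia`, `inertia_history`, `n_iter`, `seed`, `cluster_sizes`.
#' @export
kshape_fit <- function(z, k = 12L, n_init = 100L, max_iter = 100L, seed = 0L) {
  if (nrow(z) < k) stop("fewer beats than clusters")
  best <- NULL
  for (r in seq_len(n_init)) {
    run <- kshape_run(z, k, max_iter, seed + r)
    if (is.null(best) || run$inertia < best$inertia) best <- run
  }
  best$seed <- seed
  best$n_init <- n_init
  class(best) <- "kshape_model"
  best
}

kshape_run <- function(z, k, max_iter, sub_seed) {
  centroids <- init_centroids(z, k, sub_seed)
  labels <- rep(NA_integer_, nrow(z))
  inertia_history <- numeric(0)
  asg <- NULL
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    asg <- kshape_assign(z, centroids)
    inertia_history <- c(inertia_history, sum(asg$distance^2))
    if (identical(asg$labels, labels)) break
    labels <- asg$labels
    for (j in seq_len(k)) {
      idx <- which(labels == j)
      if (length(idx) == 0L) {
        warning("empty cluster ", j, " reseeded with the farthest beat")
        far <- which.max(asg$distance)
        centroids[j, ] <- z[far, ]
      } else {
        centroids[j, ] <- shape_extraction(z[idx, , drop = FALSE],
                                           centroids[j, ])
      }
    }
  }
  labels <- asg$labels
  list(k = k, centroids = centroids, labels = labels,
       distance = asg$distance,
       inertia = sum(asg$distance^2),
       inertia_history = inertia_history, n_iter = n_iter,
       cluster_sizes = tabulate(labels, nbins = k))
}

#' @export
print.kshape_model <- function(x, ...) {
  cat(sprintf("kshape_model: k=%d, %d beats, inertia %.4f after %d iteration(s)\n",
              x$k, length(x$labels), x$inertia, x$n_iter))
  cat("cluster sizes:", paste(x$cluster_sizes, collapse = " "), "\n")
  invisible(x)
}

#' Exclude beats in clusters below a minimum size
#'
#' Beats in clusters with fewer than `min_size` members are marked excluded
#' (label set to `NA`); the cluster list itself is preserved, and excluded
#' clusters simply produce no template downstream.
#'
#' @param model A `"kshape_model"`.
#' @param min_size Minimum cluster size retained (default 5; a cluster of
#'   exactly `min_size` is kept).
#' @return The model with `labels` updated and `small_clusters` recorded.
#' @export
filter_small_clusters <- function(model, min_size = 5L) {
  small <- which(model$cluster_sizes < min_size)
  if (length(small)) {
    model$labels[model$labels %in% small] <- NA_integer_
  }
  model$small_clusters <- small
  model
}

#' Recompute model inertia from labels and centroids
#'
#' Audit helper: the stored inertia must equal the total squared SBD of each
#' labeled beat to its centroid.
#'
#' @param model A `"kshape_model"`.
#' @param z Beat matrix the model was fitted on.
#' @return Numeric inertia.
#' @export
recompute_inertia <- function(model, z) {
  tot <- 0
  for (i in seq_len(nrow(z))) {
    lab <- model$labels[i]
    if (is.na(lab)) next
    tot <- tot + sbd(z[i, ], model$centroids[lab, ])$distance^2
  }
  tot
}
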