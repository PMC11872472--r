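# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive: they re-derive expected values from definitions, never
# from the implementation under test.

# Eq.-style cross-correlation by naive double loop (independent of the
# package's direct/FFT routes).
oracle_cross_correlation <- function(x, y) {
  m <- length(x)
  vapply(seq(-(m - 1L), m - 1L), function(k) {
    s <- 0
    for (l in seq_len(m)) {
      if (l + k >= 1L && l + k <= m) s <- s + x[l + k] * y[l]
    }
    s
  }, numeric(1L))
}

oracle_sbd <- function(x, y) {
  cc <- oracle_cross_correlation(x, y)
  1 - max(cc) / sqrt(sum(x^2) * sum(y^2))
}

# Enumerate every monotone contiguous warping path from (1,1) to (m,n),
# returning the minimal sqrt-sum-of-squares cost overall and per path
# length. Feasible for m + n <= ~12.
oracle_dtw_enum <- function(x, y) {
  m <- length(x)
  n <- length(y)
  best <- new.env()
  best$overall <- Inf
  best$by_len <- rep(Inf, m + n - 1L)
  walk <- function(i, j, cost, len) {
    cost <- cost + (x[i] - y[j])^2
    if (i == m && j == n) {
      best$overall <- min(best$overall, cost)
      best$by_len[len] <- min(best$by_len[len], cost)
      return(invisible())
    }
    if (i < m && j < n) walk(i + 1L, j + 1L, cost, len + 1L)
    if (i < m) walk(i + 1L, j, cost, len + 1L)
    if (j < n) walk(i, j + 1L, cost, len + 1L)
  }
  walk(1L, 1L, 0, 1L)
  list(dtw = sqrt(best$overall),
       ldtw = function(max_len) {
         sqrt(min(best$by_len[seq_len(min(max_len, m + n - 1L))]))
       })
}

# Adjusted Rand index between two labelings.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  nij <- comb2(as.vector(tab))
  ai <- comb2(rowSums(tab))
  bj <- comb2(colSums(tab))
  nn <- comb2(sum(tab))
  expected <- ai * bj / nn
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# Two-way ANOVA mean squares through stats::aov (independent decomposition
# route for the ICC check).
oracle_icc_mean_squares <- function(ratings) {
  n <- nrow(ratings)
  k <- ncol(ratings)
  long <- data.frame(score = as.vector(ratings),
                     subject = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(score ~ subject + rater, data = long))[[1L]][
    , "Mean Sq"]
  list(msr = ms[1L], msc = ms[2L], mse = ms[3L])
}

oracle_icc_2_1 <- function(ratings) {
  n <- nrow(ratings)
  k <- ncol(ratings)
  ms <- oracle_icc_mean_squares(ratings)
  (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
}

# 6-subject, 2-rater fixture; expected values frozen from an independent
# reference implementation before the build.
icc_fixture <- function() {
  cbind(ref = c(402, 415, 398, 430, 421, 409),
        cand = c(405, 412, 401, 436, 418, 407))
}
ICC_FIXTURE_EXPECTED <- 0.957955299845
ICC_FIXTURE_OFFSET25_EXPECTED <- 0.300750312630

# Three well-separated beat shapes (z-normalized), plus noisy copies.
make_class_beats <- function(n_per_class, noise_sd = 0.05, L = 400L,
                             seed = 1L, classes = c("normal", "inverted",
                                                    "biphasic")) {
  fs <- 250
  protos <- lapply(classes, function(cl) {
    render_beat(beat_shape_spec(cl), rr_ms = 1600, fs = fs)$samples[
      seq_len(L) + 20L]
  })
  set.seed(seed)
  z <- matrix(0, n_per_class * length(classes), L)
  lab <- integer(nrow(z))
  r <- 0L
  for (c_i in seq_along(protos)) {
    for (j in seq_len(n_per_class)) {
      r <- r + 1L
      z[r, ] <- znormalize(protos[[c_i]] + rnorm(L, 0, noise_sd))$z
      lab[r] <- c_i
    }
  }
  list(z = z, labels = lab)
}
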