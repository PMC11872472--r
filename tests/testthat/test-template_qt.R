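# minimal hand-built clustering object for unit-level checks
fake_clustering <- function(z, labels, centroids, fs = 250) {
  n <- nrow(z)
  bs <- list(fs = fs, L = ncol(z), samples = z, z = z,
             beats = data.frame(beat_index = seq_len(n) - 1L,
                                r_peak = 100L * seq_len(n),
                                rr_prev = 1000, rr_next = 1000,
                                excluded = FALSE, exclusion_reason = "none",
                                cluster = labels))
  class(bs) <- "beat_set"
  model <- structure(list(k = nrow(centroids), centroids = centroids,
                          labels = labels, cluster_sizes =
                            tabulate(labels, nrow(centroids)),
                          small_clusters = integer(0)),
                     class = "kshape_model")
  structure(list(bs = bs, model = model, rows = seq_len(n)),
            class = "qt_clustering")
}

test_that("template selection takes the DTW argmin with lowest-index ties", {
  set.seed(21)
  L <- 60L
  cen <- znormalize(rnorm(L))$z
  z <- rbind(znormalize(cen + rnorm(L, 0, 0.5))$z,
             cen,                                   # exact member
             znormalize(cen + rnorm(L, 0, 0.5))$z)
  cl <- fake_clustering(z, rep(1L, 3L), rbind(cen))
  cl <- select_templates(cl)
  expect_length(cl$templates, 1L)
  expect_identical(cl$templates[[1L]]$beat_index, 1L)   # 0-based index of row 2
  expect_equal(dtw(cen, cl$templates[[1L]]$z)$distance, 0, tolerance = 1e-12)

  # brute-force argmin agreement on a 20-member cluster
  z20 <- t(vapply(1:20, function(i) znormalize(cen + rnorm(L, 0, 0.3))$z,
                  numeric(L)))
  cl2 <- select_templates(fake_clustering(z20, rep(1L, 20L), rbind(cen)))
  brute <- which.min(vapply(1:20, function(i) dtw(cen, z20[i, ])$distance,
                            numeric(1L)))
  expect_identical(cl2$templates[[1L]]$beat_index, brute - 1L)

  # exact duplicates tie at distance 0: lowest beat index wins
  zdup <- rbind(cen, cen, znormalize(cen + rnorm(L, 0, 0.4))$z)
  cl3 <- select_templates(fake_clustering(zdup, rep(1L, 3L), rbind(cen)))
  expect_identical(cl3$templates[[1L]]$beat_index, 0L)
})

test_that("outlier exclusion uses the interpolated 90th percentile with caps", {
  set.seed(22)
  L <- 30L
  cen <- znormalize(rnorm(L))$z
  z <- matrix(rep(cen, 10), 10, L, byrow = TRUE)
  cl <- fake_clustering(z, rep(1L, 10L), rbind(cen))
  cl <- select_templates(cl)
  cl$bs$beats$dtw_dist <- as.numeric(1:10)       # crafted distances
  out <- exclude_outlier_beats(cl)
  excl <- out$bs$beats[out$bs$beats$excluded, ]
  expect_identical(nrow(excl), 1L)
  expect_identical(excl$dtw_dist, 10)            # 90th pct = 9.1; 9 retained
  expect_identical(excl$exclusion_reason, "dtw_outlier")

  # all-equal distances: degenerate, none excluded
  cl$bs$beats$dtw_dist <- rep(2.5, 10)
  cl$bs$beats$excluded <- FALSE
  expect_identical(sum(exclude_outlier_beats(cl)$bs$beats$excluded), 0L)

  # 5-member cluster: at most ceil(0.5) = 1 exclusion
  cl5 <- fake_clustering(z[1:5, ], rep(1L, 5L), rbind(cen))
  cl5 <- select_templates(cl5)
  cl5$bs$beats$dtw_dist <- c(1, 5, 5, 5, 5)
  out5 <- exclude_outlier_beats(cl5)
  expect_identical(sum(out5$bs$beats$excluded), 1L)
})

test_that("fiducial registration validates rows and attaches indices", {
  set.seed(23)
  L <- 400L
  z <- rbind(znormalize(rnorm(L))$z)
  cl <- select_templates(fake_clustering(z, 1L, z))
  reg <- data.frame(cluster_id = 1L, qrs_onset = 30L, t_end = 130L)
  cl <- register_fiducials(cl, reg)
  t <- cl$templates[[1L]]
  expect_identical(t$qrs_onset, 30L)
  expect_identical(t$t_end, 130L)
  expect_equal(compute_qt(t$qrs_onset, t$t_end, 250), 400)  # template QT

  expect_error(register_fiducials(cl, data.frame(cluster_id = 9L,
                                                 qrs_onset = 1L, t_end = 2L)),
               "cluster\\(s\\): 1")
  expect_error(register_fiducials(cl, data.frame(cluster_id = 1L,
                                                 qrs_onset = 50L, t_end = 50L)),
               "invalid fiducials")
})

test_that("fiducial transfer follows the latest-onset / earliest-end rule", {
  tmpl <- structure(list(cluster_id = 1L, qrs_onset = 2L, t_end = 5L),
                    class = "qt_template")
  diagonal <- cbind(i = 0:6, j = 0:6)
  expect_identical(transfer_fiducials(tmpl, diagonal),
                   c(qrs_onset = 2L, t_end = 5L))

  # onset linked to beats 5,6,7 -> latest (7); t_end to 40,41 -> earliest (40)
  path <- cbind(i = c(0, 1, 2, 2, 2, 3, 4, 5, 5, 6),
                j = c(0, 4, 5, 6, 7, 8, 20, 40, 41, 42))
  expect_identical(transfer_fiducials(tmpl, path)[["qrs_onset"]], 7)
  expect_identical(transfer_fiducials(tmpl, path)[["t_end"]], 40)

  unreg <- structure(list(qrs_onset = NA_integer_, t_end = NA_integer_),
                     class = "qt_template")
  expect_error(transfer_fiducials(unreg, diagonal), "not registered")
})

test_that("compute_qt and bazett follow their closed forms", {
  expect_equal(compute_qt(30, 130, 250), 400)
  expect_equal(compute_qt(20, 140, 250), 480)
  expect_true(is.na(compute_qt(30, 30, 250)))
  expect_equal(bazett(400, 1000), 400)
  expect_equal(bazett(400, 640), 500)
  expect_equal(bazett(350, 1440), 291.67, tolerance = 0.01 / 291)
  expect_error(bazett(400, 0), "> 0")
  # monotone decreasing in RR for fixed QT
  rr <- seq(400, 1900, by = 100)
  expect_true(all(diff(bazett(380, rr)) < 0))
})

test_that("a beat that IS the template measures the registered QT exactly", {
  set.seed(24)
  L <- 80L
  tz <- znormalize(cumsum(rnorm(L)))$z
  cl <- select_templates(fake_clustering(rbind(tz, tz), c(1L, 1L),
                                         rbind(tz), fs = 250))
  cl <- register_fiducials(cl, data.frame(cluster_id = 1L, qrs_onset = 10L,
                                          t_end = 60L))
  meas <- measure_qt(cl)
  expect_equal(meas$qrs_onset, c(10L, 10L))
  expect_equal(meas$t_end, c(60L, 60L))
  expect_equal(meas$qt_ms, rep((60 - 10) / 250 * 1000, 2L))
  expect_equal(meas$qtcb_ms, meas$qt_ms / sqrt(1000 / 1000))
})
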