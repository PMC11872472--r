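make_measurements <- function(r_peaks, qt_ms, excluded = FALSE) {
  n <- length(r_peaks)
  data.frame(beat_index = seq_len(n) - 1L, r_peak = r_peaks,
             cluster_id = 1L, qrs_onset = 10L, t_end = 110L,
             rr_prev_ms = 1000, qt_ms = qt_ms, qtcb_ms = qt_ms,
             excluded = rep_len(excluded, n),
             exclusion_reason = ifelse(rep_len(excluded, n), "rr_short",
                                       "none"))
}

ref_annotations <- function(r_peaks, qt_samples) {
  structure(data.frame(r_peak = r_peaks, qrs_onset = r_peaks - 10L,
                       t_end = r_peaks - 10L + qt_samples),
            class = c("expert_annotations", "data.frame"))
}

test_that("pair_beats matches by R-peak proximity within tolerance", {
  fs <- 250
  r <- seq(500L, by = 250L, length.out = 15L)
  ref <- ref_annotations(r, 100L)          # 400 ms reference QT
  cand <- make_measurements(r, 398)
  p <- pair_beats(ref, cand, fs)
  expect_identical(nrow(p), 15L)
  expect_true(all(p$reference_ms == 400))
  expect_true(all(p$candidate_ms == 398))

  # candidate shifted by 200 ms (50 samples): no matches within 150 ms
  cand2 <- make_measurements(r + 50L, 398)
  expect_error(pair_beats(ref[1L, ], cand2, fs), "no beats matched")

  # excluded candidate beats never match
  cand3 <- make_measurements(r, 398, excluded = TRUE)
  expect_error(pair_beats(ref, cand3, fs), "no beats matched")

  # 15 reference beats, more candidate beats: at most 15 pairs
  cand4 <- make_measurements(seq(250L, by = 125L, length.out = 60L), 402)
  p4 <- pair_beats(ref, cand4, fs)
  expect_lte(nrow(p4), 15L)
})

test_that("icc_2_1 matches the ANOVA mean-squares oracle and frozen fixture", {
  fx <- icc_fixture()
  r <- icc_2_1(fx)
  expect_equal(r$icc, oracle_icc_2_1(fx), tolerance = 1e-9)
  expect_equal(r$icc, ICC_FIXTURE_EXPECTED, tolerance = 1e-9)
  expect_equal(round(r$ci, 2), c(0.74, 0.99), tolerance = 0.011)

  ms <- oracle_icc_mean_squares(fx)
  expect_equal(r$msr, ms$msr, tolerance = 1e-9)
  expect_equal(r$msc, ms$msc, tolerance = 1e-9)
  expect_equal(r$mse, ms$mse, tolerance = 1e-9)

  off <- fx
  off[, 2L] <- off[, 2L] + 25
  r_off <- icc_2_1(off)
  expect_equal(r_off$icc, ICC_FIXTURE_OFFSET25_EXPECTED, tolerance = 1e-9)
  expect_equal(r_off$icc, oracle_icc_2_1(off), tolerance = 1e-9)

  set.seed(61)
  for (i in 1:10) {
    m <- matrix(rnorm(30, 400, 20), 15L, 2L)
    expect_equal(icc_2_1(m)$icc, oracle_icc_2_1(m), tolerance = 1e-9)
  }
})

test_that("icc_2_1 is 1 on identical raters and below Pearson under offset", {
  x <- c(402, 415, 398, 430, 421, 409)
  r <- icc_2_1(cbind(x, x))
  expect_equal(r$icc, 1)

  shifted <- cbind(x, x + 30)
  r2 <- icc_2_1(shifted)
  pr <- stats::cor(shifted[, 1L], shifted[, 2L])
  expect_lt(r2$icc, pr)
  expect_lte(r2$icc, pr + 1e-9)
  expect_error(icc_2_1(matrix(5, 3, 2)), "zero variance")
  expect_error(icc_2_1(cbind(x[1:2], x[1:2])), ">= 3 subjects")
})

test_that("bland_altman matches direct two-pass formulas", {
  x <- c(400, 410, 395, 420)
  ba0 <- bland_altman(cbind(x, x))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$diff_sd, 0)
  ba10 <- bland_altman(cbind(x, x + 10))
  expect_equal(ba10$bias, 10)
  expect_equal(ba10$diff_sd, 0)
  expect_equal(ba10$loa, c(10, 10))

  set.seed(62)
  ref <- rnorm(40, 400, 15)
  cand <- ref + rnorm(40, 2, 8)
  ba <- bland_altman(cbind(ref, cand))
  d <- cand - ref
  expect_equal(ba$bias, sum(d) / length(d), tolerance = 1e-12)
  expect_equal(ba$diff_sd, sqrt(sum((d - mean(d))^2) / (length(d) - 1)),
               tolerance = 1e-12)
  expect_equal(ba$loa, ba$bias + c(-1.96, 1.96) * ba$diff_sd)
  # loa symmetric about bias
  expect_equal(mean(ba$loa), ba$bias)
})

test_that("morphology table stratifies differences with an 'all' row", {
  pairs <- structure(data.frame(reference_ms = rep(400, 60),
                                candidate_ms = 400 + c(rep(0.5, 40),
                                                       rep(5.5, 20))),
                     class = c("paired_measurements", "data.frame"))
  labels <- rep(c("normal", "biphasic"), c(40L, 20L))
  tab <- morphology_table(pairs, labels)
  expect_setequal(tab$morphology, c("normal", "biphasic", "all"))
  expect_equal(tab$bias[tab$morphology == "biphasic"], 5.5)
  expect_equal(tab$bias[tab$morphology == "all"],
               mean(pairs$candidate_ms - pairs$reference_ms))

  # single morphology equals global stats
  tab1 <- morphology_table(pairs, rep("normal", 60L))
  expect_equal(tab1$bias[1L], tab1$bias[2L])
  expect_equal(tab1$sd[1L], tab1$sd[2L])

  expect_error(morphology_table(pairs, labels[1:10]), "one morphology label")
  expect_error(morphology_table(pairs, replace(labels, 3L, NA)), "unlabeled")
})

test_that("agreement_report composes the statistics deterministically", {
  set.seed(63)
  ref <- rnorm(30, 405, 12)
  pairs <- structure(data.frame(reference_ms = ref,
                                candidate_ms = ref + rnorm(30, 1, 5)),
                     class = c("paired_measurements", "data.frame"))
  r1 <- agreement_report(pairs)
  r2 <- agreement_report(pairs)
  expect_identical(r1$icc$icc, r2$icc$icc)
  expect_equal(r1$pearson_r,
               stats::cor(pairs$reference_ms, pairs$candidate_ms))
  expect_output(print(r1), "ICC\\(2,1\\)")
})
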