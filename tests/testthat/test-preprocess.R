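# amplitude of a pure tone after filtering, measured on the central half by
# least squares against quadrature carriers
tone_gain <- function(f, fs, n = 2000) {
  t <- seq_len(n) / fs
  x <- sin(2 * pi * f * t)
  y <- lowpass_filter(x, fs)
  mid <- seq(n %/% 4, 3 * n %/% 4)
  X <- cbind(sin(2 * pi * f * t[mid]), cos(2 * pi * f * t[mid]))
  cf <- stats::lm.fit(X, y[mid])$coefficients
  sqrt(sum(cf^2))
}

test_that("low-pass filter meets the 3 dB / 40 dB template and is zero-phase", {
  fs <- 250
  expect_lt(max(abs(lowpass_filter(rep(0.7, 1000), fs) - 0.7)), 1e-6)
  expect_gte(tone_gain(20, fs), 10^(-3 / 20))
  expect_lte(tone_gain(80, fs), 10^(-40 / 20))
  # zero phase + near-unit passband gain: a slow tone passes unshifted
  t <- seq_len(1000) / fs
  x <- sin(2 * pi * 5 * t)
  y <- lowpass_filter(x, fs)
  expect_lt(max(abs(y[100:900] - x[100:900])), 0.02)
  expect_error(lowpass_filter(rnorm(100), fs = 100), "too low")
})

test_that("beat extraction applies the window, truncation and padding rules", {
  fs <- 250
  sig <- seq(0, by = 0.001, length.out = 1300)   # strictly increasing ramp
  rec <- ecg_record("ramp", sig, fs, r_peaks = c(100, 500, 750, 1250))
  bs <- extract_beats(rec)
  expect_identical(bs$L, 400L)
  expect_identical(nrow(bs$beats), 4L)
  expect_true(all(bs$beats$excluded[c(1L, 4L)]))
  expect_identical(bs$beats$exclusion_reason[1L], "first_or_last")

  # beat at r=500 (next 750): raw window [470, 730) = 260 samples, padded
  b2 <- bs$samples[2L, ]
  expect_equal(b2[1:260], sig[471:730])
  expect_equal(b2[261:400], rep((sig[471] + sig[730]) / 2, 140))
  # beat at r=750 (next 1250): raw window [720, 1230) = 510, truncated to 400
  b3 <- bs$samples[3L, ]
  expect_equal(b3, sig[721:1120])

  expect_equal(bs$beats$rr_prev[2L], (500 - 100) / fs * 1000)
  expect_equal(bs$beats$rr_next[2L], (750 - 500) / fs * 1000)
  expect_error(extract_beats(ecg_record("x", sig, fs, r_peaks = c(10, 20))),
               ">= 3 R peaks")
})

test_that("3 R peaks give 1 interior beat and the count identity holds", {
  fs <- 250
  rec <- ecg_record("tiny", rnorm(1000), fs, r_peaks = c(100, 400, 700))
  bs <- extract_beats(rec)
  interior <- bs$beats[bs$beats$exclusion_reason != "first_or_last", ]
  expect_identical(nrow(interior), 1L)
  bs <- apply_rr_exclusions(bs)
  expect_identical(sum(!interior$excluded) + sum(interior$excluded),
                   nrow(interior))
})

test_that("RR exclusion rules use strict inequalities with correct reasons", {
  mk <- function(rr_prev, rr_next) {
    bs <- list(beats = data.frame(rr_prev = rr_prev, rr_next = rr_next,
                                  excluded = FALSE, exclusion_reason = "none"))
    class(bs) <- "beat_set"
    apply_rr_exclusions(bs)$beats
  }
  b <- mk(250, 1000)
  expect_true(b$excluded)
  expect_identical(b$exclusion_reason, "rr_short")
  b <- mk(2100, 1900)
  expect_identical(b$exclusion_reason, "rr_long")
  b <- mk(1000, 1600)                      # ratio 0.625 < 0.70
  expect_identical(b$exclusion_reason, "rr_ratio")
  b <- mk(1400, 1000)                      # ratio 1.4 > 1.30
  expect_identical(b$exclusion_reason, "rr_ratio")
  # boundaries retained (strict comparisons)
  for (case in list(c(300, 300), c(2000, 2000), c(700, 1000), c(1300, 1000),
                    c(1000, 1000))) {
    expect_false(mk(case[1L], case[2L])$excluded)
  }
})

test_that("znormalize matches the closed form and is idempotent/invariant", {
  r <- znormalize(c(1, 2, 3))
  expect_equal(r$mu, 2)
  expect_equal(r$sigma, sqrt(2 / 3))
  expect_equal(r$z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$z, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  set.seed(9)
  x <- rnorm(50)
  z1 <- znormalize(x)$z
  expect_equal(mean(z1), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z1^2)), 1, tolerance = 1e-9)
  expect_equal(znormalize(z1)$z, z1, tolerance = 1e-9)       # idempotent
  expect_equal(znormalize(3.7 * x - 2.2)$z, z1, tolerance = 1e-9)
  expect_error(znormalize(rep(5, 4)), "degenerate")
})

test_that("znormalize_beats excludes degenerate beats with a warning", {
  bs <- list(fs = 250, L = 4L,
             samples = rbind(c(1, 2, 3, 4), c(5, 5, 5, 5)),
             beats = data.frame(beat_index = 0:1, r_peak = c(10L, 20L),
                                rr_prev = c(NA, 40), rr_next = c(40, NA),
                                excluded = FALSE, exclusion_reason = "none"))
  class(bs) <- "beat_set"
  expect_warning(out <- znormalize_beats(bs), "degenerate")
  expect_true(out$beats$excluded[2L])
  expect_identical(out$beats$exclusion_reason[2L], "degenerate")
  expect_equal(mean(out$z[1L, ]), 0, tolerance = 1e-12)
})
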