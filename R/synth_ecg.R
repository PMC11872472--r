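#' Gaussian-wave beat shape specification
#'
#' A heartbeat is modeled as a sum of Gaussian components (P, Q, R, S, T)
#' with amplitudes in mV, centers in ms relative to the R peak, and widths
#' (SD) in ms. Each morphology carries analytic ground-truth fiducials:
#' `qrs_onset_ms` (negative, before R) and `t_end_ms` (positive), so the
#' true QT of an unwarped beat is `t_end_ms - qrs_onset_ms`. T morphologies:
#' `normal`, `inverted` (sign-flipped T), `biphasic` (two opposite-sign
#' Gaussians 60 ms apart), `flat` (T amplitude 0.04 mV), `tall` (2x normal).
#'
#' @param morphology One of `"normal"`, `"inverted"`, `"biphasic"`,
#'   `"flat"`, `"tall"`.
#' @return A `"beat_shape_spec"`: list with `waves` (data frame `amp`,
#'   `center`, `width`), `qrs_onset_ms`, `t_end_ms`, `morphology`.
#' @export
beat_shape_spec <- function(morphology = c("normal", "inverted", "biphasic",
                                           "flat", "tall")) {
  morphology <- match.arg(morphology)
  pqrs <- data.frame(
    amp    = c(0.15, -0.08, 1.00, -0.25),
    center = c(-160, -22,   0,    22),
    width  = c(25,   7,     9,    7))
  t_end <- 360
  tw <- switch(morphology,
    normal   = data.frame(amp = 0.35, center = 280, width = 40),
    inverted = data.frame(amp = -0.35, center = 280, width = 40),
    tall     = data.frame(amp = 0.70, center = 280, width = 40),
    flat     = data.frame(amp = 0.04, center = 280, width = 40),
    biphasic = {
      t_end <- 370
      data.frame(amp = c(0.25, -0.25), center = c(250, 310), width = c(30, 30))
    })
  structure(list(waves = rbind(pqrs, tw), qrs_onset_ms = -40,
                 t_end_ms = t_end, morphology = morphology),
            class = "beat_shape_spec")
}

gaussian_sum <- function(t_ms, waves) {
  out <- numeric(length(t_ms))
  for (i in seq_len(nrow(waves))) {
    out <- out + waves$amp[i] *
      exp(-0.5 * ((t_ms - waves$center[i]) / waves$width[i])^2)
  }
  out
}

# Smooth monotone time warp over [t0, t1]: derivative exp(log(s) * g(t))
# with g a smooth field in [-1, 1]. The window endpoints AND the R peak
# (t = 0) are pinned, because R-peak positions enter the pipeline as exact
# annotations; the warp distorts intra-beat timing around a fixed R. Local
# stretch stays within ~warp_strength and never reverses. Draws from the
# current RNG stream.
make_warp <- function(t_grid, warp_strength) {
  if (warp_strength <= 1) return(t_grid)
  kn <- stats::runif(8L, -1, 1)
  g <- stats::spline(seq(min(t_grid), max(t_grid), length.out = 8L), kn,
                     xout = t_grid)$y
  g <- pmax(-1, pmin(1, g))
  d <- exp(log(warp_strength) * g)
  w <- cumsum(d) - d[1L]
  # piecewise renormalization pinning t0 -> t0, 0 -> 0, t1 -> t1
  i0 <- which.min(abs(t_grid))
  pre <- seq_len(i0)
  post <- i0:length(t_grid)
  w_out <- numeric(length(t_grid))
  w_out[pre] <- t_grid[1L] +
    (w[pre] - w[1L]) * (t_grid[i0] - t_grid[1L]) / (w[i0] - w[1L])
  w_out[post] <- t_grid[i0] +
    (w[post] - w[i0]) * (t_grid[length(t_grid)] - t_grid[i0]) /
      (w[length(w)] - w[i0])
  w_out <- w_out - w_out[i0] + t_grid[i0]
  if (any(diff(w_out) <= 0)) stop("internal error: warp not monotone")
  w_out
}

#' Render one synthetic heartbeat with ground-truth fiducials
#'
#' Samples the Gaussian-sum beat model at `fs` over the window
#' \[-300 ms, rr_ms) around the R peak, optionally applies a smooth
#' monotone time warp (identically to samples and fiducials) and additive
#' Gaussian noise. Fiducial indices are returned in samples RELATIVE TO THE
#' R PEAK (onset negative); with no warp they equal
#' `round(fiducial_ms * fs / 1000)`.
#'
#' @param spec A [beat_shape_spec()].
#' @param rr_ms RR interval to the next beat, in \[300, 2000\] ms.
#' @param fs Sampling rate (Hz).
#' @param warp_strength Max local time-stretch factor (1 = identity).
#' @param noise_sd Additive Gaussian noise SD in mV (0 = none).
#' @return List with `samples`, `offset` (samples from window start to R),
#'   `true_qrs_onset_idx`, `true_t_end_idx` (relative to R).
#' @export
render_beat <- function(spec, rr_ms, fs, warp_strength = 1, noise_sd = 0) {
  if (rr_ms < 300 || rr_ms > 2000) stop("rr_ms must lie in [300, 2000]")
  offset <- round(0.300 * fs)
  idx <- seq(-offset, round(rr_ms * fs / 1000) - 1L)
  t_ms <- idx / fs * 1000
  w <- make_warp(t_ms, warp_strength)
  samples <- gaussian_sum(w, spec$waves)
  if (noise_sd > 0) samples <- samples + stats::rnorm(length(samples), 0, noise_sd)
  # observed fiducial time t* solves w(t*) = nominal fiducial time
  inv <- function(f_ms) {
    if (identical(w, t_ms)) return(as.integer(round(f_ms * fs / 1000)))
    as.integer(round(stats::approx(w, t_ms, xout = f_ms)$y * fs / 1000))
  }
  list(samples = samples, offset = offset,
       true_qrs_onset_idx = inv(spec$qrs_onset_ms),
       true_t_end_idx = inv(spec$t_end_ms))
}

#' Synthetic record configuration
#'
#' Defaults describe the desk-scale stand-in for a 15-minute Holter
#' segment: 900 beats at a mean RR of 1000 ms with 40 ms jitter, a
#' normal/inverted/biphasic morphology mixture, 0.05 mV additive noise and
#' mild (1.2x) local time warping at 250 Hz.
#'
#' @param n_beats Number of beats.
#' @param mean_rr_ms,rr_jitter_sd_ms RR distribution (Gaussian, clipped to
#'   \[300, 2000\] ms).
#' @param class_mixture Named probability vector over morphologies.
#' @param noise_sd_mv Additive Gaussian noise SD (mV).
#' @param warp_strength Max local time stretch (>= 1).
#' @param fs Sampling rate (Hz).
#' @param seed RNG seed.
#' @return A `"synth_config"` list.
#' @export
synth_config <- function(n_beats = 900L, mean_rr_ms = 1000,
                         rr_jitter_sd_ms = 40,
                         class_mixture = c(normal = 0.6, inverted = 0.2,
                                           biphasic = 0.2),
                         noise_sd_mv = 0.05, warp_strength = 1.2,
                         fs = 250, seed = 0L) {
  if (abs(sum(class_mixture) - 1) > 1e-9) stop("class_mixture must sum to 1")
  if (warp_strength < 1) stop("warp_strength must be >= 1")
  structure(list(n_beats = n_beats, mean_rr_ms = mean_rr_ms,
                 rr_jitter_sd_ms = rr_jitter_sd_ms,
                 class_mixture = class_mixture, noise_sd_mv = noise_sd_mv,
                 warp_strength = warp_strength, fs = fs, seed = seed),
            class = "synth_config")
}

#' Generate a synthetic ECG record with per-beat ground truth
#'
#' Concatenates rendered beats at jittered RR intervals into a continuous
#' single-channel record, recording for every beat its morphology class and
#' true (post-warp) fiducial sample indices. The same seed always yields a
#' bit-identical record.
#'
#' @param config A [synth_config()].
#' @return List with `record` (an [ecg_record()] with R peaks set) and
#'   `truth`, a data frame with `beat_index`, `r_peak`, `class`,
#'   `qrs_onset_idx`, `t_end_idx` (absolute 0-based sample indices) and
#'   `qt_true_ms`.
#' @export
generate_record <- function(config = synth_config()) {
  with_seed(config$seed, function() {
    fs <- config$fs
    n <- config$n_beats
    rr <- pmin(2000, pmax(300, stats::rnorm(n, config$mean_rr_ms,
                                            config$rr_jitter_sd_ms)))
    classes <- sample(names(config$class_mixture), n, replace = TRUE,
                      prob = config$class_mixture)
    r_peaks <- as.integer(round(0.5 * fs) + cumsum(c(0, rr[-n]) * fs / 1000))
    total <- r_peaks[n] + as.integer(round(2 * fs))
    sig <- numeric(total)
    onset_abs <- tend_abs <- integer(n)
    specs <- lapply(stats::setNames(nm = names(config$class_mixture)),
                    beat_shape_spec)
    for (b in seq_len(n)) {
      rb <- render_beat(specs[[classes[b]]], rr[b], fs,
                        warp_strength = config$warp_strength, noise_sd = 0)
      pos <- r_peaks[b] - rb$offset + seq_along(rb$samples)  # 1-based slice
      keep <- pos >= 1L & pos <= total
      sig[pos[keep]] <- sig[pos[keep]] + rb$samples[keep]
      onset_abs[b] <- r_peaks[b] + rb$true_qrs_onset_idx
      tend_abs[b] <- r_peaks[b] + rb$true_t_end_idx
    }
    if (config$noise_sd_mv > 0) {
      sig <- sig + stats::rnorm(total, 0, config$noise_sd_mv)
    }
    rec <- ecg_record(sprintf("synth%06d", config$seed),
                      matrix(sig, nrow = 1L), fs, r_peaks = r_peaks,
                      channel_names = "synthetic")
    truth <- data.frame(beat_index = seq_len(n) - 1L, r_peak = r_peaks,
                        class = classes, qrs_onset_idx = onset_abs,
                        t_end_idx = tend_abs,
                        stringsAsFactors = FALSE)
    truth$qt_true_ms <- truth_qt(truth, fs)
    list(record = rec, truth = truth)
  })
}

#' Ground-truth QT per beat
#'
#' @param truth Truth table from [generate_record()].
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of true QT in ms.
#' @export
truth_qt <- function(truth, fs) {
  (truth$t_end_idx - truth$qrs_onset_idx) / fs * 1000
}

#' Build a fiducial registration table from generator ground truth
#'
#' Looks up each selected template's source beat in the truth table and
#' converts its absolute true fiducials into template-window coordinates.
#' This stands in for the manual registration step when validating the
#' pipeline against synthetic records.
#'
#' @param cl A `"qt_clustering"` with templates selected.
#' @param truth Truth table from [generate_record()].
#' @return Data frame `cluster_id`, `qrs_onset`, `t_end`.
#' @export
registration_from_truth <- function(cl, truth) {
  pre <- as.integer(round(0.120 * cl$bs$fs))
  rows <- lapply(cl$templates, function(t) {
    tr <- truth[truth$beat_index == t$beat_index, ]
    if (nrow(tr) != 1L) stop("template beat ", t$beat_index, " not in truth table")
    start <- tr$r_peak - pre
    data.frame(cluster_id = t$cluster_id,
               qrs_onset = tr$qrs_onset_idx - start,
               t_end = tr$t_end_idx - start)
  })
  do.call(rbind, rows)
}
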