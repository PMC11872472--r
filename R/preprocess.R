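#' Low-pass filter specification
#'
#' Frequency-domain template for the noise-removal filter: passband edge,
#' stopband edge, maximum passband loss and minimum stopband attenuation.
#' Defaults are the production settings for suppressing high-frequency noise
#' while leaving QRS morphology intact: passband to 50 Hz (3 dB), at least
#' 40 dB attenuation from 60 Hz.
#'
#' @param passband_edge,stopband_edge Edges in Hz, `0 < passband < stopband`.
#' @param max_passband_loss_db Maximum passband loss (dB).
#' @param min_stopband_loss_db Minimum stopband attenuation (dB).
#' @return A `"filter_spec"` list.
#' @export
filter_spec <- function(passband_edge = 50, stopband_edge = 60,
                        max_passband_loss_db = 3, min_stopband_loss_db = 40) {
  if (!(passband_edge > 0 && passband_edge < stopband_edge)) {
    stop("need 0 < passband_edge < stopband_edge")
  }
  structure(list(passband_edge = passband_edge, stopband_edge = stopband_edge,
                 max_passband_loss_db = max_passband_loss_db,
                 min_stopband_loss_db = min_stopband_loss_db),
            class = "filter_spec")
}

# Kaiser-window FIR low-pass taps meeting `spec` at sampling rate fs.
# Linear phase, odd length, unit DC gain.
kaiser_lowpass_taps <- function(fs, spec) {
  A <- spec$min_stopband_loss_db
  d_omega <- 2 * pi * (spec$stopband_edge - spec$passband_edge) / fs
  beta <- if (A > 50) {
    0.1102 * (A - 8.7)
  } else if (A >= 21) {
    0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
  } else 0
  ntaps <- ceiling((A - 8) / (2.285 * d_omega)) + 1
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1        # odd length: integer delay
  mid <- (ntaps - 1) / 2
  fc <- (spec$passband_edge + spec$stopband_edge) / 2   # -6 dB point
  k <- seq_len(ntaps) - 1 - mid
  h <- ifelse(k == 0, 2 * fc / fs, sin(2 * pi * fc / fs * k) / (pi * k))
  w <- besselI(beta * sqrt(pmax(0, 1 - (k / mid)^2)), 0) / besselI(beta, 0)
  h <- h * w
  h / sum(h)                                      # exact unit DC gain
}

#' Zero-phase low-pass filtering of a continuous ECG signal
#'
#' Removes high-frequency noise with a linear-phase FIR low-pass designed by
#' the Kaiser-window method to meet `spec`, applied with exact integer
#' group-delay compensation so fiducial landmarks are not shifted. Signal
#' edges are extended by replication before convolution, so a constant (DC)
#' signal passes through unchanged.
#'
#' @param signal Numeric vector of voltage samples (mV).
#' @param fs Sampling rate in Hz; must exceed twice the stopband edge.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as the input.
#' @export
lowpass_filter <- function(signal, fs, spec = filter_spec()) {
  if (fs <= 2 * spec$stopband_edge) {
    stop("fs = ", fs, " Hz too low: need fs > 2 * stopband_edge (",
         2 * spec$stopband_edge, " Hz)")
  }
  h <- kaiser_lowpass_taps(fs, spec)
  d <- (length(h) - 1) / 2
  n <- length(signal)
  if (n == 0L) return(signal)
  pad <- c(rep(signal[1L], d), signal, rep(signal[n], d))
  y <- stats::convolve(pad, rev(h), type = "open")  # length n + 4d
  y[(2 * d + 1):(2 * d + n)]
}

#' Extract fixed-length heartbeat windows from a continuous record
#'
#' Each beat window runs from 120 ms before its R peak to 80 ms before the
#' next R peak (half-open, 0-based sample indices), then is standardized to
#' a fixed duration of 1600 ms: longer windows are truncated, shorter ones
#' are tail-padded with the mean of the raw window's first and last samples.
#' The first and last beats lack an RR neighbor and are emitted flagged
#' `first_or_last`; a window falling outside the record is flagged
#' `out_of_bounds`.
#'
#' @param record An [ecg_record()] with at least 3 R peaks.
#' @param channel Channel to extract (default 1).
#' @return A `"beat_set"`: list with `fs`, `L` (samples per beat,
#'   `round(1.6 * fs)`), `samples` (beats x L matrix), and `beats`, a data
#'   frame with `beat_index`, `r_peak`, `rr_prev`, `rr_next` (ms),
#'   `excluded`, `exclusion_reason`.
#' @export
extract_beats <- function(record, channel = 1L) {
  stopifnot(inherits(record, "ecg_record"))
  r <- record$r_peaks
  if (length(r) < 3L) stop("need >= 3 R peaks (boundary beats are excluded)")
  fs <- record$fs
  sig <- record$signal[channel, ]
  nsamp <- length(sig)
  L <- as.integer(round(1.6 * fs))
  pre <- as.integer(round(0.120 * fs))
  post <- as.integer(round(0.080 * fs))
  nb <- length(r)

  samples <- matrix(0, nrow = nb, ncol = L)
  rr_prev <- c(NA_real_, diff(r)) / fs * 1000
  rr_next <- c(diff(r), NA_real_) / fs * 1000
  excluded <- logical(nb)
  reason <- rep("none", nb)

  for (b in seq_len(nb)) {
    start <- r[b] - pre
    end <- if (b < nb) r[b + 1L] - post else r[b] - pre + L
    if (b == 1L || b == nb) {
      excluded[b] <- TRUE
      reason[b] <- "first_or_last"
    }
    if (start < 0L || end > nsamp) {
      if (!excluded[b]) {
        excluded[b] <- TRUE
        reason[b] <- "out_of_bounds"
      }
      start <- max(start, 0L)
      end <- min(end, nsamp)
      if (end <= start) next  # leave zeros; beat already excluded
    }
    raw <- sig[(start + 1L):end]            # half-open [start, end), 0-based
    if (length(raw) >= L) {
      samples[b, ] <- raw[seq_len(L)]       # truncate at 1600 ms
    } else {
      fill <- (raw[1L] + raw[length(raw)]) / 2
      samples[b, ] <- c(raw, rep(fill, L - length(raw)))
    }
  }

  beats <- data.frame(beat_index = seq_len(nb) - 1L, r_peak = r,
                      rr_prev = rr_prev, rr_next = rr_next,
                      excluded = excluded, exclusion_reason = reason,
                      stringsAsFactors = FALSE)
  structure(list(fs = fs, L = L, samples = samples, beats = beats),
            class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("beat_set: %d beats of %d samples (%.0f ms at %g Hz), %d excluded\n",
              nrow(x$beats), x$L, x$L / x$fs * 1000, x$fs,
              sum(x$beats$excluded)))
  invisible(x)
}

#' Flag beats with unreliable RR context
#'
#' Excludes bradycardic, tachycardic and unstable beats: a beat is dropped
#' when its preceding RR interval is below 300 ms or above 2000 ms, or is
#' less than 70% or more than 130% of the following RR interval. All four
#' comparisons are strict, so boundary values (exactly 300, 2000, 0.70,
#' 1.30) are retained. Already-excluded beats keep their original reason.
#'
#' @param bs A `"beat_set"` from [extract_beats()].
#' @param rr_min,rr_max Preceding-RR bounds in ms.
#' @param ratio_min,ratio_max Bounds on `rr_prev / rr_next`.
#' @return The `beat_set` with updated `excluded` / `exclusion_reason`.
#' @export
apply_rr_exclusions <- function(bs, rr_min = 300, rr_max = 2000,
                                ratio_min = 0.70, ratio_max = 1.30) {
  b <- bs$beats
  open <- !b$excluded
  ratio <- b$rr_prev / b$rr_next
  mark <- function(cond, why) {
    hit <- open & !is.na(cond) & cond
    b$excluded[hit] <<- TRUE
    b$exclusion_reason[hit] <<- why
    open[hit] <<- FALSE
  }
  mark(b$rr_prev < rr_min, "rr_short")
  mark(b$rr_prev > rr_max, "rr_long")
  mark(ratio < ratio_min | ratio > ratio_max, "rr_ratio")
  bs$beats <- b
  bs
}

#' z-normalize a heartbeat waveform
#'
#' Standardizes a beat to zero mean and unit standard deviation,
#' `z = (x - mu) / sigma`, with the population standard deviation
#' (divide by n) as in the shape-based clustering convention. The original
#' mean and SD are kept so measurements can be related back to mV.
#'
#' @param x Numeric vector with positive variance.
#' @return A `"normalized_beat"`: list with `z`, `mu`, `sigma`.
#' @export
#' @examples
#' znormalize(c(1, 2, 3))$z  # -1.2247 0 1.2247
znormalize <- function(x) {
  x <- as.numeric(x)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop("degenerate beat: constant samples cannot be z-normalized")
  structure(list(z = (x - mu) / sigma, mu = mu, sigma = sigma),
            class = "normalized_beat")
}

#' z-normalize every retained beat in a beat set
#'
#' Degenerate (constant) beats are excluded with reason `"degenerate"` and a
#' warning instead of stopping.
#'
#' @param bs A `"beat_set"`.
#' @return The `beat_set` with an added `z` matrix (rows of excluded beats
#'   are zero) and `mu` / `sigma` columns in `beats`.
#' @export
znormalize_beats <- function(bs) {
  n <- nrow(bs$samples)
  z <- matrix(0, n, bs$L)
  mu <- sigma <- rep(NA_real_, n)
  degen <- 0L
  for (i in seq_len(n)) {
    if (bs$beats$excluded[i]) next
    xi <- bs$samples[i, ]
    m <- mean(xi)
    s <- sqrt(mean((xi - m)^2))
    if (s == 0) {
      bs$beats$excluded[i] <- TRUE
      bs$beats$exclusion_reason[i] <- "degenerate"
      degen <- degen + 1L
      next
    }
    z[i, ] <- (xi - m) / s
    mu[i] <- m
    sigma[i] <- s
  }
  if (degen > 0L) warning(degen, " constant beat(s) excluded as degenerate")
  bs$z <- z
  bs$beats$mu <- mu
  bs$beats$sigma <- sigma
  bs
}
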