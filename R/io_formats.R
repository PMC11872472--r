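#' Continuous ECG record container
#'
#' Holds a multi-channel ECG signal in mV with its sampling rate and R-peak
#' sample positions. All sample indices in the package are 0-based and
#' windows are half-open `[start, end)`.
#'
#' @param record_id Character identifier.
#' @param signal Numeric matrix, one row per channel (a vector is treated as
#'   one channel).
#' @param fs Sampling rate in Hz (> 0).
#' @param r_peaks Integer vector of 0-based R-peak sample indices, strictly
#'   increasing, within `[0, n_samples)`.
#' @param channel_names Optional channel labels.
#' @return An `"ecg_record"` list.
#' @export
ecg_record <- function(record_id, signal, fs, r_peaks = integer(0),
                       channel_names = NULL) {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1L)
  if (fs <= 0) stop("fs must be > 0")
  r_peaks <- as.integer(r_peaks)
  n <- ncol(signal)
  if (length(r_peaks)) {
    if (any(r_peaks < 0L) || any(r_peaks >= n)) {
      stop("r_peaks must lie within [0, n_samples)")
    }
    if (any(diff(r_peaks) <= 0L)) stop("r_peaks must be strictly increasing")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(signal)) - 1L)
  }
  structure(list(record_id = record_id, signal = signal, fs = fs,
                 r_peaks = r_peaks, channel_names = channel_names),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ecg_record '%s': %d channel(s) x %d samples at %g Hz (%.1f min), %d R peaks\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs / 60, length(x$r_peaks)))
  invisible(x)
}

# ---- WFDB signals ---------------------------------------------------------

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nsig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(sub("/.*", "", top[3L])) else 250
  nsamp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  sig <- lapply(lines[1L + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    gain_field <- if (length(f) >= 3L) f[3L] else "200"
    gain_core <- sub("/.*", "", gain_field)
    baseline <- 0
    if (grepl("\\(", gain_core)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_core))
      gain_core <- sub("\\(.*", "", gain_core)
    }
    gain <- as.numeric(gain_core)
    if (is.na(gain) || gain == 0) gain <- 200
    list(file = f[1L], fmt = sub("x.*|:.*|\\+.*", "", f[2L]),
         gain = gain, baseline = baseline,
         name = if (length(f) >= 9L) paste(f[9L:length(f)], collapse = " ")
                else NA_character_)
  })
  list(record = top[1L], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_format16 <- function(path, nsig, nsamp) {
  if (is.na(nsamp)) nsamp <- file.size(path) %/% (2L * nsig)
  raw <- readBin(path, what = "integer", size = 2L, signed = TRUE,
                 endian = "little", n = nsig * nsamp + nsig)
  nsamp <- min(nsamp, length(raw) %/% nsig)
  matrix(raw[seq_len(nsig * nsamp)], nrow = nsig)
}

read_dat_format212 <- function(path, nsig, nsamp) {
  if (is.na(nsamp)) nsamp <- (file.size(path) * 2L) %/% (3L * nsig)
  total <- nsig * nsamp
  bytes <- as.integer(readBin(path, what = "raw", n = ceiling(total / 2) * 3L))
  npair <- length(bytes) %/% 3L
  b0 <- bytes[3L * seq_len(npair) - 2L]
  b1 <- bytes[3L * seq_len(npair) - 1L]
  b2 <- bytes[3L * seq_len(npair)]
  s1 <- bitwOr(bitwShiftL(bitwAnd(b1, 0x0FL), 8L), b0)
  s2 <- bitwOr(bitwShiftL(bitwAnd(b1, 0xF0L), 4L), b2)
  dec <- function(v) ifelse(v >= 2048L, v - 4096L, v)
  flat <- numeric(2L * npair)
  flat[seq(1L, by = 2L, length.out = npair)] <- dec(s1)
  flat[seq(2L, by = 2L, length.out = npair)] <- dec(s2)
  matrix(flat[seq_len(total)], nrow = nsig)
}

#' Read one channel of a WFDB record
#'
#' Minimal reader for WFDB `.hea` / `.dat` pairs, supporting sample formats
#' 16 (16-bit little-endian) and 212 (packed 12-bit pairs, the QT Database
#' format). ADC units are converted to mV as `(adc - baseline) / gain`.
#' R peaks are left empty; attach them from an annotation source.
#'
#' @param path Record path without extension (or with `.hea`).
#' @param channel 0-based channel index (default 0).
#' @return An [ecg_record()] with the selected channel only.
#' @export
read_wfdb_record <- function(path, channel = 0L) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  hdr <- parse_wfdb_header(hea)
  if (channel < 0L || channel >= hdr$nsig) {
    stop("channel ", channel, " does not exist: record has ", hdr$nsig,
         " channel(s)")
  }
  dat <- file.path(dirname(hea), hdr$signals[[1L]]$file)
  if (!file.exists(dat)) stop("WFDB signal file not found: ", dat)
  fmt <- hdr$signals[[1L]]$fmt
  adc <- switch(fmt,
    "16" = read_dat_format16(dat, hdr$nsig, hdr$nsamp),
    "212" = read_dat_format212(dat, hdr$nsig, hdr$nsamp),
    stop("unsupported WFDB sample format: ", fmt)
  )
  ch <- channel + 1L
  s <- hdr$signals[[ch]]
  mv <- (adc[ch, , drop = TRUE] - s$baseline) / s$gain
  ecg_record(record_id = basename(base), signal = matrix(mv, nrow = 1L),
             fs = hdr$fs,
             channel_names = if (is.na(s$name)) NULL else s$name)
}

#' Write an ECG record as a WFDB header/signal pair (format 16)
#'
#' @param record An [ecg_record()].
#' @param dir Output directory.
#' @param gain ADC units per mV (default 1000).
#' @return The header path, invisibly.
#' @export
write_wfdb_record <- function(record, dir, gain = 1000) {
  nsig <- nrow(record$signal)
  nsamp <- ncol(record$signal)
  base <- record$record_id
  adc <- round(record$signal * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  hea <- file.path(dir, paste0(base, ".hea"))
  datname <- paste0(base, ".dat")
  siglines <- vapply(seq_len(nsig), function(i) {
    sprintf("%s 16 %g(0)/mV 16 0 %d 0 0 %s", datname, gain, as.integer(adc[i, 1L]),
            record$channel_names[i])
  }, character(1L))
  writeLines(c(sprintf("%s %d %g %d", base, nsig, record$fs, nsamp), siglines),
             hea)
  con <- file(file.path(dir, datname), "wb")
  on.exit(close(con))
  writeBin(as.integer(adc), con, size = 2L, endian = "little")
  invisible(hea)
}

# ---- WFDB annotations -----------------------------------------------------

# MIT annotation code -> display symbol, for the codes this package maps
wfdb_ann_symbols <- c(`1` = "N", `2` = "L", `3` = "R", `5` = "V", `8` = "A",
                      `24` = "p", `27` = "t", `28` = "u", `39` = "(",
                      `40` = ")")

#' Read a WFDB (MIT-format) annotation file
#'
#' Decodes the standard 2-byte annotation stream, handling SKIP (long
#' intervals), AUX, NUM, SUB and CHN pseudo-annotations. Returns one row per
#' annotation with its absolute 0-based sample time, numeric type code and
#' display symbol (for the codes used by QT-type fiducial files: beat labels
#' N/L/R/V/A, `p`, `t`, `u`, and the waveform boundary marks `(` and `)`).
#'
#' @param path Annotation file (e.g. a `.q1c` or `.atr`).
#' @return Data frame with columns `sample`, `code`, `symbol`.
#' @export
read_wfdb_annotations <- function(path) {
  bytes <- as.integer(readBin(path, what = "raw", n = file.size(path)))
  i <- 1L
  t <- 0
  sample <- integer(0)
  code <- integer(0)
  while (i + 1L <= length(bytes)) {
    a <- bytes[i] + 256L * bytes[i + 1L]
    typ <- a %/% 1024L
    intv <- a %% 1024L
    i <- i + 2L
    if (typ == 0L && intv == 0L) break          # EOF
    if (typ == 59L) {                           # SKIP: 4-byte PDP-11 interval
      if (intv == 0L) {
        hi <- bytes[i] + 256L * bytes[i + 1L]
        lo <- bytes[i + 2L] + 256L * bytes[i + 3L]
        i <- i + 4L
        t <- t + hi * 65536 + lo
      }
    } else if (typ == 63L) {                    # AUX: skip payload (+pad)
      i <- i + intv + (intv %% 2L)
    } else if (typ %in% c(60L, 61L, 62L)) {     # NUM/SUB/CHN: no time change
    } else {
      t <- t + intv
      sample <- c(sample, t)
      code <- c(code, typ)
    }
  }
  sym <- wfdb_ann_symbols[as.character(code)]
  sym[is.na(sym)] <- "?"
  data.frame(sample = as.integer(sample), code = code, symbol = unname(sym),
             stringsAsFactors = FALSE)
}

#' Read expert fiducial annotations (WFDB annotation file or CSV)
#'
#' For WFDB annotation files the QT-Database convention is applied: the QRS
#' onset of a beat is the `(` mark immediately preceding its beat label, and
#' the T end is the `)` mark immediately following a `t` (or `t`-pair) after
#' the beat. The CSV dialect has header `r_peak,qrs_onset,t_end` with
#' 0-based sample indices. Beats lacking either fiducial, or violating
#' `qrs_onset < t_end`, are dropped with a message / warning.
#'
#' @param path Annotation path; CSV detected by extension `.csv`.
#' @return Data frame with columns `r_peak`, `qrs_onset`, `t_end` (class
#'   `"expert_annotations"`).
#' @export
read_fiducial_annotations <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("r_peak", "qrs_onset", "t_end")
    if (!all(need %in% names(df))) {
      stop("fiducial CSV must have header r_peak,qrs_onset,t_end: ", path)
    }
    if (nrow(df) == 0L) return(empty_annotations())
    bad <- !(df$qrs_onset < df$t_end)
    if (any(bad)) {
      warning(sum(bad), " row(s) rejected (t_end <= qrs_onset) at line(s) ",
              paste(which(bad) + 1L, collapse = ", "))
      df <- df[!bad, , drop = FALSE]
    }
    return(as_annotations(df[c("r_peak", "qrs_onset", "t_end")]))
  }
  ann <- read_wfdb_annotations(path)
  beat_codes <- c(1L, 2L, 3L, 5L, 8L)
  idx_beat <- which(ann$code %in% beat_codes)
  out <- lapply(idx_beat, function(b) {
    onset <- if (b > 1L && ann$symbol[b - 1L] == "(") ann$sample[b - 1L] else NA
    tend <- NA
    j <- b + 1L
    while (j <= nrow(ann) && !(ann$code[j] %in% beat_codes)) {
      if (ann$symbol[j] == ")" && j > 1L && ann$symbol[j - 1L] == "t") {
        tend <- ann$sample[j]
        break
      }
      j <- j + 1L
    }
    c(ann$sample[b], onset, tend)
  })
  m <- do.call(rbind, out)
  if (is.null(m)) return(empty_annotations())
  keep <- !is.na(m[, 2L]) & !is.na(m[, 3L]) & m[, 2L] < m[, 3L]
  if (any(!keep)) {
    message(sum(!keep), " annotated beat(s) dropped: missing or invalid fiducials")
  }
  as_annotations(data.frame(r_peak = as.integer(m[keep, 1L]),
                            qrs_onset = as.integer(m[keep, 2L]),
                            t_end = as.integer(m[keep, 3L])))
}

empty_annotations <- function() {
  as_annotations(data.frame(r_peak = integer(0), qrs_onset = integer(0),
                            t_end = integer(0)))
}

as_annotations <- function(df) {
  class(df) <- c("expert_annotations", "data.frame")
  df
}

# ---- fiducial registration & measurement CSVs -----------------------------

#' Read a per-cluster fiducial registration file
#'
#' CSV with header `cluster_id,qrs_onset,t_end`: integer 0-based sample
#' indices within the 1600 ms template window, one row per template cluster.
#'
#' @param path CSV path.
#' @return Data frame with the three columns; rows violating
#'   `qrs_onset < t_end` are rejected with a warning.
#' @export
read_fiducial_registration <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cluster_id", "qrs_onset", "t_end")
  if (!all(need %in% names(df))) {
    stop("registration CSV must have header cluster_id,qrs_onset,t_end: ", path)
  }
  bad <- !(df$qrs_onset < df$t_end)
  if (any(bad)) {
    warning(sum(bad), " registration row(s) rejected (t_end <= qrs_onset)")
    df <- df[!bad, , drop = FALSE]
  }
  df[need]
}

#' Write a fiducial registration file
#' @param registration Data frame with `cluster_id`, `qrs_onset`, `t_end`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fiducial_registration <- function(registration, path) {
  utils::write.csv(registration[c("cluster_id", "qrs_onset", "t_end")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

measurement_columns <- c("beat_index", "r_peak", "cluster_id", "qrs_onset",
                         "t_end", "rr_prev_ms", "qt_ms", "qtcb_ms",
                         "excluded", "exclusion_reason")

#' Write per-beat QT measurements as CSV
#'
#' One row per beat in increasing `beat_index` order, columns
#' `beat_index,r_peak,cluster_id,qrs_onset,t_end,rr_prev_ms,qt_ms,qtcb_ms,excluded,exclusion_reason`.
#' Millisecond values are written with 3 decimal places so a round trip is
#' exact to 1e-3 ms.
#'
#' @param measurements Data frame of measurements (see [measure_qt()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  df <- measurements[order(measurements$beat_index), measurement_columns,
                     drop = FALSE]
  for (col in c("rr_prev_ms", "qt_ms", "qtcb_ms")) {
    df[[col]] <- sprintf("%.3f", df[[col]])
    df[[col]][df[[col]] == "NA"] <- ""
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement CSV written by [write_measurements()]
#' @param path CSV path.
#' @return Data frame with the measurement columns.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(measurement_columns %in% names(df))) {
    stop("not a measurement CSV: ", path)
  }
  df$excluded <- as.logical(df$excluded)
  df
}
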