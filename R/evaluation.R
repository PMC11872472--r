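#' Pair expert-annotated beats with algorithm measurements
#'
#' Matches beats between a reference annotation set and a candidate
#' measurement set by R-peak proximity: a reference beat pairs with the
#' nearest retained candidate beat whose R peak lies within
#' `tolerance_ms`. Unmatched beats on either side are dropped (counts
#' reported via message); excluded candidate beats never match. The
#' reference QT is derived from its fiducials.
#'
#' @param reference An `"expert_annotations"` data frame (`r_peak`,
#'   `qrs_onset`, `t_end`).
#' @param candidate A measurement data frame from [measure_qt()].
#' @param fs Sampling rate (Hz) shared by both index sets.
#' @param tolerance_ms Maximum R-peak separation for a match (default 150).
#' @return A `"paired_measurements"` data frame with columns
#'   `reference_ms`, `candidate_ms`, `r_peak_ref`, `r_peak_cand`.
#' @export
pair_beats <- function(reference, candidate, fs, tolerance_ms = 150) {
  cand <- candidate[!candidate$excluded & !is.na(candidate$qt_ms), ]
  tol <- tolerance_ms * fs / 1000
  out <- lapply(seq_len(nrow(reference)), function(i) {
    dr <- abs(cand$r_peak - reference$r_peak[i])
    if (length(dr) == 0L || min(dr) > tol) return(NULL)
    j <- which.min(dr)
    data.frame(
      reference_ms = (reference$t_end[i] - reference$qrs_onset[i]) / fs * 1000,
      candidate_ms = cand$qt_ms[j],
      r_peak_ref = reference$r_peak[i], r_peak_cand = cand$r_peak[j])
  })
  pairs <- do.call(rbind, out)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("no beats matched between reference and candidate")
  }
  dropped <- nrow(reference) - nrow(pairs)
  if (dropped > 0L) message(dropped, " reference beat(s) unmatched")
  class(pairs) <- c("paired_measurements", "data.frame")
  pairs
}

#' Intraclass correlation ICC(2,1) with 95% confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC
#' (Shrout–Fleiss ICC(2,1)) computed from the two-way ANOVA mean squares of
#' an n-subjects x k-raters matrix, with the standard F-distribution
#' confidence bounds (McGraw & Wong). For the usual two-column case pass
#' the paired reference/candidate values.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns
#'   (>= 3 subjects, >= 2 raters), or a `"paired_measurements"` object.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `icc`, `ci` (length-2 vector), and the mean squares
#'   `msr`, `msc`, `mse`.
#' @export
icc_2_1 <- function(ratings, conf_level = 0.95) {
  if (inherits(ratings, "paired_measurements")) {
    ratings <- cbind(ratings$reference_ms, ratings$candidate_ms)
  }
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 3L || k < 2L) stop("need >= 3 subjects and >= 2 raters")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings)
  colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sse <- sum((ratings - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0 && msc == 0 && mse == 0) {
    stop("zero variance everywhere: ICC undefined")
  }
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- (msr - mse) / denom

  alpha <- 1 - conf_level
  # McGraw & Wong F-based bounds for ICC(A,1)
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  if (!is.finite(v) || v <= 0) {
    ci <- c(icc, icc)   # degenerate (e.g. perfect agreement): no spread
  } else {
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lower, upper)
  }
  list(icc = icc, ci = ci, msr = msr, msc = msc, mse = mse)
}

#' Bland–Altman agreement analysis
#'
#' Differences are candidate minus reference; bias is their mean, and the
#' limits of agreement are `bias +/- 1.96 * SD` (sample SD). The per-pair
#' means and differences are returned for plotting.
#'
#' @param pairs A `"paired_measurements"` object or a 2-column matrix
#'   (reference, candidate), >= 2 pairs.
#' @return List with `bias`, `diff_sd`, `loa` (length-2), `mean` and `diff`
#'   vectors.
#' @export
bland_altman <- function(pairs) {
  if (inherits(pairs, "paired_measurements")) {
    ref <- pairs$reference_ms
    cand <- pairs$candidate_ms
  } else {
    ref <- pairs[, 1L]
    cand <- pairs[, 2L]
  }
  if (length(ref) < 2L) stop("need >= 2 pairs")
  d <- cand - ref
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, diff_sd = s, loa = c(bias - 1.96 * s, bias + 1.96 * s),
       mean = (cand + ref) / 2, diff = d)
}

#' Morphology-stratified difference table
#'
#' Mean and SD of the candidate-minus-reference differences for each
#' T-wave morphology present, plus an `"all"` row pooling every pair.
#' Morphology classes with no pairs are omitted.
#'
#' @param pairs A `"paired_measurements"` data frame.
#' @param labels Character vector of morphology labels, one per pair (e.g.
#'   the record-level class replicated over its beats).
#' @return Data frame with `morphology`, `n`, `bias`, `sd`.
#' @export
morphology_table <- function(pairs, labels) {
  if (length(labels) != nrow(pairs)) {
    stop("need one morphology label per pair")
  }
  if (anyNA(labels)) {
    stop("unlabeled pair(s) at row(s): ",
         paste(which(is.na(labels)), collapse = ", "))
  }
  d <- pairs$candidate_ms - pairs$reference_ms
  rows <- lapply(unique(labels), function(lb) {
    di <- d[labels == lb]
    data.frame(morphology = lb, n = length(di), bias = mean(di),
               sd = stats::sd(di), stringsAsFactors = FALSE)
  })
  rbind(do.call(rbind, rows),
        data.frame(morphology = "all", n = length(d), bias = mean(d),
                   sd = stats::sd(d), stringsAsFactors = FALSE))
}

#' Full agreement report between candidate and reference measurements
#'
#' @param pairs A `"paired_measurements"` data frame.
#' @param labels Optional morphology labels per pair.
#' @return An `"agreement_report"`: list with `icc` (from [icc_2_1()]),
#'   `bland_altman`, `pearson_r`, `n_pairs`, and `morphology` table when
#'   labels are given.
#' @export
agreement_report <- function(pairs, labels = NULL) {
  rep <- list(
    icc = icc_2_1(pairs),
    bland_altman = bland_altman(pairs),
    pearson_r = stats::cor(pairs$reference_ms, pairs$candidate_ms),
    n_pairs = nrow(pairs),
    morphology = if (!is.null(labels)) morphology_table(pairs, labels))
  class(rep) <- "agreement_report"
  rep
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement over %d pairs:\n", x$n_pairs))
  cat(sprintf("  ICC(2,1) %.3f [%.3f, %.3f]\n", x$icc$icc, x$icc$ci[1L],
              x$icc$ci[2L]))
  cat(sprintf("  bias %.2f ms (SD %.2f), LoA [%.2f, %.2f]\n",
              x$bland_altman$bias, x$bland_altman$diff_sd,
              x$bland_altman$loa[1L], x$bland_altman$loa[2L]))
  cat(sprintf("  Pearson r %.3f\n", x$pearson_r))
  if (!is.null(x$morphology)) {
    cat("  by morphology:\n")
    m <- x$morphology
    for (i in seq_len(nrow(m))) {
      cat(sprintf("    %-9s n=%4d  %+.1f (+/-%.1f) ms\n", m$morphology[i],
                  m$n[i], m$bias[i], m$sd[i]))
    }
  }
  invisible(x)
}
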