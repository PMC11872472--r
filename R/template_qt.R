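#' Cluster the beats of a record
#'
#' Convenience wrapper tying the beat set to the clustering model: fits
#' K-shape on the retained (z-normalized) beats, excludes clusters smaller
#' than `min_cluster_size` (their beats get exclusion reason
#' `"cluster_small"`), and stores the per-beat cluster id.
#'
#' @param bs A `"beat_set"` after [znormalize_beats()].
#' @param k,n_init,max_iter,seed Passed to [kshape_fit()].
#' @param min_cluster_size Minimum cluster size kept (default 5).
#' @return A `"qt_clustering"`: list with `bs` (beat set with added
#'   `cluster` column), `model` (the `"kshape_model"`), and `rows` (the rows
#'   of `bs` the model was fitted on).
#' @export
qt_cluster <- function(bs, k = 12L, n_init = 100L, max_iter = 100L, seed = 0L,
                       min_cluster_size = 5L) {
  if (is.null(bs$z)) bs <- znormalize_beats(bs)
  rows <- which(!bs$beats$excluded)
  model <- kshape_fit(bs$z[rows, , drop = FALSE], k = k, n_init = n_init,
                      max_iter = max_iter, seed = seed)
  model <- filter_small_clusters(model, min_size = min_cluster_size)
  bs$beats$cluster <- NA_integer_
  bs$beats$cluster[rows] <- model$labels
  dropped <- rows[is.na(model$labels)]
  if (length(dropped)) {
    bs$beats$excluded[dropped] <- TRUE
    bs$beats$exclusion_reason[dropped] <- "cluster_small"
  }
  structure(list(bs = bs, model = model, rows = rows),
            class = "qt_clustering")
}

#' Select one template beat per cluster by DTW distance to the centroid
#'
#' For every surviving cluster the DTW distance from the centroid to each
#' member beat is computed; the member with the smallest distance becomes
#' the cluster's template (ties go to the lowest beat index). The per-beat
#' distances are kept on the beat table (`dtw_dist`) for the outlier
#' exclusion step. Empty clusters are skipped with a warning.
#'
#' @param cl A `"qt_clustering"` from [qt_cluster()].
#' @return The clustering object with `templates` attached: a list of
#'   `"qt_template"` objects (fields `cluster_id`, `beat_index`, `samples`
#'   raw mV, `z` normalized, `qrs_onset`, `t_end` — fiducials `NA` until
#'   registered).
#' @export
select_templates <- function(cl) {
  bs <- cl$bs
  b <- bs$beats
  b$dtw_dist <- NA_real_
  templates <- list()
  for (j in seq_len(cl$model$k)) {
    rows <- which(!is.na(b$cluster) & b$cluster == j & !b$excluded)
    if (length(rows) == 0L) {
      if (!(j %in% cl$model$small_clusters)) {
        warning("cluster ", j, " has no retained beats; no template")
      }
      next
    }
    d <- vapply(rows, function(r) {
      dtw(cl$model$centroids[j, ], bs$z[r, ])$distance
    }, numeric(1L))
    b$dtw_dist[rows] <- d
    pick <- rows[which.min(d)]          # which.min takes the first = lowest index
    templates[[length(templates) + 1L]] <- structure(
      list(cluster_id = j, beat_index = b$beat_index[pick],
           samples = bs$samples[pick, ], z = bs$z[pick, ],
           qrs_onset = NA_integer_, t_end = NA_integer_),
      class = "qt_template")
  }
  cl$bs$beats <- b
  cl$templates <- templates
  cl
}

#' Exclude beats far from their cluster centroid
#'
#' Within each cluster, beats whose DTW distance to the centroid reaches the
#' cluster's 90th percentile (linear-interpolation percentile, comparison
#' `>=`) are excluded, with two guards: a cluster where all distances are
#' equal loses no beats, and at most `ceiling(0.10 * size)` beats are
#' excluded per cluster (the largest distances first), so ties can never
#' empty a cluster.
#'
#' @param cl A `"qt_clustering"` after [select_templates()].
#' @param probs Percentile threshold (default 0.90).
#' @return The clustering object with outlier beats marked
#'   (`exclusion_reason "dtw_outlier"`).
#' @export
exclude_outlier_beats <- function(cl, probs = 0.90) {
  b <- cl$bs$beats
  for (j in unique(stats::na.omit(b$cluster))) {
    rows <- which(!is.na(b$cluster) & b$cluster == j & !b$excluded &
                    !is.na(b$dtw_dist))
    if (length(rows) < 2L) next
    d <- b$dtw_dist[rows]
    if (max(d) - min(d) <= 0) next              # degenerate all-equal cluster
    thr <- stats::quantile(d, probs, type = 7L, names = FALSE)
    over <- rows[d >= thr]
    cap <- ceiling((1 - probs) * length(rows))
    if (length(over) > cap) {
      over <- over[order(-b$dtw_dist[over], b$beat_index[over])][seq_len(cap)]
    }
    b$excluded[over] <- TRUE
    b$exclusion_reason[over] <- "dtw_outlier"
  }
  cl$bs$beats <- b
  cl
}

#' Attach registered fiducials to templates
#'
#' Consumes a fiducial registration table (see
#' [read_fiducial_registration()]): one row per template cluster giving the
#' 0-based QRS-onset and T-end sample indices within the 1600 ms template
#' window. In the production workflow these positions are placed manually on
#' each template by a trained operator; this function is the programmatic
#' side of that hand-off.
#'
#' @param cl A `"qt_clustering"` with templates.
#' @param registration Data frame with `cluster_id`, `qrs_onset`, `t_end`.
#' @return The clustering object with fiducials set on every template.
#' @export
register_fiducials <- function(cl, registration) {
  have <- vapply(cl$templates, function(t) t$cluster_id, integer(1L))
  missing <- setdiff(have, registration$cluster_id)
  if (length(missing)) {
    stop("no fiducial registration for cluster(s): ",
         paste(missing, collapse = ", "))
  }
  L <- cl$bs$L
  for (i in seq_along(cl$templates)) {
    row <- registration[registration$cluster_id ==
                          cl$templates[[i]]$cluster_id, ][1L, ]
    on <- as.integer(row$qrs_onset)
    te <- as.integer(row$t_end)
    if (!(on >= 0L && te > on && te < L)) {
      stop("invalid fiducials for cluster ", row$cluster_id,
           ": need 0 <= qrs_onset < t_end < ", L)
    }
    cl$templates[[i]]$qrs_onset <- on
    cl$templates[[i]]$t_end <- te
  }
  cl
}

#' Transfer template fiducials to a beat through a warping path
#'
#' Given the warping path between a template (first index) and a beat
#' (second index), the beat's QRS onset is the LATEST beat sample linked to
#' the template's registered onset, and the beat's T end is the EARLIEST
#' beat sample linked to the template's T end. This asymmetric rule keeps
#' the transferred QT conservative when the path lingers at a fiducial.
#'
#' @param template A registered `"qt_template"`.
#' @param path A `"warping_path"` (0-based, template index first).
#' @return Named integer vector `c(qrs_onset, t_end)` of beat sample
#'   indices within the beat window.
#' @export
transfer_fiducials <- function(template, path) {
  if (is.na(template$qrs_onset) || is.na(template$t_end)) {
    stop("template fiducials not registered")
  }
  j_on <- path[path[, 1L] == template$qrs_onset, 2L]
  j_te <- path[path[, 1L] == template$t_end, 2L]
  if (length(j_on) == 0L || length(j_te) == 0L) {
    stop("internal error: fiducial index absent from warping path")
  }
  c(qrs_onset = max(j_on), t_end = min(j_te))
}

#' QT interval from fiducial sample indices
#'
#' @param qrs_onset_beat,t_end_beat 0-based sample indices within the beat.
#' @param fs Sampling rate (Hz).
#' @return QT in ms; `NA` (invalid) when the interval is not positive.
#' @export
compute_qt <- function(qrs_onset_beat, t_end_beat, fs) {
  qt <- (t_end_beat - qrs_onset_beat) / fs * 1000
  qt[qt <= 0] <- NA_real_
  qt
}

#' Bazett heart-rate correction
#'
#' `QTcB = QT / sqrt(RR)` with the preceding RR interval expressed in
#' seconds. The preceding RR is used because the upstream exclusion rules
#' guarantee it lies in \[300, 2000\] ms.
#'
#' @param qt_ms QT interval(s) in ms.
#' @param rr_prev_ms Preceding RR interval(s) in ms (> 0).
#' @return QTcB in ms.
#' @export
#' @examples
#' bazett(400, 640)  # 500
bazett <- function(qt_ms, rr_prev_ms) {
  if (any(!is.na(rr_prev_ms) & rr_prev_ms <= 0)) {
    stop("rr_prev_ms must be > 0")
  }
  qt_ms / sqrt(rr_prev_ms / 1000)
}

#' Measure QT and QTcB for every retained beat
#'
#' For each retained beat, computes the LDTW warping path between its
#' cluster's registered template and the beat (both z-normalized,
#' `max_length = L + max_length_offset`, clipped to the vacuous bound),
#' transfers the template fiducials through the path, and derives QT and
#' Bazett-corrected QTcB. Beats whose transferred interval is not positive
#' are flagged `invalid_qt`.
#'
#' @param cl A registered `"qt_clustering"` (after [register_fiducials()]).
#' @param max_length_offset Added to the series length to form the LDTW
#'   path-length bound (default 10).
#' @return Data frame with columns `beat_index`, `r_peak`, `cluster_id`,
#'   `qrs_onset`, `t_end`, `rr_prev_ms`, `qt_ms`, `qtcb_ms`, `excluded`,
#'   `exclusion_reason` — one row per beat of the record, excluded beats
#'   carrying `NA` measurements.
#' @export
measure_qt <- function(cl, max_length_offset = 10L) {
  bs <- cl$bs
  b <- bs$beats
  L <- bs$L
  max_len <- min(L + max_length_offset, 2L * L - 1L)
  tmpl_by_cluster <- list()
  for (t in cl$templates) tmpl_by_cluster[[as.character(t$cluster_id)]] <- t

  n <- nrow(b)
  onset <- tend <- rep(NA_integer_, n)
  qt <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (b$excluded[i]) next
    t <- tmpl_by_cluster[[as.character(b$cluster[i])]]
    if (is.null(t)) next
    res <- ldtw(t$z, bs$z[i, ], max_length = max_len)
    fid <- transfer_fiducials(t, res$path)
    onset[i] <- fid[["qrs_onset"]]
    tend[i] <- fid[["t_end"]]
    qt[i] <- compute_qt(onset[i], tend[i], bs$fs)
    if (is.na(qt[i])) {
      b$excluded[i] <- TRUE
      b$exclusion_reason[i] <- "invalid_qt"
    }
  }
  qtcb <- bazett(qt, b$rr_prev)
  data.frame(beat_index = b$beat_index, r_peak = b$r_peak,
             cluster_id = b$cluster, qrs_onset = onset, t_end = tend,
             rr_prev_ms = b$rr_prev, qt_ms = qt, qtcb_ms = qtcb,
             excluded = b$excluded, exclusion_reason = b$exclusion_reason,
             stringsAsFactors = FALSE)
}

#' Run the full QT pipeline on a record
#'
#' Filter, segment, exclude, z-normalize, cluster, select templates,
#' exclude outliers, register fiducials and measure: the whole chain with
#' the production defaults, in one call.
#'
#' @param record An [ecg_record()] with R peaks attached.
#' @param registration Fiducial registration data frame, or a function
#'   `function(cl) data.frame(...)` called after template selection (useful
#'   when fiducials come from ground truth or an operator UI).
#' @param k,n_init,max_iter,seed,min_cluster_size Clustering controls.
#' @param outlier_percentile DTW outlier threshold (default 0.90).
#' @param max_length_offset LDTW path-length margin (default 10).
#' @param filter Logical: apply the low-pass filter first (default TRUE).
#' @param spec A [filter_spec()].
#' @return List with `measurements` (data frame), `clustering`
#'   (`"qt_clustering"`), and `counts` (beats retained/excluded by reason).
#' @export
qt_pipeline <- function(record, registration,
                        k = 12L, n_init = 100L, max_iter = 100L, seed = 0L,
                        min_cluster_size = 5L, outlier_percentile = 0.90,
                        max_length_offset = 10L, filter = TRUE,
                        spec = filter_spec()) {
  if (filter) {
    record$signal[1L, ] <- lowpass_filter(record$signal[1L, ], record$fs, spec)
  }
  bs <- extract_beats(record)
  bs <- apply_rr_exclusions(bs)
  bs <- znormalize_beats(bs)
  cl <- qt_cluster(bs, k = k, n_init = n_init, max_iter = max_iter,
                   seed = seed, min_cluster_size = min_cluster_size)
  cl <- select_templates(cl)
  cl <- exclude_outlier_beats(cl, probs = outlier_percentile)
  reg <- if (is.function(registration)) registration(cl) else registration
  cl <- register_fiducials(cl, reg)
  meas <- measure_qt(cl, max_length_offset = max_length_offset)
  counts <- table(meas$exclusion_reason)
  list(measurements = meas, clustering = cl, counts = counts)
}
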