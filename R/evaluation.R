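#' Match detected peaks against reference beats
#'
#' One-to-one greedy matching in increasing time: each reference beat may
#' claim at most one detection within `round(tol_s * fs)` samples, taking
#' the nearest unclaimed detection (ties resolve to the earlier one).
#' Matched pairs count as true positives, unmatched references as false
#' negatives, unmatched detections as false positives. With references
#' farther apart than twice the tolerance -- always the case for
#' physiological RR intervals and the default 50 ms window -- this greedy
#' scheme attains the optimal matching.
#'
#' @param peaks An `rpeak_set` or a sorted integer vector of 0-based
#'   detection indices.
#' @param truth A [beat_annotations] or a sorted integer vector of 0-based
#'   reference indices.
#' @param fs Sampling rate in Hz.
#' @param tol_s Tolerance window half-width in seconds (default 0.05,
#'   i.e. 50 ms).
#' @return A list with counts `TP`, `FN`, `FP` and a data frame `pairs`
#'   (`truth_index`, `peak_index` for each matched pair).
#' @export
match_beats <- function(peaks, truth, fs, tol_s = 0.05) {
  stopifnot(tol_s > 0, fs > 0)
  p <- if (inherits(peaks, "rpeak_set")) peaks$indices else as.integer(peaks)
  a <- if (inherits(truth, "beat_annotations")) truth$indices
       else as.integer(truth)
  tol <- as.integer(round(tol_s * fs))
  used <- logical(length(p))
  ti <- integer(0); pi <- integer(0)
  for (k in seq_along(a)) {
    cand <- which(!used & abs(p - a[k]) <= tol)
    if (length(cand)) {
      d <- abs(p[cand] - a[k])
      best <- cand[which(d == min(d))][1L]  # tie -> earlier detection
      used[best] <- TRUE
      ti <- c(ti, a[k]); pi <- c(pi, p[best])
    }
  }
  list(TP = length(ti), FN = length(a) - length(ti),
       FP = length(p) - length(ti),
       pairs = data.frame(truth_index = ti, peak_index = pi))
}

#' Beat-detection performance metrics
#'
#' Sensitivity `SEN = 100 * TP / (TP + FN)`, positive predictivity
#' `+P = 100 * TP / (TP + FP)` and accuracy
#' `ACC = 100 * TP / (TP + FN + FP)`, reported to 2 decimals. Inputs are
#' vectorized; one row is returned per element.
#'
#' @param TP,FN,FP Non-negative counts (`TP + FN > 0` per row).
#' @param record_id Optional record identifier(s).
#' @return A data frame of class `eval_report` with columns `record_id`,
#'   `total_beats`, `TP`, `FN`, `FP`, `SEN`, `pos_pred`, `ACC`.
#' @export
detection_metrics <- function(TP, FN, FP, record_id = "record") {
  if (any(TP < 0 | FN < 0 | FP < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(TP + FN == 0))
    stop("metrics undefined when TP + FN = 0 (no reference beats)",
         call. = FALSE)
  out <- data.frame(
    record_id = rep_len(as.character(record_id), length(TP)),
    total_beats = TP + FN, TP = TP, FN = FN, FP = FP,
    SEN = round(100 * TP / (TP + FN), 2),
    pos_pred = round(100 * TP / (TP + FP), 2),
    ACC = round(100 * TP / (TP + FN + FP), 2))
  class(out) <- c("eval_report", class(out))
  out
}

#' Detect and evaluate one record
#'
#' Convenience wrapper: runs [detect_rpeaks()], matches against the
#' reference annotations and computes the metrics.
#'
#' @param rec An [ecg_record].
#' @param truth A [beat_annotations].
#' @param params A [threshold_params].
#' @param tol_s Tolerance window half-width in seconds.
#' @param ... Further arguments passed to [detect_rpeaks()].
#' @return A one-row `eval_report` (see [detection_metrics()]); the
#'   `rpeak_set` is attached as attribute `"peaks"`.
#' @export
evaluate_detection <- function(rec, truth, params = threshold_params(),
                               tol_s = 0.05, ...) {
  peaks <- detect_rpeaks(rec, params = params, ...)
  m <- match_beats(peaks, truth, rec$fs, tol_s)
  rep <- detection_metrics(m$TP, m$FN, m$FP, record_id = rec$record_id)
  attr(rep, "peaks") <- peaks
  rep
}

#' Sweep the threshold coefficients over a grid
#'
#' Re-runs the thresholding stage for every `(K_amp, K_time)` grid cell on
#' every record, pooling TP/FN/FP across records before computing the
#' percentages (pooled totals, not record averages). The enhancement,
#' mirroring and local-maximum stages do not depend on the coefficients and
#' are computed once per record.
#'
#' @param records A list of `list(record = <ecg_record>,
#'   truth = <beat_annotations>)` pairs.
#' @param K_amp_grid,K_time_grid Non-empty numeric grids.
#' @param params Base [threshold_params] supplying `segment_s` and
#'   `width_cap_s`.
#' @param tol_s Tolerance window half-width in seconds.
#' @param mirror_cfg A [mirror_config].
#' @param ... Further arguments passed to [wmra_enhance()].
#' @return A data frame of class `sweep_result`, one row per grid cell:
#'   `K_amp`, `K_time`, `TP`, `FN`, `FP`, `SEN`, `pos_pred`, `ACC`,
#'   `n_detections`.
#' @export
threshold_sweep <- function(records, K_amp_grid, K_time_grid,
                            params = threshold_params(), tol_s = 0.05,
                            mirror_cfg = mirror_config(), ...) {
  stopifnot(length(K_amp_grid) >= 1L, length(K_time_grid) >= 1L,
            length(records) >= 1L)
  stages <- lapply(records, function(r) {
    enh <- wmra_enhance(r$record, ...)
    .detect_prepare(enh, mirror_cfg)
  })
  grid <- expand.grid(K_amp = K_amp_grid, K_time = K_time_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    p <- threshold_params(K_amp = grid$K_amp[g], K_time = grid$K_time[g],
                          segment_s = params$segment_s,
                          width_cap_s = params$width_cap_s)
    tp <- fn <- fp <- nd <- 0L
    for (ri in seq_along(records)) {
      peaks <- .detect_threshold(stages[[ri]], p,
                                 records[[ri]]$record$record_id)
      m <- match_beats(peaks, records[[ri]]$truth, records[[ri]]$record$fs,
                       tol_s)
      tp <- tp + m$TP; fn <- fn + m$FN; fp <- fp + m$FP
      nd <- nd + length(peaks$indices)
    }
    met <- detection_metrics(tp, fn, fp, record_id = "pooled")
    data.frame(K_amp = grid$K_amp[g], K_time = grid$K_time[g],
               TP = tp, FN = fn, FP = fp, SEN = met$SEN,
               pos_pred = met$pos_pred, ACC = met$ACC, n_detections = nd)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Published per-record reference results
#'
#' Per-record beat counts and detection tallies (total beats, TP, FN, FP and
#' the printed SEN/+P/ACC percentages) reported for this detector on the
#' MIT-BIH arrhythmia database (48 records, 360 Hz) and the QT database
#' (82 annotated records, 250 Hz), bundled as plain CSV. They serve as
#' arithmetic regression fixtures for [detection_metrics()] and as the
#' pooled-total inputs for reproducing the published summary percentages.
#'
#' @param db `"mitdb"`, `"qtdb"`, or `"sweep"` for the published
#'   `(K_amp, K_time)` coefficient sweep summary.
#' @return A data frame.
#' @export
reference_results <- function(db = c("mitdb", "qtdb", "sweep")) {
  db <- match.arg(db)
  f <- system.file("extdata",
                   switch(db,
                          mitdb = "mitdb_reference_results.csv",
                          qtdb = "qtdb_reference_results.csv",
                          sweep = "threshold_coefficient_sweep.csv"),
                   package = "rpeakr", mustWork = TRUE)
  df <- utils::read.csv(f)
  if (db != "sweep") df$record <- as.character(df$record)
  df
}
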