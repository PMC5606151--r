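#' Adaptive threshold parameters
#'
#' @param K_amp Amplitude-threshold coefficient: within each segment
#'   `a_t = K_amp * max(segment amplitude)` (default 0.25; in (0, 1)).
#' @param K_time Time-interval coefficient:
#'   `ti_t = K_time * mean(adjacent surviving-candidate spacing)` (default
#'   0.45; in (0, 1)).
#' @param segment_s Length of each thresholding segment in seconds
#'   (default 10).
#' @param width_cap_s Per-side cap, in seconds, when measuring a peak's width
#'   along the baseline (default 0.278, the mirroring window).
#' @return A list of class `threshold_params`.
#' @export
threshold_params <- function(K_amp = 0.25, K_time = 0.45, segment_s = 10,
                             width_cap_s = 0.278) {
  stopifnot(K_amp >= 0, K_amp < 1, K_time > 0, K_time < 1, segment_s > 0,
            width_cap_s > 0)
  structure(list(K_amp = K_amp, K_time = K_time, segment_s = segment_s,
                 width_cap_s = width_cap_s),
            class = "threshold_params")
}

## average RR (seconds) used to bootstrap ti_t when a segment offers fewer
## than two surviving candidates and no previous segment exists
.bootstrap_rr_s <- 0.82

#' Per-segment adaptive thresholds
#'
#' `a_t = K_amp * MAX_seg_amp` with `MAX_seg_amp` the maximum signal
#' amplitude inside the segment; `ti_t = K_time * AVE_max_dis` with
#' `AVE_max_dis` the mean index spacing of adjacent candidates that survive
#' the amplitude threshold inside the segment. With fewer than two survivors
#' `ti_t` is carried over from the previous segment, or bootstrapped as
#' `K_time * 0.82 * fs` (0.82 s being a representative average RR interval)
#' for the first segment.
#'
#' @param candidates A `candidate_set` (from [local_maxima()]).
#' @param signal The numeric signal the candidates index into.
#' @param seg Integer pair `(start, end)`: 0-based segment bounds,
#'   start-inclusive, end-exclusive.
#' @param params A [threshold_params].
#' @param fs Sampling rate in Hz (used only for the bootstrap).
#' @param prev_ti_t Previous segment's `ti_t` in samples, or `NULL`.
#' @return A list of class `segment_thresholds`: `a_t`, `ti_t`,
#'   `max_seg_amp`, `ave_max_dis` (`NA` when carried), `segment`, and
#'   `carried` (`TRUE` when `ti_t` was inherited or bootstrapped).
#' @export
segment_thresholds <- function(candidates, signal, seg, params, fs,
                               prev_ti_t = NULL) {
  stopifnot(inherits(params, "threshold_params"), length(seg) == 2L)
  lo <- as.integer(seg[1L]); hi <- as.integer(seg[2L])
  stopifnot(lo >= 0L, hi > lo, hi <= length(signal))
  max_seg_amp <- max(signal[(lo + 1L):hi])
  a_t <- params$K_amp * max_seg_amp
  inseg <- candidates[candidates$index >= lo & candidates$index < hi, ,
                      drop = FALSE]
  surv <- amplitude_filter(inseg, a_t)
  if (nrow(surv) >= 2L) {
    ave_max_dis <- mean(diff(surv$index))
    ti_t <- params$K_time * ave_max_dis
    carried <- FALSE
  } else {
    ave_max_dis <- NA_real_
    ti_t <- if (!is.null(prev_ti_t)) prev_ti_t
            else params$K_time * .bootstrap_rr_s * fs
    carried <- TRUE
  }
  structure(list(a_t = a_t, ti_t = ti_t, max_seg_amp = max_seg_amp,
                 ave_max_dis = ave_max_dis, segment = c(lo, hi),
                 carried = carried),
            class = "segment_thresholds")
}

#' Filter candidates by the amplitude threshold
#'
#' Retains exactly the candidates whose amplitude exceeds `a_t`, preserving
#' order.
#'
#' @param candidates A `candidate_set`.
#' @param a_t Amplitude threshold in mV (>= 0).
#' @return The filtered `candidate_set`.
#' @export
amplitude_filter <- function(candidates, a_t) {
  stopifnot(a_t >= 0 || is.na(a_t))
  candidates[candidates$amplitude > a_t, , drop = FALSE]
}

#' Width of a peak along the baseline
#'
#' Measures how far the signal stays positive around a peak: the distance
#' from the last non-positive sample at/before the peak to the first
#' non-positive sample at/after it. Each side searches at most
#' `round(cap_s * fs)` samples and contributes the cap when no crossing is
#' found within it.
#'
#' @param signal Numeric vector (baseline at 0).
#' @param index 0-based peak position; `signal[index] > 0` is required.
#' @param fs Sampling rate in Hz.
#' @param cap_s Per-side search cap in seconds (default 0.278).
#' @return Width in samples (>= 1).
#' @export
peak_width <- function(signal, index, fs, cap_s = 0.278) {
  x <- as.numeric(signal)
  i <- as.integer(index) + 1L  # to 1-based
  stopifnot(i >= 1L, i <= length(x))
  if (x[i] <= 0)
    stop("peak_width requires a positive sample at `index`", call. = FALSE)
  cap <- max(1L, as.integer(round(cap_s * fs)))
  left <- cap
  if (i > 1L) {
    lo <- max(1L, i - cap)
    seg <- x[lo:(i - 1L)]
    cross <- which(seg <= 0)
    if (length(cross)) left <- i - (lo + cross[length(cross)] - 1L)
  }
  right <- cap
  if (i < length(x)) {
    hi <- min(length(x), i + cap)
    seg <- x[(i + 1L):hi]
    cross <- which(seg <= 0)
    if (length(cross)) right <- cross[1L]
  }
  as.integer(left + right)
}

#' Arbitrate closely spaced candidates with the time-interval threshold
#'
#' Implements the pairwise recognition procedure. The first candidate is the
#' true reference `Tref`, the next one the comparative reference `Cref`.
#' When their spacing `t_p >= ti_t`, `Tref` is accepted and `Cref` becomes
#' the new reference. When `t_p < ti_t` one of the two is false: the
#' narrower peak wins (widths along the baseline); on a width tie the larger
#' amplitude wins, with an exact amplitude tie resolving to `Cref`. The
#' loser is discarded, the winner keeps the reference role and the next
#' candidate steps in as the new `Cref`. A final lone reference is accepted.
#' Consecutive accepted peaks are therefore always at least `ti_t` apart.
#'
#' @param candidates A `candidate_set` (already amplitude-filtered), or a
#'   data frame with columns `index`, `amplitude` and optionally `width`.
#' @param ti_t Time-interval threshold in samples (> 0).
#' @param signal Signal used to measure peak widths when `candidates` has no
#'   `width` column.
#' @param fs Sampling rate (needed with `signal`).
#' @param width_cap_s Per-side width cap in seconds, see [peak_width()].
#' @return Integer vector of accepted 0-based peak indices.
#' @export
recognize_peaks <- function(candidates, ti_t, signal = NULL, fs = NULL,
                            width_cap_s = 0.278) {
  n <- nrow(candidates)
  if (!n) return(integer(0))
  stopifnot(ti_t > 0)
  if (is.null(candidates$width)) {
    if (is.null(signal) || is.null(fs))
      stop("either a `width` column or `signal` + `fs` is required",
           call. = FALSE)
    candidates$width <- vapply(
      candidates$index, function(i) peak_width(signal, i, fs, width_cap_s),
      integer(1))
  }
  keep <- .recognize_core(candidates$index, candidates$amplitude,
                          candidates$width, ti_t)
  as.integer(candidates$index[keep])
}

## returns the row positions of accepted candidates
.recognize_core <- function(index, amplitude, width, ti_t) {
  n <- length(index)
  if (!n) return(integer(0))
  acc <- integer(0)
  t <- 1L  # Tref
  cr <- 2L # Cref
  while (cr <= n) {
    tp <- index[cr] - index[t]
    if (tp >= ti_t) {
      acc <- c(acc, t)
      t <- cr
    } else {
      tref_wins <-
        if (width[t] < width[cr]) TRUE
        else if (width[t] > width[cr]) FALSE
        else amplitude[t] > amplitude[cr]     # amplitude tie -> Cref
      if (!tref_wins) t <- cr
    }
    cr <- cr + 1L
  }
  c(acc, t)
}

#' Detect R-peaks in an ECG record
#'
#' Runs the full pipeline: wavelet enhancement ([wmra_enhance()]), mirroring
#' of large negative deflections ([mirror_signal()]), local-maximum location
#' ([local_maxima()]), then per-segment adaptive thresholding
#' ([segment_thresholds()], [amplitude_filter()], [recognize_peaks()]) over
#' contiguous non-overlapping segments of `segment_s` seconds. The last
#' accepted peak of a segment is carried into the next segment's first
#' time-interval comparison (and may be revoked if that comparison finds a
#' narrower, larger rival), so accepted peaks are never closer than the
#' local `ti_t` across a boundary. Returned indices refer to the original
#' sample grid.
#'
#' @param rec An [ecg_record].
#' @param params A [threshold_params].
#' @param mirror_cfg A [mirror_config]; set `enabled = FALSE` for the
#'   no-mirroring ablation.
#' @param wavelet,levels,shrinkage,keep Passed to [wmra_enhance()].
#' @param enhance Set `FALSE` to skip wavelet enhancement (the signal is
#'   then assumed to already have a zero baseline).
#' @return An object of class `rpeak_set`: list with `indices` (0-based,
#'   strictly increasing), `fs`, `record_id`, `thresholds` (one row per
#'   segment: bounds, `a_t`, `ti_t`, `max_seg_amp`, `ave_max_dis`,
#'   candidate/survivor counts), and `params`.
#' @export
detect_rpeaks <- function(rec, params = threshold_params(),
                          mirror_cfg = mirror_config(),
                          wavelet = "bior6.8", levels = 8L,
                          shrinkage = c("universal", "none"), keep = NULL,
                          enhance = TRUE) {
  stopifnot(inherits(rec, "ecg_record"), inherits(params, "threshold_params"))
  enh <- if (enhance)
    wmra_enhance(rec, wavelet = wavelet, levels = levels,
                 shrinkage = shrinkage, keep = keep)
  else rec
  stage <- .detect_prepare(enh, mirror_cfg)
  .detect_threshold(stage, params, rec$record_id)
}

## enhancement-independent precomputation shared by detect_rpeaks and sweeps
.detect_prepare <- function(enh, mirror_cfg) {
  mir <- mirror_signal(enh$samples, enh$fs, mirror_cfg)
  list(samples = mir$samples, fs = enh$fs,
       candidates = local_maxima(mir$samples),
       mirrored_runs = mir$mirrored_runs)
}

.detect_threshold <- function(stage, params, record_id = "ecg") {
  x <- stage$samples
  fs <- stage$fs
  L <- length(x)
  seg_len <- max(1L, as.integer(round(params$segment_s * fs)))
  starts <- seq(0L, L - 1L, by = seg_len)
  accepted <- integer(0)
  prev_ti_t <- NULL
  thr_rows <- vector("list", length(starts))
  for (si in seq_along(starts)) {
    lo <- starts[si]
    hi <- min(L, lo + seg_len)
    thr <- segment_thresholds(stage$candidates, x, c(lo, hi), params, fs,
                              prev_ti_t = prev_ti_t)
    inseg <- stage$candidates[stage$candidates$index >= lo &
                              stage$candidates$index < hi, , drop = FALSE]
    surv <- amplitude_filter(inseg, thr$a_t)
    n_cand <- nrow(inseg)
    n_surv <- nrow(surv)
    if (n_surv) {
      surv$width <- vapply(surv$index,
                           function(i) peak_width(x, i, fs,
                                                  params$width_cap_s),
                           integer(1))
      carry <- length(accepted) > 0L
      if (carry) {
        p <- accepted[length(accepted)]
        prev_row <- data.frame(index = p, amplitude = x[p + 1L],
                               width = peak_width(x, p, fs,
                                                  params$width_cap_s))
        block <- rbind(prev_row, surv)
      } else block <- surv
      keep <- .recognize_core(block$index, block$amplitude, block$width,
                              thr$ti_t)
      if (carry) {
        if (!(1L %in% keep))  # the carried peak lost an arbitration
          accepted <- accepted[-length(accepted)]
        keep <- keep[keep > 1L]
      }
      accepted <- c(accepted, as.integer(block$index[keep]))
    }
    prev_ti_t <- thr$ti_t
    thr_rows[[si]] <- data.frame(
      segment_start = lo, segment_end = hi, a_t = thr$a_t, ti_t = thr$ti_t,
      max_seg_amp = thr$max_seg_amp, ave_max_dis = thr$ave_max_dis,
      ti_t_carried = thr$carried, n_candidates = n_cand,
      n_survivors = n_surv)
  }
  structure(list(indices = accepted, fs = fs, record_id = record_id,
                 thresholds = do.call(rbind, thr_rows), params = params),
            class = "rpeak_set")
}

#' @export
print.rpeak_set <- function(x, ...) {
  cat(sprintf("<rpeak_set> %s: %d peaks @ %g Hz\n", x$record_id,
              length(x$indices), x$fs))
  invisible(x)
}
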