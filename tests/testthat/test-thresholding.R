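test_that("segment thresholds implement a_t and ti_t arithmetic", {
  fs <- 360
  # impulses every 0.8 s: 12 peaks of 2.0 mV inside a 10 s segment
  idx <- 144L + 288L * (0:11)
  x <- numeric(3600)
  x[idx + 1L] <- 2.0
  x[idx] <- 1.0; x[idx + 2L] <- 1.0  # make them local maxima
  cand <- local_maxima(x)
  thr <- segment_thresholds(cand, x, c(0, 3600), threshold_params(), fs)
  expect_equal(thr$max_seg_amp, 2.0)
  expect_equal(thr$a_t, 0.5)            # K_amp 0.25 * 2.0 mV
  expect_equal(thr$ave_max_dis, 288)
  expect_equal(thr$ti_t, 129.6)         # K_time 0.45 * 288
  expect_false(thr$carried)

  thr0 <- segment_thresholds(cand, x, c(0, 3600),
                             threshold_params(K_amp = 0), fs)
  expect_equal(thr0$a_t, 0)

  # empty segment: ti_t carried over, or bootstrapped from a 0.82 s RR
  empty <- data.frame(index = integer(0), amplitude = numeric(0))
  boot <- segment_thresholds(empty, x, c(0, 3600), threshold_params(), fs)
  expect_true(boot$carried)
  expect_equal(boot$ti_t, 0.45 * 0.82 * 360)
  carry <- segment_thresholds(empty, x, c(0, 3600), threshold_params(), fs,
                              prev_ti_t = 100)
  expect_equal(carry$ti_t, 100)
})

test_that("the amplitude filter keeps exactly the candidates above a_t", {
  cand <- data.frame(index = c(10L, 20L, 30L),
                     amplitude = c(0.1, 0.6, 0.4))
  expect_equal(amplitude_filter(cand, 0.5)$index, 20L)
  expect_equal(amplitude_filter(cand, 0)$index, cand$index)
  set.seed(31)
  for (r in 1:25) {
    rc <- data.frame(index = sort(sample(1e5, 50)),
                     amplitude = runif(50, -0.2, 2))
    at <- runif(1, 0, 1.5)
    got <- amplitude_filter(rc, at)
    expect_identical(got$index, rc$index[rc$amplitude > at])
  }
})

test_that("peak width measures baseline crossings with a per-side cap", {
  fs <- 360
  expect_equal(peak_width(c(0, 1, 2, 1, 0), 2L, fs), 4L)   # triangle
  expect_equal(peak_width(c(0, 1, 1, 1, 0), 2L, fs), 4L)   # w=3 rectangle
  cap <- round(0.278 * fs)
  expect_equal(peak_width(rep(1, 500), 250L, fs), 2L * cap) # no crossing
  expect_error(peak_width(c(0, -1, 0), 1L, fs), "positive")
})

test_that("recognition follows the five-step arbitration", {
  x <- NULL
  # spacing >= ti_t accepts both
  two <- data.frame(index = c(1000L, 1400L), amplitude = c(1, 1),
                    width = c(10L, 10L))
  expect_equal(recognize_peaks(two, 130), c(1000L, 1400L))
  # close pair: narrower width wins
  close1 <- data.frame(index = c(1000L, 1060L), amplitude = c(1, 1),
                       width = c(10L, 40L))
  expect_equal(recognize_peaks(close1, 130), 1000L)
  # wider Tref loses, winner carries on
  close2 <- data.frame(index = c(1000L, 1060L, 1400L),
                       amplitude = c(1, 1, 1), width = c(40L, 10L, 12L))
  expect_equal(recognize_peaks(close2, 130), c(1060L, 1400L))
  # width tie -> amplitude; exact amplitude tie -> Cref
  tie <- data.frame(index = c(1000L, 1060L), amplitude = c(0.8, 0.8),
                    width = c(10L, 10L))
  expect_equal(recognize_peaks(tie, 130), 1060L)
  ampwin <- data.frame(index = c(1000L, 1060L), amplitude = c(0.9, 0.8),
                       width = c(10L, 10L))
  expect_equal(recognize_peaks(ampwin, 130), 1000L)
  # empty input
  expect_length(recognize_peaks(data.frame(index = integer(0),
                                           amplitude = numeric(0),
                                           width = integer(0)), 130), 0L)
})

test_that("recognition equals the literal step-by-step transcription", {
  set.seed(4242)
  for (r in 1:200) {
    n <- sample(2:40, 1)
    rc <- random_candidates(n)
    ti_t <- sample(60:250, 1)
    got <- recognize_peaks(rc, ti_t)
    ref <- recognize_reference(rc$index, rc$amplitude, rc$width, ti_t)
    expect_identical(got, as.integer(ref))
    expect_true(all(diff(got) >= ti_t))
  }
})

test_that("detection finds every beat of a clean noisy fixture", {
  syn <- synth_ecg(synth_config(duration_s = 48.2, noise_sd = 0.05,
                                seed = 11))
  peaks <- detect_rpeaks(syn$record)
  m <- match_beats(peaks, syn$annotations, syn$record$fs)
  expect_equal(m$FN, 0L)
  expect_equal(m$FP, 0L)
  # every detection within 50 ms of its beat
  expect_true(all(abs(m$pairs$peak_index - m$pairs$truth_index) <= 18))
})

test_that("detected peaks respect the per-segment time-interval threshold", {
  syn <- synth_ecg(synth_preset("noisy"))
  peaks <- detect_rpeaks(syn$record)
  expect_true(all(diff(peaks$indices) >= min(peaks$thresholds$ti_t)))
  expect_true(all(peaks$thresholds$a_t >= 0))
})

test_that("a flat record yields no peaks", {
  rec <- ecg_record(numeric(4000), 360, "flat")
  peaks <- detect_rpeaks(rec)
  expect_length(peaks$indices, 0L)
})

test_that("mirroring is what recovers inverted-R beats", {
  syn <- synth_ecg(synth_preset("pvc"))
  on <- detect_rpeaks(syn$record)
  off <- detect_rpeaks(syn$record, mirror_cfg = mirror_config(enabled = FALSE))
  m_on <- match_beats(on, syn$annotations, 360)
  m_off <- match_beats(off, syn$annotations, 360)
  expect_gt(m_on$TP, m_off$TP)
  # the beats lost without mirroring are the PVC-like ones
  missed <- setdiff(syn$annotations$indices, m_off$pairs$truth_index)
  lab <- syn$annotations$labels[match(missed, syn$annotations$indices)]
  expect_true(all(lab == "V"))
  expect_gt(length(missed), 0L)
})
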