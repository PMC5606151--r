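test_that("matching handles identity and out-of-window detections", {
  fs <- 360
  truth <- c(1000L, 1400L, 1800L)
  m <- match_beats(truth, truth, fs)
  expect_equal(c(m$TP, m$FN, m$FP), c(3L, 0L, 0L))
  # 60 ms away at 360 Hz (22 samples) is outside the 50 ms window
  m2 <- match_beats(1022L, 1000L, fs)
  expect_equal(c(m2$TP, m2$FN, m2$FP), c(0L, 1L, 1L))
  # 40 ms away is inside
  m3 <- match_beats(1014L, 1000L, fs)
  expect_equal(c(m3$TP, m3$FN, m3$FP), c(1L, 0L, 0L))
})

test_that("greedy matching attains the optimal bipartite matching", {
  skip_if_not_installed("igraph")
  set.seed(2024)
  fs <- 250
  tol <- round(0.05 * fs)
  for (r in 1:50) {
    nt <- sample(5:40, 1)
    truth <- cumsum(sample((2 * tol + 2):(3 * tol), nt, replace = TRUE))
    keep <- runif(nt) > 0.15
    det <- truth[keep] + sample((-2 * tol):(2 * tol), sum(keep),
                                replace = TRUE)
    det <- sort(unique(c(det, sample(max(truth), 5))))  # spurious extras
    m <- match_beats(det, truth, fs)
    expect_identical(m$TP, match_oracle_tp(det, truth, tol))
    expect_equal(m$FN, nt - m$TP)
    expect_equal(m$FP, length(det) - m$TP)
  }
})

test_that("matching is symmetric between false positives and negatives", {
  set.seed(5)
  fs <- 360
  a <- cumsum(sample(100:400, 30, replace = TRUE))
  b <- cumsum(sample(100:400, 33, replace = TRUE))
  expect_equal(match_beats(a, b, fs)$FP, match_beats(b, a, fs)$FN)
})

test_that("metrics reproduce printed per-record rows to two decimals", {
  r105 <- detection_metrics(2528, 44, 50, "105")
  expect_equal(r105$SEN, 98.29)
  expect_equal(r105$pos_pred, 98.06)
  expect_equal(r105$ACC, 96.41)
  r207 <- detection_metrics(2018, 314, 328, "207")
  expect_equal(c(r207$SEN, r207$pos_pred, r207$ACC),
               c(86.54, 86.02, 75.86))
  perfect <- detection_metrics(100, 0, 0)
  expect_equal(c(perfect$SEN, perfect$pos_pred, perfect$ACC),
               c(100, 100, 100))
  expect_equal(r105$total_beats, 2572)
  expect_error(detection_metrics(0, 0, 5), "undefined")
  expect_error(detection_metrics(-1, 2, 3), "non-negative")
})

test_that("metrics are scale-free in the counts", {
  base <- detection_metrics(400, 13, 29)
  for (c in c(2, 7, 100)) {
    scaled <- detection_metrics(400 * c, 13 * c, 29 * c)
    expect_equal(scaled[, c("SEN", "pos_pred", "ACC")],
                 base[, c("SEN", "pos_pred", "ACC")])
  }
})

test_that("a 1x1 sweep equals a direct detect-and-evaluate run", {
  syn <- synth_ecg(synth_config(duration_s = 30, noise_sd = 0.03, seed = 9))
  records <- list(list(record = syn$record, truth = syn$annotations))
  sw <- threshold_sweep(records, 0.25, 0.45)
  direct <- evaluate_detection(syn$record, syn$annotations)
  expect_equal(sw$TP, direct$TP)
  expect_equal(sw$FN, direct$FN)
  expect_equal(sw$FP, direct$FP)
  expect_equal(sw$SEN, direct$SEN)
  expect_equal(nrow(sw), 1L)
})

test_that("sweep pools counts across records before taking percentages", {
  s1 <- synth_ecg(synth_config(duration_s = 20, noise_sd = 0.05, seed = 13))
  s2 <- synth_ecg(synth_config(duration_s = 25, noise_sd = 0.05, seed = 14))
  records <- list(list(record = s1$record, truth = s1$annotations),
                  list(record = s2$record, truth = s2$annotations))
  sw <- threshold_sweep(records, 0.25, 0.45)
  e1 <- evaluate_detection(s1$record, s1$annotations)
  e2 <- evaluate_detection(s2$record, s2$annotations)
  expect_equal(sw$TP, e1$TP + e2$TP)
  expect_equal(sw$SEN,
               round(100 * sw$TP / (sw$TP + sw$FN), 2))
})

test_that("bundled reference tables load with the published shape", {
  mit <- reference_results("mitdb")
  qt <- reference_results("qtdb")
  expect_equal(nrow(mit), 48L)
  expect_equal(nrow(qt), 82L)
  expect_equal(sum(mit$total_beats), 109966)
  expect_equal(sum(qt$total_beats), 86995)
  sw <- reference_results("sweep")
  expect_equal(nrow(sw), 81L)
  expect_equal(sort(unique(sw$K_amp)), seq(0.10, 0.50, by = 0.05))
})
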