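test_that("CSV signals read back with the requested sampling rate", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sample_index = 0:4,
                              amplitude = c(0, 0.5, 1.2, 0.5, 0)),
                   f, row.names = FALSE)
  rec <- read_ecg(f, fs = 360)
  expect_s3_class(rec, "ecg_record")
  expect_length(rec, 5L)
  expect_equal(rec$fs, 360)
  expect_equal(rec$samples, c(0, 0.5, 1.2, 0.5, 0))
})

test_that("record validation rejects bad inputs with informative errors", {
  expect_error(read_ecg("does-not-exist.csv", fs = 360), "no such file")
  expect_error(read_ecg("does-not-exist.hea"), "no such file")
  expect_error(ecg_record(numeric(0), 360), "non-empty")
  expect_error(ecg_record(c(1, NA, 2), 360), "index 1")
  expect_error(ecg_record(1:5, 0), "positive")
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sample_index = 0:2,
                              amplitude = c(0, NA, 1)), f, row.names = FALSE)
  expect_error(read_ecg(f, fs = 250), "index 1")
})

test_that("WFDB records round-trip through formats 16 and 212", {
  set.seed(42)
  x <- round(rnorm(1000, sd = 0.8), 3)
  rec <- ecg_record(x, 360, "rt")
  for (fmt in c("16", "212")) {
    base <- file.path(withr::local_tempdir(), paste0("rt", fmt))
    write_wfdb_record(rec, base, format = fmt)
    back <- read_ecg(paste0(base, ".hea"))
    expect_equal(back$fs, 360)
    expect_length(back, 1000L)
    # gain 200 adu/mV: quantization error at most half an adu
    expect_lt(max(abs(back$samples - x)), 1 / 200 / 2 + 1e-9)
    expect_error(read_ecg(paste0(base, ".hea"), channel = 1),
                 "out of range")
  }
})

test_that("annotation files round-trip, including long gaps", {
  d <- withr::local_tempdir()
  set.seed(7)
  idx <- sort(sample(0:900000, 120))  # forces SKIP words (gaps > 1023)
  ann <- beat_annotations(idx, rep(c("N", "V"), 60))
  f <- file.path(d, "rt.atr")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_identical(back$indices, as.integer(idx))
  expect_identical(back$labels, ann$labels)
  expect_true(all(diff(back$indices) > 0))
})

test_that("non-beat annotation codes are filtered out", {
  # hand-packed MIT words: (code << 10) | delta, little-endian
  words <- c(1L * 1024L + 10L,    # N at 10
             28L * 1024L + 90L,   # '+' rhythm change (non-beat) at 100
             5L * 1024L + 200L,   # V at 300
             19L * 1024L + 100L,  # T-wave mark (non-beat) at 400
             0L)
  f <- withr::local_tempfile(fileext = ".atr")
  writeBin(as.raw(rbind(words %% 256L, words %/% 256L)), f)
  ann <- read_annotations(f)
  expect_identical(ann$indices, c(10L, 300L))
  expect_identical(ann$labels, c("N", "V"))
})

test_that("an annotation stream with no beats yields an empty set + warning", {
  f <- withr::local_tempfile(fileext = ".atr")
  writeBin(as.raw(c(0, 0)), f)
  expect_warning(ann <- read_annotations(f), "no beat annotations")
  expect_length(ann$indices, 0L)
})

test_that("detection files follow the CSV dialect and round-trip exactly", {
  d <- withr::local_tempdir()
  f <- file.path(d, "det.csv")
  write_detections(c(100L, 460L, 820L), f, fs = 360)
  lines <- readLines(f)
  expect_identical(lines[1], "sample_index,time_s")
  expect_length(lines, 4L)
  df <- utils::read.csv(f)
  expect_equal(df$time_s, c(100, 460, 820) / 360)

  write_detections(integer(0), f, fs = 360)
  expect_identical(readLines(f), "sample_index,time_s")

  set.seed(11)
  idx <- sort(sample(0:2e6, 100))
  for (fmt in c("csv", "wfdb")) {
    g <- file.path(d, paste0("rt.", fmt))
    write_detections(idx, g, format = fmt, fs = 360)
    expect_identical(read_detections(g), as.integer(idx))
  }
})

test_that("synthetic records survive a WFDB write/read cycle losslessly", {
  syn <- synth_ecg(synth_config(duration_s = 10, seed = 3))
  base <- file.path(withr::local_tempdir(), "syn")
  write_wfdb_record(syn$record, base)
  write_annotations(syn$annotations, paste0(base, ".atr"))
  rec <- read_ecg(base)
  ann <- read_annotations(paste0(base, ".atr"))
  expect_lt(max(abs(rec$samples - syn$record$samples)), 1 / 200)
  expect_identical(ann$indices, syn$annotations$indices)
})
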