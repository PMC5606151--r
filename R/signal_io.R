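#' ECG record container
#'
#' A uniformly sampled single-channel ECG in physical units (millivolts).
#' Sample positions throughout the package are 0-based, matching the native
#' WFDB convention.
#'
#' @param samples Numeric vector of amplitudes in mV. Must be non-empty and
#'   finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param record_id Record identifier (single string).
#' @return An object of class `ecg_record`: a list with elements `record_id`,
#'   `samples`, `fs`.
#' @export
ecg_record <- function(samples, fs, record_id = "ecg") {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  bad <- which(!is.finite(samples))
  if (length(bad))
    stop(sprintf("non-finite sample at index %d", bad[1L] - 1L), call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  structure(
    list(record_id = as.character(record_id)[1L],
         samples = as.numeric(samples), fs = as.numeric(fs)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d samples @ %g Hz (%.1f s)\n",
              x$record_id, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

#' Reference beat annotations
#'
#' Sorted 0-based sample positions of annotated beats with their annotation
#' symbols.
#'
#' @param indices Integer vector of 0-based sample positions, strictly
#'   increasing.
#' @param labels Character vector of per-beat symbols (recycled if length 1).
#' @return An object of class `beat_annotations` with elements `indices` and
#'   `labels`.
#' @export
beat_annotations <- function(indices = integer(0), labels = character(0)) {
  indices <- as.integer(indices)
  if (length(indices) && any(diff(indices) <= 0L))
    stop("annotation indices must be strictly increasing", call. = FALSE)
  if (length(indices) && any(indices < 0L))
    stop("annotation indices must be >= 0", call. = FALSE)
  if (length(labels) == 1L) labels <- rep(labels, length(indices))
  if (length(labels) != length(indices))
    stop("`labels` must match `indices` in length", call. = FALSE)
  structure(list(indices = indices, labels = as.character(labels)),
            class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %d beats\n", length(x$indices)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## WFDB annotation codes. Codes 1..13 plus the escape/fusion/R-on-T codes mark
## beats; everything else (noise, artifact, rhythm changes, wave boundaries,
## aux notes) is a non-beat mark excluded from beat_annotations.
.wfdb_codes <- local({
  sym <- rep(NA_character_, 63)
  sym[c(1:13, 25, 34, 35, 37, 38, 41)] <-
    c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j", "/", "Q",
      "B", "e", "n", "x", "f", "r")
  sym[c(14, 16, 18, 19, 20, 21, 22, 23, 24, 26, 27, 28, 29, 30, 31, 32, 33,
        39, 40)] <-
    c("~", "|", "s", "T", "*", "D", "=", "\"", "p", "^", "t", "+", "u", "?",
      "!", "[", "]", "(", ")")
  list(symbol = sym,
       beat = c(1:13, 25, 34, 35, 37, 38, 41))
})

.code_for_symbol <- function(symbol) {
  code <- match(symbol, .wfdb_codes$symbol)
  code[is.na(code)] <- 13L  # unknown beat
  code
}

## ---------------------------------------------------------------------------
## WFDB header / signal files

.parse_hea <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty WFDB header: ", path, call. = FALSE)
  rec <- strsplit(lines[1L], "[ \t]+")[[1L]]
  name <- sub("/.*$", "", rec[1L])
  nsig <- as.integer(rec[2L])
  fs <- if (length(rec) >= 3L) as.numeric(sub("/.*$", "", rec[3L])) else 250
  nsamp <- if (length(rec) >= 4L) as.integer(rec[4L]) else NA_integer_
  if (length(lines) < 1L + nsig)
    stop("WFDB header lists ", nsig, " signals but has too few lines",
         call. = FALSE)
  sig <- lapply(lines[1L + seq_len(nsig)], function(ln) {
    f <- strsplit(ln, "[ \t]+")[[1L]]
    fmt <- sub("[x:+].*$", "", f[2L])
    gainfield <- if (length(f) >= 3L) f[3L] else "200"
    baseline <- NA_integer_
    if (grepl("\\(", gainfield))
      baseline <- as.integer(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gainfield))
    gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gainfield)))
    if (is.na(gain) || gain == 0) gain <- 200
    adczero <- if (length(f) >= 5L) as.integer(f[5L]) else 0L
    if (is.na(baseline)) baseline <- adczero
    list(file = f[1L], format = fmt, gain = gain, baseline = baseline)
  })
  list(name = name, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

.read_dat_16 <- function(path, nsig, nsamp) {
  raw <- readBin(path, "integer", n = file.size(path) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
  mat <- matrix(raw[seq_len((length(raw) %/% nsig) * nsig)], nrow = nsig)
  if (!is.na(nsamp)) mat <- mat[, seq_len(min(ncol(mat), nsamp)), drop = FALSE]
  mat
}

.read_dat_212 <- function(path, nsig, nsamp) {
  b <- as.integer(readBin(path, "raw", n = file.size(path)))
  ntrip <- length(b) %/% 3L
  i <- 3L * (seq_len(ntrip) - 1L)
  s1 <- b[i + 1L] + bitwAnd(b[i + 2L], 15L) * 256L
  s2 <- b[i + 3L] + bitwShiftR(b[i + 2L], 4L) * 256L
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  flat <- as.vector(rbind(s1, s2))
  mat <- matrix(flat[seq_len((length(flat) %/% nsig) * nsig)], nrow = nsig)
  if (!is.na(nsamp)) mat <- mat[, seq_len(min(ncol(mat), nsamp)), drop = FALSE]
  mat
}

#' Read an ECG record from a WFDB header or a CSV file
#'
#' WFDB records are read through their `.hea` header (signal formats 16 and
#' 212 are supported) and converted to physical units via
#' `(adu - baseline) / gain`. CSV input holds either a single `amplitude`
#' column or `sample_index,amplitude` columns already in mV, and requires
#' `fs` to be given.
#'
#' @param path Path to a `.hea` header (or record name without extension) or
#'   to a `.csv` file.
#' @param channel 0-based signal channel to extract (default 0, the first
#'   channel).
#' @param fs Sampling rate in Hz; required for CSV input, ignored for WFDB.
#' @param record_id Optional record identifier; defaults to the file base
#'   name.
#' @return An [ecg_record].
#' @export
read_ecg <- function(path, channel = 0L, fs = NULL, record_id = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    if (is.null(fs)) stop("`fs` is required for CSV input", call. = FALSE)
    df <- utils::read.csv(path)
    amp <- if (ncol(df) >= 2L) df[[2L]] else df[[1L]]
    bad <- which(!is.finite(amp))
    if (length(bad))
      stop(sprintf("non-finite sample at index %d", bad[1L] - 1L),
           call. = FALSE)
    id <- if (is.null(record_id)) sub("\\.csv$", "", basename(path),
                                      ignore.case = TRUE) else record_id
    return(ecg_record(amp, fs, id))
  }
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("no such file: ", hea, call. = FALSE)
  h <- .parse_hea(hea)
  channel <- as.integer(channel)
  if (channel < 0L || channel >= h$nsig)
    stop(sprintf("channel %d out of range (record has %d signals)",
                 channel, h$nsig), call. = FALSE)
  datfile <- file.path(dirname(hea), h$signals[[channel + 1L]]$file)
  if (!file.exists(datfile)) stop("no such file: ", datfile, call. = FALSE)
  fmt <- h$signals[[1L]]$format
  mat <- switch(fmt,
    "16" = .read_dat_16(datfile, h$nsig, h$nsamp),
    "212" = .read_dat_212(datfile, h$nsig, h$nsamp),
    stop("unsupported WFDB signal format: ", fmt, call. = FALSE))
  adu <- mat[channel + 1L, ]
  sig <- h$signals[[channel + 1L]]
  mv <- (adu - sig$baseline) / sig$gain
  bad <- which(!is.finite(mv))
  if (length(bad))
    stop(sprintf("non-finite sample at index %d", bad[1L] - 1L),
         call. = FALSE)
  id <- if (is.null(record_id)) h$name else record_id
  ecg_record(mv, h$fs, id)
}

#' Write an ECG record as a WFDB header/signal pair
#'
#' Amplitudes are digitized as `round(mV * gain)` with baseline 0 and written
#' in format 16 (16-bit little-endian) or format 212 (packed 12-bit).
#'
#' @param rec An [ecg_record].
#' @param path Output path; the `.hea`/`.dat` extensions are appended to its
#'   base.
#' @param format WFDB signal format, `"16"` (default) or `"212"`.
#' @param gain ADC units per mV (default 200).
#' @return The header path, invisibly.
#' @export
write_wfdb_record <- function(rec, path, format = c("16", "212"), gain = 200) {
  stopifnot(inherits(rec, "ecg_record"))
  format <- match.arg(format)
  base <- sub("\\.hea$", "", path)
  adu <- as.integer(round(rec$samples * gain))
  lim <- if (format == "212") 2047L else 32767L
  adu <- pmax(pmin(adu, lim), -lim - 1L)
  datname <- paste0(basename(base), ".dat")
  checksum <- sum(adu) %% 65536L
  if (checksum > 32767L) checksum <- checksum - 65536L
  hea <- c(
    sprintf("%s 1 %g %d", basename(base), rec$fs, length(adu)),
    sprintf("%s %s %g(0)/mV 16 0 %d %d 0 ECG", datname, format, gain,
            adu[1L], checksum)
  )
  writeLines(hea, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  if (format == "16") {
    writeBin(adu, con, size = 2L, endian = "little")
  } else {
    if (length(adu) %% 2L == 1L) adu <- c(adu, 0L)
    u <- ifelse(adu < 0L, adu + 4096L, adu)
    s1 <- u[seq(1L, length(u), 2L)]
    s2 <- u[seq(2L, length(u), 2L)]
    b1 <- s1 %% 256L
    b2 <- (s1 %/% 256L) + 16L * (s2 %/% 256L)
    b3 <- s2 %% 256L
    writeBin(as.raw(as.vector(rbind(b1, b2, b3))), con)
  }
  invisible(paste0(base, ".hea"))
}

## ---------------------------------------------------------------------------
## MIT annotation format: a stream of 16-bit little-endian words
## (code << 10) | interval, where interval is the sample offset from the
## previous annotation. Pseudo-codes: SKIP (59, followed by a 32-bit interval,
## high word first), NUM (60), SUB (61), CHN (62), AUX (63, followed by the
## even-padded aux bytes). A zero word terminates the stream.

#' Read beat annotations
#'
#' Reads a WFDB (MIT-format) annotation file or a CSV with columns
#' `sample_index,symbol`, keeping only beat-type annotations (non-beat marks
#' such as rhythm changes, noise and wave-boundary labels are dropped).
#'
#' @param path Path to the annotation file.
#' @return A [beat_annotations]. If the file contains no beat annotations an
#'   empty set is returned with a warning.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, colClasses = c("integer", "character"))
    idx <- df[[1L]]
    lab <- df[[2L]]
  } else {
    b <- as.integer(readBin(path, "raw", n = file.size(path)))
    idx <- integer(0); code <- integer(0)
    t <- 0; i <- 1L
    while (i + 1L <= length(b)) {
      word <- b[i] + 256L * b[i + 1L]
      i <- i + 2L
      a <- word %/% 1024L
      interval <- word %% 1024L
      if (word == 0L) break
      if (a == 59L) {           # SKIP: 32-bit interval, high word first
        hi <- b[i] + 256L * b[i + 1L]
        lo <- b[i + 2L] + 256L * b[i + 3L]
        i <- i + 4L
        skip <- hi * 65536 + lo
        if (skip >= 2^31) skip <- skip - 2^32
        t <- t + skip
      } else if (a == 63L) {    # AUX: skip the even-padded byte payload
        i <- i + interval + (interval %% 2L)
      } else if (a %in% c(60L, 61L, 62L)) {
        # NUM/SUB/CHN field updates: no time advance
      } else {
        t <- t + interval
        idx <- c(idx, t)
        code <- c(code, a)
      }
    }
    keep <- code %in% .wfdb_codes$beat
    idx <- idx[keep]
    lab <- .wfdb_codes$symbol[code[keep]]
  }
  o <- order(idx)
  idx <- idx[o]; lab <- lab[o]
  if (!length(idx)) warning("no beat annotations found in ", path)
  beat_annotations(idx, lab)
}

#' Write beat annotations as a WFDB (MIT-format) annotation file
#'
#' @param ann A [beat_annotations].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "beat_annotations"))
  codes <- .code_for_symbol(ann$labels)
  words <- integer(0)
  prev <- 0
  for (k in seq_along(ann$indices)) {
    delta <- ann$indices[k] - prev
    prev <- ann$indices[k]
    if (delta > 1023) {
      # SKIP word, then the 32-bit interval (high half-word first), then the
      # annotation word with a zero interval field
      words <- c(words, 59L * 1024L,
                 delta %/% 65536, delta %% 65536,
                 codes[k] * 1024L)
    } else {
      words <- c(words, codes[k] * 1024L + delta)
    }
  }
  words <- c(words, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(as.vector(rbind(words %% 256L, words %/% 256L))), con)
  invisible(path)
}

#' Write detected R-peaks
#'
#' CSV output has a header line `sample_index,time_s` and one row per peak;
#' WFDB output is a MIT-format annotation file in which every peak carries the
#' normal-beat symbol `"N"`.
#'
#' @param peaks An `rpeak_set` (from [detect_rpeaks()]) or an integer vector
#'   of 0-based peak indices.
#' @param path Output file path.
#' @param format `"csv"` (default) or `"wfdb"`.
#' @param fs Sampling rate in Hz; taken from `peaks` when it is an
#'   `rpeak_set`.
#' @return `path`, invisibly.
#' @export
write_detections <- function(peaks, path, format = c("csv", "wfdb"),
                             fs = NULL) {
  format <- match.arg(format)
  if (inherits(peaks, "rpeak_set")) {
    if (is.null(fs)) fs <- peaks$fs
    idx <- peaks$indices
  } else idx <- as.integer(peaks)
  if (format == "csv") {
    if (is.null(fs)) stop("`fs` is required for CSV output", call. = FALSE)
    df <- data.frame(sample_index = idx, time_s = idx / fs)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    write_annotations(beat_annotations(idx, rep("N", length(idx))), path)
  }
  invisible(path)
}

#' Read detected R-peaks written by [write_detections()]
#'
#' @param path Path to a detection CSV or WFDB annotation file.
#' @return Integer vector of 0-based peak indices.
#' @export
read_detections <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    as.integer(df$sample_index)
  } else {
    read_annotations(path)$indices
  }
}
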