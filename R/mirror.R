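#' Locate local maxima by the sign of the first forward difference
#'
#' Computes `d[n] = x[n+1] - x[n]`, maps it through `sgn` to \{-1, 0, 1\},
#' differences the sign sequence again and reports a maximum one sample to
#' the right of every `-2` entry. Zero signs (plateaus) are replaced by the
#' nearest following nonzero sign, so a rise-plateau-fall contributes exactly
#' one maximum at the first plateau sample; endpoints are never returned.
#'
#' @param signal Numeric vector, length >= 3.
#' @return A data frame of class `candidate_set` with columns `index`
#'   (0-based, strictly increasing) and `amplitude` (signal value there).
#' @export
local_maxima <- function(signal) {
  x <- as.numeric(signal)
  if (length(x) < 3L)
    stop("`signal` must have at least 3 samples", call. = FALSE)
  s <- sign(diff(x))
  # fill zeros from the right (next nonzero sign); trailing zeros fall back
  # to the preceding nonzero sign
  z <- s == 0
  if (any(z)) {
    nz <- which(!z)
    if (!length(nz)) {
      out <- data.frame(index = integer(0), amplitude = numeric(0))
      class(out) <- c("candidate_set", class(out))
      return(out)
    }
    pos <- findInterval(which(z), nz) + 1L       # next nonzero, as rank in nz
    fill <- ifelse(pos > length(nz), nz[length(nz)], nz[pmin(pos, length(nz))])
    s[z] <- s[fill]
  }
  dd <- diff(s)
  idx <- which(dd == -2L)  # 1-based position in dd == 0-based maximum index
  out <- data.frame(index = as.integer(idx), amplitude = x[idx + 1L])
  class(out) <- c("candidate_set", class(out))
  out
}

#' Mirroring configuration
#'
#' @param amplitude_multiple How many times larger (in absolute amplitude) a
#'   negative trough must be than every sample in its comparison window to be
#'   mirrored (default 1.5; must exceed 1).
#' @param window_s Half-width of the comparison window in seconds
#'   (default 0.278).
#' @param scope What gets reflected (and excluded from the comparison):
#'   `"run"` (default) negates the whole contiguous negative run containing
#'   the trough, so the reflected wave keeps its shape; `"point"` negates the
#'   trough sample alone.
#' @param enabled Set `FALSE` to turn the stage off (used for ablations).
#' @return A list of class `mirror_config`.
#' @export
mirror_config <- function(amplitude_multiple = 1.5, window_s = 0.278,
                          scope = c("run", "point"), enabled = TRUE) {
  stopifnot(amplitude_multiple > 1, window_s > 0)
  structure(list(amplitude_multiple = amplitude_multiple,
                 window_s = window_s, scope = match.arg(scope),
                 enabled = isTRUE(enabled)),
            class = "mirror_config")
}

#' Mirror large negative deflections about the baseline
#'
#' Candidate troughs are the negative local minima of the signal (the local
#' maxima of its negation). A trough at 0-based position `k` is reflected
#' when its absolute amplitude is at least `amplitude_multiple` times the
#' absolute amplitude of every sample in the window
#' `[k - round(window_s*fs), k + round(window_s*fs)]`, excluding the samples
#' that would themselves be reflected with it (the contiguous negative run
#' containing `k` for `scope = "run"`, only `k` itself for
#' `scope = "point"`). Large positive neighbours therefore veto mirroring.
#' The baseline is taken as 0, as produced by [wmra_enhance()].
#'
#' @param signal Numeric vector (baseline at 0), non-empty.
#' @param fs Sampling rate in Hz.
#' @param cfg A [mirror_config].
#' @return A list of class `mirrored_signal`: `samples` (the mirrored
#'   signal), `mirrored_runs` (data frame of 0-based `start`,`end` of each
#'   reflected run, inclusive), `fs`, `cfg`.
#' @export
mirror_signal <- function(signal, fs, cfg = mirror_config()) {
  x <- as.numeric(signal)
  if (!length(x)) stop("`signal` is empty", call. = FALSE)
  stopifnot(inherits(cfg, "mirror_config"), fs > 0)
  runs <- data.frame(start = integer(0), end = integer(0))
  if (!cfg$enabled || length(x) < 3L) {
    return(structure(list(samples = x, mirrored_runs = runs, fs = fs,
                          cfg = cfg), class = "mirrored_signal"))
  }
  w <- as.integer(round(cfg$window_s * fs))
  L <- length(x)
  minima <- local_maxima(-x)
  minima <- minima[x[minima$index + 1L] < 0, , drop = FALSE]
  flip <- logical(L)
  if (nrow(minima)) {
    neg <- x < 0
    run_id <- cumsum(c(neg[1L], diff(neg)) != 0)  # contiguous sign runs
    for (k in minima$index) {
      lo <- max(0L, k - w); hi <- min(L - 1L, k + w)
      win <- (lo:hi) + 1L
      excl <- if (cfg$scope == "run") win[run_id[win] == run_id[k + 1L] & neg[win]]
              else k + 1L
      cmp <- setdiff(win, excl)
      ok <- !length(cmp) ||
        abs(x[k + 1L]) >= cfg$amplitude_multiple * max(abs(x[cmp]))
      if (ok) {
        if (cfg$scope == "run") flip[win[run_id[win] == run_id[k + 1L] & neg[win]]] <- TRUE
        else flip[k + 1L] <- TRUE
      }
    }
  }
  y <- x
  y[flip] <- -y[flip]
  if (any(flip)) {
    r <- rle(flip)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values] - 1L,
                       end = ends[r$values] - 1L)
  }
  structure(list(samples = y, mirrored_runs = runs, fs = fs, cfg = cfg),
            class = "mirrored_signal")
}

#' @export
print.mirrored_signal <- function(x, ...) {
  cat(sprintf("<mirrored_signal> %d samples, %d mirrored run(s)\n",
              length(x$samples), nrow(x$mirrored_runs)))
  invisible(x)
}
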