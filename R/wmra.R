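## Biorthogonal 6.8 filter bank (analysis lo/hi, synthesis lo/hi). These are
## the standard published bior6.8 coefficients; the decimated transform below
## is periodized, so decompose -> reconstruct is exact at any signal length.
.bior68 <- list(
  dec_lo = c(0, 0.0019088317364812906, -0.0019142861290887667,
             -0.016990639867602342, 0.01193456527972926, 0.04973290349094079,
             -0.07726317316720414, -0.09405920349573646, 0.4207962846098268,
             0.8259229974584023, 0.4207962846098268, -0.09405920349573646,
             -0.07726317316720414, 0.04973290349094079, 0.01193456527972926,
             -0.016990639867602342, -0.0019142861290887667,
             0.0019088317364812906),
  dec_hi = c(0, 0, 0, 0.014426282505624435, -0.014467504896790148,
             -0.07872200106262882, 0.04036797903033992, 0.41784910915027457,
             -0.7589077294536541, 0.41784910915027457, 0.04036797903033992,
             -0.07872200106262882, -0.014467504896790148,
             0.014426282505624435, 0, 0, 0, 0),
  rec_lo = c(0, 0, 0, 0.014426282505624435, 0.014467504896790148,
             -0.07872200106262882, -0.04036797903033992, 0.41784910915027457,
             0.7589077294536541, 0.41784910915027457, -0.04036797903033992,
             -0.07872200106262882, 0.014467504896790148,
             0.014426282505624435, 0, 0, 0, 0),
  rec_hi = c(0, -0.0019088317364812906, -0.0019142861290887667,
             0.016990639867602342, 0.01193456527972926, -0.04973290349094079,
             -0.07726317316720414, 0.09405920349573646, 0.4207962846098268,
             -0.8259229974584023, 0.4207962846098268, 0.09405920349573646,
             -0.07726317316720414, -0.04973290349094079, 0.01193456527972926,
             0.016990639867602342, -0.0019142861290887667,
             -0.0019088317364812906)
)

.wavelet_filters <- function(wavelet) {
  if (!identical(wavelet, "bior6.8"))
    stop("unsupported wavelet: ", wavelet, " (only \"bior6.8\" is built in)",
         call. = FALSE)
  .bior68
}

.circ <- function(i, n) ((i %% n) + n) %% n + 1L

## one analysis step on an even-length signal: circular convolution with the
## analysis pair, keeping odd outputs
.dwt_step <- function(x, lo, hi) {
  n <- length(x)
  half <- n %/% 2L
  a <- numeric(half); d <- numeric(half)
  k <- 0:(half - 1L)
  for (m in seq_along(lo)) {
    xi <- x[.circ(2L * k + 2L - m, n)]
    a <- a + lo[m] * xi
    d <- d + hi[m] * xi
  }
  list(a = a, d = d)
}

## one synthesis step; the periodized two-channel bank reconstructs the input
## up to a fixed circular delay of length(filter) - 2 samples, undone here
.idwt_step <- function(a, d, lo, hi) {
  n <- 2L * length(a)
  ua <- numeric(n); ud <- numeric(n)
  ua[seq(1L, n, 2L)] <- a
  ud[seq(1L, n, 2L)] <- d
  y <- numeric(n)
  nn <- 0:(n - 1L)
  for (m in seq_along(lo)) {
    ii <- .circ(nn - (m - 1L), n)
    y <- y + lo[m] * ua[ii] + hi[m] * ud[ii]
  }
  y[.circ(nn + (length(lo) - 2L), n)]
}

#' Dyadic frequency bands of a multilevel wavelet decomposition
#'
#' Level `j` detail coefficients `cDj` cover `(fs/2^(j+1), fs/2^j]` Hz and the
#' deepest approximation `cA<levels>` covers `[0, fs/2^(levels+1)]` Hz. At
#' 360 Hz with 8 levels this puts cD1 at 90--180 Hz and cA8 at 0--0.70 Hz;
#' at 250 Hz, cA8 spans 0--0.49 Hz.
#'
#' @param fs Sampling rate in Hz (> 0).
#' @param levels Decomposition depth (default 8).
#' @return A data frame with columns `set` (`"cD1"`..`"cD<levels>"`,
#'   `"cA<levels>"`), `lo_hz`, `hi_hz` (exact edges; round to 2 decimals for
#'   display).
#' @export
band_edges <- function(fs, levels = 8L) {
  stopifnot(fs > 0, levels >= 1)
  j <- seq_len(levels)
  data.frame(
    set = c(paste0("cD", j), paste0("cA", levels)),
    lo_hz = c(fs / 2^(j + 1), 0),
    hi_hz = c(fs / 2^j, fs / 2^(levels + 1))
  )
}

#' Multilevel wavelet decomposition of an ECG record
#'
#' Decimated eight-level (by default) multiresolution decomposition with the
#' bior6.8 filter bank and periodized boundaries. Odd-length levels are
#' extended by repeating the final sample, and the pre-extension lengths are
#' recorded so that reconstruction trims exactly back to the input length.
#'
#' @param rec An [ecg_record], or a numeric vector together with `fs`.
#' @param wavelet Wavelet name; only `"bior6.8"` is built in.
#' @param levels Decomposition depth (default 8).
#' @param fs Sampling rate when `rec` is a bare numeric vector.
#' @return An object of class `wavelet_bands`: a list with `approx` (the
#'   deepest approximation), `details` (list `cD1`..`cD<levels>`), `lens`
#'   (per-level input lengths), `fs`, `L`, `wavelet`, `levels`, and the
#'   [band_edges()] table.
#' @export
wmra_decompose <- function(rec, wavelet = "bior6.8", levels = 8L, fs = NULL) {
  if (inherits(rec, "ecg_record")) {
    x <- rec$samples; fs <- rec$fs; id <- rec$record_id
  } else {
    x <- as.numeric(rec)
    if (is.null(fs)) stop("`fs` is required for a bare signal", call. = FALSE)
    id <- "signal"
  }
  levels <- as.integer(levels)
  minlen <- 2^levels
  if (length(x) < minlen)
    stop(sprintf("signal too short for %d-level decomposition (need >= %d samples, got %d)",
                 levels, minlen, length(x)), call. = FALSE)
  flt <- .wavelet_filters(wavelet)
  details <- vector("list", levels)
  lens <- integer(levels)
  cur <- x
  for (j in seq_len(levels)) {
    lens[j] <- length(cur)
    if (length(cur) %% 2L == 1L) cur <- c(cur, cur[length(cur)])
    s <- .dwt_step(cur, flt$dec_lo, flt$dec_hi)
    details[[j]] <- s$d
    cur <- s$a
  }
  names(details) <- paste0("cD", seq_len(levels))
  structure(
    list(wavelet = wavelet, levels = levels, fs = fs, L = length(x),
         record_id = id, approx = cur, details = details, lens = lens,
         band_edges = band_edges(fs, levels), zeroed = character(0),
         lambda = NULL),
    class = "wavelet_bands"
  )
}

#' @export
print.wavelet_bands <- function(x, ...) {
  cat(sprintf("<wavelet_bands> %s, %d levels, fs = %g Hz, L = %d\n",
              x$wavelet, x$levels, x$fs, x$L))
  if (length(x$zeroed)) cat("  zeroed:", paste(x$zeroed, collapse = ", "), "\n")
  invisible(x)
}

#' Zero out-of-band coefficient sets
#'
#' The deepest approximation (sub-`fs/2^(levels+1)` Hz, carrying baseline
#' drift) is always zeroed. The first detail level is zeroed when its band
#' lies entirely at or above 90 Hz, i.e. when `fs/4 >= 90`: at 360 Hz this
#' drops cD1 (90--180 Hz) while at 250 Hz cD1 (62.5--125 Hz) still overlaps
#' the QRS band and is kept.
#'
#' @param bands A `wavelet_bands` object.
#' @param keep Optional character vector naming the coefficient sets to keep
#'   (e.g. `c("cD2", ..., "cD8")`); overrides the frequency rule. Sets not
#'   named are zeroed; `keep = "all"` leaves the decomposition untouched.
#' @return The modified `wavelet_bands`, with the zeroed set names recorded
#'   in `$zeroed`.
#' @export
wmra_select_bands <- function(bands, keep = NULL) {
  stopifnot(inherits(bands, "wavelet_bands"))
  sets <- c(names(bands$details), paste0("cA", bands$levels))
  if (is.null(keep)) {
    zero <- paste0("cA", bands$levels)
    if (bands$fs / 4 >= 90) zero <- c("cD1", zero)
  } else if (identical(keep, "all")) {
    zero <- character(0)
  } else {
    unknown <- setdiff(keep, sets)
    if (length(unknown))
      stop("unknown coefficient set(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    zero <- setdiff(sets, keep)
  }
  for (z in zero) {
    if (z == paste0("cA", bands$levels)) bands$approx[] <- 0
    else bands$details[[z]][] <- 0
  }
  bands$zeroed <- union(bands$zeroed, zero)
  bands
}

#' Soft-threshold retained detail coefficients
#'
#' Applies wavelet shrinkage `eta(c) = sign(c) * max(|c| - lambda, 0)` to each
#' retained (non-zeroed) detail level. With `method = "universal"` the
#' per-level threshold is `lambda_j = sigma * sqrt(2 * log(N_j))`, `N_j` the
#' level length, with the noise scale `sigma = median(|cD1|) / 0.6745`
#' estimated once from the finest detail level. The finest level is the only
#' one that is noise-dominated on an ECG: deeper levels carry the cardiac
#' waves themselves, so estimating a per-level "noise" scale there would
#' shrink away signal, not noise.
#'
#' @param bands A `wavelet_bands` object.
#' @param method `"universal"` (default) or `"none"`.
#' @return The shrunk `wavelet_bands`; the per-level thresholds used are
#'   stored in `$lambda` and the noise scale in `$sigma`.
#' @export
wmra_soft_threshold <- function(bands, method = c("universal", "none")) {
  stopifnot(inherits(bands, "wavelet_bands"))
  method <- match.arg(method)
  if (method == "none") return(bands)
  sigma <- stats::median(abs(bands$details[[1L]])) / 0.6745
  lambda <- stats::setNames(numeric(bands$levels), names(bands$details))
  for (j in seq_len(bands$levels)) {
    nm <- names(bands$details)[j]
    if (nm %in% bands$zeroed) next
    d <- bands$details[[j]]
    lam <- sigma * sqrt(2 * log(length(d)))
    bands$details[[j]] <- sign(d) * pmax(abs(d) - lam, 0)
    lambda[nm] <- lam
  }
  bands$lambda <- lambda
  bands$sigma <- sigma
  bands
}

#' Reconstruct a signal from (possibly modified) wavelet bands
#'
#' @param bands A `wavelet_bands` object.
#' @return An [ecg_record] of the original length and sampling rate.
#' @export
wmra_reconstruct <- function(bands) {
  stopifnot(inherits(bands, "wavelet_bands"))
  flt <- .wavelet_filters(bands$wavelet)
  cur <- bands$approx
  for (j in rev(seq_len(bands$levels))) {
    y <- .idwt_step(cur, bands$details[[j]], flt$rec_lo, flt$rec_hi)
    cur <- y[seq_len(bands$lens[j])]
  }
  ecg_record(cur, bands$fs, bands$record_id)
}

#' Wavelet multiresolution enhancement of an ECG record
#'
#' The full enhancement stage: decompose, zero the out-of-band coefficient
#' sets, soft-threshold the retained detail levels, reconstruct. The output
#' has (near-)zero baseline, which the downstream mirroring stage relies on.
#'
#' @inheritParams wmra_decompose
#' @param shrinkage Shrinkage rule, `"universal"` (default) or `"none"`.
#' @param keep Optional keep-set override passed to [wmra_select_bands()].
#' @return An [ecg_record] containing the enhanced signal.
#' @export
wmra_enhance <- function(rec, wavelet = "bior6.8", levels = 8L,
                         shrinkage = c("universal", "none"), keep = NULL,
                         fs = NULL) {
  bands <- wmra_decompose(rec, wavelet = wavelet, levels = levels, fs = fs)
  bands <- wmra_select_bands(bands, keep = keep)
  bands <- wmra_soft_threshold(bands, method = shrinkage)
  wmra_reconstruct(bands)
}
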