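## Independent reference implementations used as oracles. These deliberately
## share no code with the package: plain per-sample loops and literal
## transcriptions, kept as slow and obvious as possible.

## local maxima by exhaustive scan: an interior sample that rises from its
## left neighbour and whose (possibly plateau-extended) right side falls.
## Returns 0-based indices of the first plateau sample.
brute_local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j < n && x[j + 1] < x[i]) out <- c(out, i - 1L)
    }
  }
  out
}

## literal transcription of the five-step time-interval arbitration, working
## on a mutable candidate list exactly as the procedure is worded:
##   A: take the first two remaining candidates as Tref / Cref
##   B: spacing >= ti_t accepts Tref, Cref becomes the reference
##   C: narrower width wins;  D: larger amplitude wins, tie -> Cref
##   E: the false maximum is replaced by the next candidate as new Cref
recognize_reference <- function(idx, amp, wid, ti_t) {
  peaks <- integer(0)
  repeat {
    ## Step A
    if (!length(idx)) return(peaks)
    if (length(idx) == 1L) return(c(peaks, idx[1L]))
    t <- 1L; cr <- 2L
    repeat {
      ## Step B
      if (idx[cr] - idx[t] >= ti_t) {
        peaks <- c(peaks, idx[t])
        idx <- idx[-t]; amp <- amp[-t]; wid <- wid[-t]
        break  # to Step A; old Cref is now the leading reference
      }
      ## Steps C and D
      tref_true <- if (wid[t] < wid[cr]) TRUE
                   else if (wid[t] > wid[cr]) FALSE
                   else amp[t] > amp[cr]
      ## Step E
      if (tref_true) {
        idx <- idx[-cr]; amp <- amp[-cr]; wid <- wid[-cr]
        if (cr > length(idx)) {          # no Rref: Step A accepts lone Tref
          peaks <- c(peaks, idx[t])
          idx <- idx[-t]; amp <- amp[-t]; wid <- wid[-t]
          break
        }
      } else {
        idx <- idx[-t]; amp <- amp[-t]; wid <- wid[-t]
        t <- 1L; cr <- 2L
        if (length(idx) < 2L) {
          peaks <- c(peaks, idx[1L])
          return(peaks)
        }
      }
    }
  }
}

## maximum bipartite matching between reference beats and detections within
## the tolerance, via igraph; returns the optimal TP count
match_oracle_tp <- function(peaks, truth, tol) {
  nt <- length(truth); np <- length(peaks)
  if (!nt || !np) return(0L)
  edges <- integer(0)
  for (i in seq_len(nt))
    for (j in seq_len(np))
      if (abs(peaks[j] - truth[i]) <= tol)
        edges <- c(edges, i, nt + j)
  if (!length(edges)) return(0L)
  g <- igraph::make_graph(edges, n = nt + np, directed = FALSE)
  igraph::V(g)$type <- c(rep(FALSE, nt), rep(TRUE, np))
  as.integer(igraph::max_bipartite_match(g)$matching_size)
}

## exhaustive per-sample evaluation of the mirroring predicate: for every
## negative local minimum k, |x[k]| must be >= mult * |x[i]| for every
## window sample i outside the contiguous negative run containing k
mirror_oracle <- function(x, fs, mult = 1.5, window_s = 0.278) {
  w <- round(window_s * fs)
  L <- length(x)
  flip <- logical(L)
  for (k0 in brute_local_maxima(-x)) {
    k1 <- k0 + 1L
    if (x[k1] >= 0) next
    # contiguous negative run containing k1
    a <- k1; while (a > 1 && x[a - 1] < 0) a <- a - 1
    b <- k1; while (b < L && x[b + 1] < 0) b <- b + 1
    lo <- max(1, k1 - w); hi <- min(L, k1 + w)
    ok <- TRUE
    for (i in lo:hi) {
      if (i >= a && i <= b) next
      if (abs(x[k1]) < mult * abs(x[i])) { ok <- FALSE; break }
    }
    if (ok) flip[a:b] <- TRUE
  }
  y <- x
  y[flip] <- -y[flip]
  y
}

## seeded random candidate sets for the recognition oracle: clustered
## indices so that both branches of Step B fire often
random_candidates <- function(n, fs = 360) {
  gaps <- sample(c(sample(20:120, n, replace = TRUE),
                   sample(150:500, n, replace = TRUE)), n)
  idx <- cumsum(gaps)
  data.frame(index = idx,
             amplitude = round(stats::runif(n, 0.2, 2), 3),
             width = sample(c(1:60, rep(c(10L, 40L), 10)), n,
                            replace = TRUE))
}

## run the installed command-line script in a subprocess
run_cli <- function(args) {
  script <- system.file("cli", "rpeak.R", package = "rpeakr")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(shQuote(script), args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
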