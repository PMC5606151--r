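#!/usr/bin/env Rscript
# Optional, non-asserted profiling helper: times the detector on synthetic
# signals of growing duration to eyeball the (near-linear) scaling of the
# pipeline. Wall-clock numbers are hardware-bound and are not part of any
# test or acceptance check.

suppressMessages(library(rpeakr))

durations <- c(30, 60, 120, 240, 480)
cat(sprintf("%10s %12s %12s %10s\n",
            "seconds", "samples", "peaks", "elapsed_s"))
for (d in durations) {
  syn <- synth_ecg(synth_config(duration_s = d, noise_sd = 0.05,
                                drift = c(0.3, 0.2), seed = 1L))
  t0 <- proc.time()["elapsed"]
  peaks <- detect_rpeaks(syn$record)
  dt <- proc.time()["elapsed"] - t0
  cat(sprintf("%10d %12d %12d %10.3f\n",
              d, length(syn$record), length(peaks$indices), dt))
}
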