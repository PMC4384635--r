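# shared helpers for the test suite

# mixed relative error between two progress curves: 0.1%-style relative
# agreement with an absolute floor at `floor_frac` of total monomer, so
# vanishing species do not blow up the ratio
progress_mixed_err <- function(a, b, total0_uM, floor_frac = 1e-4) {
  cols <- c("M_uM", "P_uM", "MM_uM", "PM_uM")
  max(vapply(cols, function(s) {
    max(abs(a[[s]] - b[[s]]) / pmax(abs(b[[s]]), floor_frac * total0_uM))
  }, numeric(1)))
}

# exact four-parameter logistic response on a dose vector (dose 0 -> floor)
logistic_response <- function(dose, ec50, hill = 1, floor = 0, ceiling = 1) {
  r <- rep(floor, length(dose))
  pos <- dose > 0
  r[pos] <- floor + (ceiling - floor) / (1 + 10^(hill * (log10(ec50) - log10(dose[pos]))))
  r
}

# first upward crossing of `level` in an observed (possibly noisy) signal,
# linearly interpolated; NA when never reached
first_crossing <- function(time_s, signal, level = 0.5) {
  idx <- which(signal >= level)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (i == 1L) return(time_s[1])
  time_s[i - 1] + (level - signal[i - 1]) / (signal[i] - signal[i - 1]) *
    (time_s[i] - time_s[i - 1])
}
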