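# shared fixture builders (all synthetic, generated at test time)

# constant-interval series
const_series <- function(n = 100, rr = 800) rr_series(rep(rr, n))

# sinusoidally modulated tachogram via IPFM: base RR (ms) + A sin(2 pi f t)
sine_tachogram <- function(freq, amp, base = 800, duration = 300, dt = 0.05) {
  ipfm_tachogram(function(t) base + amp * sin(2 * pi * freq * t), duration, dt)
}

# group parameters with zero spread: every subject sits at the group median
degenerate_params <- function(base = default_group_params()) {
  for (nm in names(base)) {
    if (nm %in% c("male_frac", "smoker_frac", "walker_frac", "power_meter_frac")) next
    for (g in c("neg", "pos")) {
      m <- base[[nm]][[g]][1]
      base[[nm]][[g]] <- c(m, m, m)
    }
  }
  base$male_frac <- list(neg = 1, pos = 1)
  base$smoker_frac <- list(neg = 0, pos = 0)
  base$walker_frac <- list(neg = 0, pos = 0)
  base$power_meter_frac <- list(neg = 1, pos = 1)
  base
}

# parameters identical across groups (difference-free cohort)
null_params <- function(base = default_group_params()) {
  for (nm in names(base)) base[[nm]]$pos <- base[[nm]]$neg
  base
}

# R reference for the centre-excluded windowed median (oracle for the C++ path)
ref_windowed_median <- function(rr, h) {
  n <- length(rr)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    median(rr[setdiff(lo:hi, i)])
  }, numeric(1))
}
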