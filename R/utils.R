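# Internal helpers: local RNG scoping, rounding, band power, fingerprints.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# randomness.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a per-record / per-fold subseed from a base seed and a counter,
# kept inside 32-bit integer range.
deriveSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 1103515245 + 7919 * as.numeric(counter)) %%
               2147483647)
}

#' Round half up to one decimal
#'
#' Rounds percentages to one decimal with ties going away from zero
#' (99.85 -> 99.9), the convention used in formatted metric tables. Base
#' `round()` rounds half to even, which would print 99.8.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return Rounded numeric vector (`NA` preserved).
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

formatMetric <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.1f", roundHalfUp(x, 1)))
}

# Tiny FNV-1a hash over a config string; used as a config fingerprint in
# reports (no cryptographic intent).
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keeps h a double < 2^32
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # multiply mod 2^32 in halves to stay within exact double integers
    hLo <- h %% 65536
    hHi <- (h - hLo) / 65536
    h <- (hLo * 16777619 + ((hHi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

# One-sided periodogram of a single channel: frequencies and raw power.
periodogram <- function(x, fs) {
  n <- length(x)
  sp <- abs(fft(x))^2 / n
  nf <- floor(n / 2)
  list(freq = (seq_len(nf)) * fs / n, power = sp[2:(nf + 1)])
}

# Frequency of maximal periodogram power, ignoring DC.
dominantFrequency <- function(x, fs) {
  pg <- periodogram(x, fs)
  pg$freq[which.max(pg$power)]
}

# Fraction of total (non-DC) spectral power inside [lo, hi] Hz.
bandPowerFraction <- function(x, fs, lo, hi) {
  pg <- periodogram(x, fs)
  sel <- pg$freq >= lo & pg$freq <= hi
  sum(pg$power[sel]) / sum(pg$power)
}

# The five canonical EEG band edges in Hz.
eegBands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 100))
}

rmsValue <- function(x) sqrt(mean(x^2))
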