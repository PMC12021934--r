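# Independent brute-force oracles used to freeze expected values.

# Enumerate every forward 30-min window [s, s+29] (0-based starts); first
# window holding >= 15 sleep minutes gives onset = first sleep minute in it.
oracle_onset <- function(flags) {
  for (s in 0:(840 - 30)) {
    win <- flags[(s + 1):(s + 30)]
    if (sum(win) >= 15) {
      return(s + which(win)[1] - 1L)
    }
  }
  NA_integer_
}

# Backward mirror: windows [e-29, e] for e = 839 down to 29; first qualifying
# window gives offset = last sleep minute in it.
oracle_offset <- function(flags) {
  for (e in 839:29) {
    win <- flags[(e - 29 + 1):(e + 1)]
    if (sum(win) >= 15) {
      return(e - 30L + rev(which(win))[1])
    }
  }
  NA_integer_
}

# Weighted cross-product log-odds of a saturated 2x2 table.
oracle_weighted_log_or <- function(w11, w10, w01, w00) {
  log((w11 * w00) / (w10 * w01))
}

# random night pattern generator for the detector-oracle property
random_night <- function() {
  flags <- logical(840)
  kind <- sample(c("bout", "fragmented", "scattered", "empty"), 1)
  if (kind == "bout") {
    on <- sample(0:700, 1)
    off <- min(on + sample(30:600, 1), 839)
    flags[(on:off) + 1] <- TRUE
  } else if (kind == "fragmented") {
    on <- sample(0:600, 1)
    off <- min(on + sample(60:500, 1), 839)
    idx <- on:off
    flags[idx[stats::runif(length(idx)) < 0.8] + 1] <- TRUE
  } else if (kind == "scattered") {
    flags[sample(0:839, sample(0:60, 1)) + 1] <- TRUE
  }
  flags
}
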