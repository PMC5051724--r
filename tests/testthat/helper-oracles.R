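# Independent brute-force oracles, deliberately coded as plain loops so
# they share nothing with the package's vectorised implementations.

brute_mad <- function(r) {
  n <- length(r)
  rbar <- sum(r) / n
  acc <- 0
  for (i in seq_len(n)) acc <- acc + abs(r[i] - rbar)
  acc / n
}

brute_enmo <- function(r, per_sample = TRUE) {
  n <- length(r)
  if (per_sample) {
    acc <- 0
    for (i in seq_len(n)) {
      e <- r[i] - 1000
      if (e > 0) acc <- acc + e
    }
    acc / n
  } else {
    acc <- 0
    for (i in seq_len(n)) acc <- acc + (r[i] - 1000)
    max(acc / n, 0)
  }
}

brute_auroc <- function(pos, neg) {
  acc <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) acc <- acc + 1
      else if (p == q) acc <- acc + 0.5
    }
  }
  acc / (length(pos) * length(neg))
}

# ROC point for rule score >= threshold by explicit counting
brute_roc_point <- function(pos, neg, thr) {
  c(sensitivity = sum(pos >= thr) / length(pos),
    specificity = sum(neg < thr) / length(neg))
}
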