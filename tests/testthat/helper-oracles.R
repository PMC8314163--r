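# Independent brute-force oracles, kept deliberately naive.

brute_entropy <- function(p) {
  h <- 0
  for (pi in p) {
    if (pi > 0) h <- h - pi * log(pi)
  }
  h
}

brute_norm_entropy <- function(p) {
  if (length(p) < 2L) return(0)
  h <- brute_entropy(p)
  if (h == 0) 0 else h / log(length(p))
}

brute_regularity <- function(a, b) {
  s <- 0
  for (t in 1:24) s <- s + a[t] * b[t]
  s / 24
}

brute_epoch_sd <- function(x) {
  m <- sum(x) / 4
  sqrt(sum((x - m)^2) / 3)
}

# Pooled SD over daily epoch-SDs, each from n_i = 4 epochs.
brute_pooled_sd <- function(daily_sds) {
  num <- 0
  den <- 0
  for (s in daily_sds) {
    num <- num + 3 * s^2
    den <- den + 3
  }
  sqrt(num / den)
}

# Holm step-down: adj_(i) = max_{j<=i} min(1, (m-j+1) p_(j)), input order.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[o[i]])
    running <- max(running, val)
    adj_sorted[i] <- running
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# BH step-up: adj_(i) = min_{j>=i} min(1, m p_(j) / j), input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    val <- min(1, m * p[o[i]] / i)
    running <- min(running, val)
    adj_sorted[i] <- running
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

brute_kappa <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  po <- (tp + tn) / n
  pe <- ((tp + fn) / n) * ((tp + fp) / n) + ((tn + fp) / n) * ((tn + fn) / n)
  (po - pe) / (1 - pe)
}
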