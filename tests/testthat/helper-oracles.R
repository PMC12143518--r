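# Independent brute-force oracles used to cross-check the implementation.

# Transform matrix built by circularly shifting zero-padded tap vectors,
# independent of the package's construction loop.
oracle_dwt_matrix <- function(taps, n) {
  M <- length(taps)
  k <- n / M
  W <- matrix(0, n, n)
  for (b in seq_len(M)) {
    base <- c(taps[[b]], rep(0, n - length(taps[[b]])))
    for (r in seq_len(k)) {
      shift <- M * (r - 1)
      row <- c(tail(base, shift), head(base, n - shift))  # circular shift right
      W[(b - 1) * k + r, ] <- row
    }
  }
  W
}

# Pair-counting adjusted Rand index: classify every cell pair as
# together/apart in each partition.
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# Plug-in entropy NMI with explicit loops over the joint distribution.
oracle_nmi <- function(a, b) {
  ua <- unique(a)
  ub <- unique(b)
  n <- length(a)
  mi <- 0
  for (x in ua) {
    for (y in ub) {
      pxy <- sum(a == x & b == y) / n
      if (pxy > 0) mi <- mi + pxy * log(pxy / (sum(a == x) / n * sum(b == y) / n))
    }
  }
  ha <- -sum(sapply(ua, function(x) { p <- sum(a == x) / n; p * log(p) }))
  hb <- -sum(sapply(ub, function(y) { p <- sum(b == y) / n; p * log(p) }))
  mi / sqrt(ha * hb)
}

# Exclusive membership by per-gene scan over all sets.
oracle_exclusive_cells <- function(sets) {
  universe <- unique(unlist(sets))
  out <- list()
  for (g in universe) {
    key <- paste(as.integer(sapply(sets, function(s) g %in% s)), collapse = "")
    out[[key]] <- c(out[[key]], g)
  }
  out
}
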