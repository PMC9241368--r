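# Independent oracles used by the tests. These deliberately share no code
# with the package implementation.

# Full O(nm) affine-gap local alignment DP (Gotoh). A gap of length L costs
# gap_open + L * gap_ext, matching the package's scoring convention.
gotoh_local_score <- function(q, s, match = 1, mismatch = -2,
                              gap_open = 5, gap_ext = 2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  Hprev <- numeric(m + 1)
  Fprev <- rep(-Inf, m + 1)
  best <- 0
  for (i in 1:n) {
    H <- numeric(m + 1)
    Fm <- rep(-Inf, m + 1)
    runmax <- -Inf
    subs <- ifelse(sc == qc[i], match, mismatch)
    for (j in 1:m) {
      Fm[j + 1] <- max(Hprev[j + 1] - gap_open - gap_ext,
                       Fprev[j + 1] - gap_ext)
      runmax <- max(runmax, H[j] + gap_ext * (j - 1))
      E <- runmax - gap_open - gap_ext * j
      h <- max(0, Hprev[j] + subs[j], Fm[j + 1], E)
      H[j + 1] <- h
      if (h > best) best <- h
    }
    Hprev <- H
    Fprev <- Fm
  }
  best
}

# Exhaustive two-sided Fisher p by direct hypergeometric enumeration
# (non-log; adequate for small tables).
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force point-in-interval scan over a 0-based half-open interval table
point_in_intervals <- function(pos, starts, ends) {
  any(starts <= pos & pos < ends)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# substitute exactly k positions (always to a different base)
diverge_seq <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  chars[pos] <- vapply(chars[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(chars, collapse = "")
}
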