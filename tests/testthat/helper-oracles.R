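# Independent brute-force oracles used to check the implementation paths.
# These deliberately share no code with the package internals.

STOPS <- c("TAA", "TAG", "TGA")

rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# enumerate every ATG..stop span in all six frames; return the longest
orf_oracle <- function(seq) {
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc_oracle(seq)
    L <- nchar(s)
    for (i in seq_len(max(0L, L - 5L))) {
      if (substring(s, i, i + 2) != "ATG") next
      j <- i + 3L
      while (j + 2L <= L) {
        if (substring(s, j, j + 2) %in% STOPS) {
          len <- j + 3L - i
          if (is.null(best) || len > best$length) {
            s0 <- i - 1L
            best <- if (strand == "+") {
              list(start = s0, end = s0 + len, length = len)
            } else {
              list(start = L - (s0 + len), end = L - s0, length = len)
            }
          }
          break
        }
        j <- j + 3L
      }
    }
  }
  best
}

# quadratic-space affine-gap global alignment score (Gotoh), matching the
# package's convention: a gap of length L costs open + L * ext; defaults
# mirror the event-calling global aligner
nw_score_oracle <- function(q, r, match = 2, mismatch = -3, open = 20,
                            ext = 2) {
  n <- nchar(q); m <- nchar(r)
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in reference (query insert)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in query
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (qs[i - 1] == rs[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# codon-by-codon scan for the first in-frame stop from position `from`
# (0-based); returns the 0-based position of the stop codon start or NA
stop_scan_oracle <- function(seq, from = 0L) {
  i <- from + 1L
  while (i + 2L <= nchar(seq)) {
    if (substring(seq, i, i + 2L) %in% STOPS) return(i - 1L)
    i <- i + 3L
  }
  NA_integer_
}

# exact hypergeometric upper tail by direct enumeration
hyper_oracle <- function(N, K, n, k) {
  js <- k:min(n, K)
  js <- js[n - js <= N - K]
  if (length(js) == 0L) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# random DNA of length n (plain base R)
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
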