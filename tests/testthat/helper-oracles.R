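# Independent oracles and fixture builders shared across tests.

random_dna <- function(n, gc = 0.5) {
  at <- (1 - gc) / 2
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at, gc / 2, gc / 2, at)), collapse = "")
}

# Brute-force recruitment oracle: a read matches iff any of its k-windows
# occurs verbatim in a bait sequence or in its reverse complement.
oracle_screen <- function(bait_seqs, read_seqs, k) {
  haystack <- c(bait_seqs, rebait::revcomp(bait_seqs))
  vapply(read_seqs, function(r) {
    n <- nchar(r)
    if (n < k) return(FALSE)
    windows <- substring(r, 1:(n - k + 1L), k:n)
    windows <- windows[!grepl("N", windows, fixed = TRUE)]
    any(vapply(windows, function(w)
      any(grepl(w, haystack, fixed = TRUE)), logical(1L)))
  }, logical(1L), USE.NAMES = FALSE)
}

# Exhaustive DP oracle for the semi-global alignment score: same model
# (match +1, mismatch -2, gap open -4, extend -1; global in the query,
# free target ends, terminal query gaps scored), written as plain
# matrix-filling R independent of the package implementation.
oracle_sg_score <- function(q, t) {
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  tc <- strsplit(t, "", fixed = TRUE)[[1L]]
  m <- length(qc); n <- length(tc); NEG <- -1e9
  M <- matrix(NEG, m + 1L, n + 1L)
  Iq <- matrix(NEG, m + 1L, n + 1L)
  It <- matrix(NEG, m + 1L, n + 1L)
  for (i in 1:m) {
    for (j in 0:n) {
      if (j > 0L) {
        prev <- if (i == 1L) 0 else max(M[i, j], Iq[i, j], It[i, j])
        s <- if (qc[i] == tc[j]) 1 else -2
        M[i + 1L, j + 1L] <- prev + s
        It[i + 1L, j + 1L] <- max(M[i + 1L, j] - 5, It[i + 1L, j] - 1)
      }
      Iq[i + 1L, j + 1L] <- if (i == 1L) -5
        else max(M[i, j + 1L] - 5, Iq[i, j + 1L] - 1)
    }
  }
  max(M[m + 1L, ], Iq[m + 1L, ])
}

oracle_sg_best <- function(q, t) {
  max(oracle_sg_score(q, t), oracle_sg_score(q, rebait::revcomp(t)))
}

# Definitional N50 oracle: largest L among the lengths such that the sum of
# lengths >= L reaches half the total.
oracle_n50 <- function(lengths) {
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= sum(lengths) / 2) return(L)
  }
  min(lengths)
}

# Brute-force end-overlap scan over all admissible prefix lengths.
oracle_end_overlap <- function(seq, min_len) {
  n <- nchar(seq)
  best <- 0L
  hi <- floor(n / 2)
  if (hi < min_len) return(0L)
  for (L in min_len:hi) {
    if (substr(seq, 1L, L) == substr(seq, n - L + 1L, n)) best <- L
  }
  best
}

# Error-free tiling reads over a sequence.
tiling_reads <- function(seq, read_len = 100L, step = 25L) {
  starts <- seq(1L, nchar(seq) - read_len + 1L, by = step)
  substring(seq, starts, starts + read_len - 1L)
}

# A small in-memory read set from plain sequences.
make_reads <- function(seqs, ids = NULL, pairing = "single", mate = NULL) {
  recs <- rebait::seq_records(seqs, id = ids)
  rebait::read_set(recs, pairing = pairing, mate = mate)
}
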