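# Independent brute-force oracles used to validate the compiled aligner and
# the permutation machinery. Deliberately naive implementations: full score
# matrices, explicit loops, no shared code with the package internals.

# plain-R local alignment score under affine gap costs
# (gap of length L costs gap_open + L * gap_extend)
oracle_sw_score <- function(q, r, match = 2, mismatch = -6,
                            gap_open = -5, gap_extend = -3) {
  n <- nchar(q); m <- nchar(r)
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  NEG <- -1e18
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                     F[i - 1, j] + gap_extend)
      s <- if (qc[i - 1] == rc[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# recompute an alignment score from its CIGAR/MD summary; agreement with the
# reported score ties the traceback to the DP
score_from_record <- function(rec, match = 2, mismatch = -6,
                              gap_open = -5, gap_extend = -3) {
  st <- parse_alignment(rec)
  ops <- parse_cigar(rec$cigar)
  gaps <- ops[ops$op %in% c("I", "D"), , drop = FALSE]
  match * st$matched + mismatch * st$mismatched +
    (if (nrow(gaps) > 0) gap_open * nrow(gaps) + gap_extend * sum(gaps$len)
     else 0)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# all permutations of a small vector (for exhaustive permutation nulls)
permn_all <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permn_all(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}
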