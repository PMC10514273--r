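# Shared fixtures built in code.

tiny_ref <- function(n_genera = 3, species_per_genus = 2, seed = 7, ...) {
  generate_reference(n_genera, species_per_genus, seed = seed, ...)
}

# a small genus-rank count table with known structure
toy_genus_counts <- function() {
  m <- rbind(S1 = c(Erodium = 900, Acmispon = 50, Panicum = 50, Weedus = 0),
             S2 = c(Erodium = 100, Acmispon = 880, Panicum = 0, Weedus = 20),
             S3 = c(Erodium = 500, Acmispon = 500, Panicum = 0, Weedus = 0),
             S4 = c(Erodium = 250, Acmispon = 740, Panicum = 0, Weedus = 10))
  attr(m, "rank") <- "genus"
  m
}

# incidence matrix with exactly Q1 uniques and Q2 duplicates among S_obs
# taxa over m samples (remaining taxa present in every sample)
incidence_with_Q <- function(m, S_obs, Q1, Q2) {
  stopifnot(S_obs >= Q1 + Q2)
  x <- matrix(0L, m, S_obs)
  col <- 1L
  for (i in seq_len(Q1)) { x[1L + (i %% m), col] <- 1L; col <- col + 1L }
  for (i in seq_len(Q2)) {
    rows <- 1L + c(i %% m, (i + 1L) %% m)
    x[unique(rows)[1:2], col] <- 1L
    col <- col + 1L
  }
  if (col <= S_obs) x[, col:S_obs] <- 1L
  x
}

# hand-evaluated stringency rule applications covering every boundary
accept_rule_cases <- function() {
  mk <- function(matched, mismatched, gaps, ls, rs)
    list(aligned_columns = matched + mismatched + gaps, matched = matched,
         mismatched = mismatched, gap_positions = gaps,
         left_skip = ls, right_skip = rs,
         identity = matched / (matched + mismatched + gaps))
  list(
    list(mk(300, 0, 0, 0, 0), TRUE,  "ok"),        # perfect
    list(mk(980, 20, 0, 0, 0), TRUE, "ok"),        # identity exactly 0.98
    list(mk(979, 21, 0, 0, 0), FALSE, "identity"), # identity 0.979
    list(mk(297, 0, 3, 0, 0), TRUE,  "ok"),        # 3 gap positions
    list(mk(296, 0, 4, 0, 0), FALSE, "gaps"),      # 4 gap positions
    list(mk(295, 0, 0, 5, 0), TRUE,  "ok"),        # left skip at the cap
    list(mk(295, 0, 0, 6, 0), FALSE, "end_skip"),  # left skip over the cap
    list(mk(295, 0, 0, 0, 5), TRUE,  "ok"),
    list(mk(295, 0, 0, 0, 6), FALSE, "end_skip"),
    list(mk(300, 0, 0, 6, 0), FALSE, "end_skip"),  # skip rejects regardless
    # both-end skips count as one gap each: at most one more gap fits
    list(mk(294, 0, 1, 3, 2), TRUE,  "ok"),
    list(mk(293, 0, 2, 3, 2), FALSE, "gaps"),
    list(mk(295, 0, 0, 5, 5), TRUE,  "ok"),
    list(mk(294, 0, 2, 5, 0), TRUE,  "ok"),        # 2 gaps + 1 skip = 3
    list(mk(293, 0, 3, 5, 0), FALSE, "gaps"),      # 3 gaps + 1 skip = 4
    list(mk(490, 10, 0, 0, 0), TRUE, "ok"),        # 490/500 = 0.98 exactly
    list(mk(489, 10, 1, 0, 0), FALSE, "identity"), # 489/500 = 0.978
    list(mk(98, 2, 0, 0, 0), TRUE, "ok"),          # 0.98 at small length
    list(mk(97, 3, 0, 0, 0), FALSE, "identity"),   # 0.97
    list(mk(294, 3, 3, 0, 0), TRUE, "ok"))         # 0.98 with 3 gaps
}
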