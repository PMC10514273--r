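#' Read trimming, pair merging with retry, and length retention
#'
#' An approximation of the trimming/merging stage of an amplicon pipeline:
#' k-mer matching of exogenous sequences (primers/adapters) with shorter
#' matches allowed at read ends, 3' quality trimming, overlap merging that
#' prefers the longest acceptable overlap, a stricter-retrim retry for
#' failed merges, and inclusive 200-450 bp length retention. Every stage
#' feeds a read-loss ledger so counts are conserved.
#'
#' @name read_processing
NULL

# all length-k substrings of x
kmers_of <- function(x, k) {
  unlist(lapply(x, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
}

#' Trim exogenous sequences (primers/adapters) from read pairs
#'
#' A read region matching any length-`k` subsequence of an exogenous
#' sequence (both strands), or a length >= `mink` match anchored at a read
#' end, is removed together with everything outward of it (toward the nearer
#' read end).
#'
#' A complete exogenous sequence sitting at a read end is also removed when
#' it carries up to `hdist` substitutions, so a sequencing error inside a
#' primer does not leave it behind.
#'
#' @param pairs read-pair data.frame (id, seq1, qual1, seq2, qual2).
#' @param exogenous character vector of primer/adapter sequences.
#' @param k full match length.
#' @param mink minimum match length at read ends.
#' @param hdist substitutions tolerated in a complete end-anchored match.
#' @return trimmed read-pair data.frame.
#' @export
trim_exogenous <- function(pairs, exogenous, k = 15L, mink = 11L,
                           hdist = 2L) {
  if (length(exogenous) == 0) {
    warnf("empty exogenous set: nothing trimmed")
    return(pairs)
  }
  if (k < mink || mink < 1) stopf("need k >= mink >= 1")
  exo <- unique(c(exogenous, revcomp(exogenous)))
  kmers <- unique(kmers_of(exo, k))
  ends <- seq.int(mink, k - 1L)
  prefixes <- unique(unlist(lapply(exo, function(s)
    substring(s, 1L, pmin(ends, nchar(s))))))
  suffixes <- unique(unlist(lapply(exo, function(s)
    substring(s, pmax(nchar(s) - ends + 1L, 1L), nchar(s)))))

  trim_one_side <- function(seqs, quals) {
    reg <- .exo_trim_scan_cpp(seqs, kmers, prefixes, suffixes, exo,
                              as.integer(k), as.integer(mink),
                              as.integer(hdist))
    keep <- reg[, 2] >= reg[, 1]
    s <- character(length(seqs)); q <- character(length(seqs))
    s[keep] <- substr(seqs[keep], reg[keep, 1], reg[keep, 2])
    q[keep] <- substr(quals[keep], reg[keep, 1], reg[keep, 2])
    list(seq = s, qual = q)
  }
  a <- trim_one_side(pairs$seq1, pairs$qual1)
  b <- trim_one_side(pairs$seq2, pairs$qual2)
  data.frame(id = pairs$id, seq1 = a$seq, qual1 = a$qual,
             seq2 = b$seq, qual2 = b$qual, stringsAsFactors = FALSE)
}

#' Trim low-quality 3' tails
#'
#' Removes the maximal suffix whose bases all have Phred quality < `q`;
#' internal low-quality bases are untouched.
#'
#' @param seqs,quals sequence and Phred+33 quality strings.
#' @param q quality threshold.
#' @return list with trimmed `seq` and `qual` vectors.
#' @export
quality_trim_3p <- function(seqs, quals, q = 10L) {
  keep <- .qtrim3_cpp(quals, as.integer(q))
  list(seq = substr(seqs, 1L, keep), qual = substr(quals, 1L, keep))
}

#' Merge one read pair by overlap
#'
#' Reverse-complements the second mate and scans overlap lengths from
#' longest to shortest, accepting the longest overlap whose mismatch rate is
#' <= `max_mismatch_rate`. Disagreements take the higher-quality base;
#' merged quality is the max of the two mates.
#'
#' @param seq1,qual1,seq2,qual2 the two mates (qualities Phred+33).
#' @param min_overlap minimum acceptable overlap (>= 8).
#' @param max_mismatch_rate maximum mismatch fraction within the overlap.
#' @return list(merged = TRUE, seq, qual, overlap, mismatches) or
#'   list(merged = FALSE, reason).
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2,
                       min_overlap = 12L, max_mismatch_rate = 0.1) {
  if (min_overlap < 8) stopf("min_overlap must be >= 8")
  if (nchar(seq1) == 0 || nchar(seq2) == 0)
    return(list(merged = FALSE, reason = "empty_read"))
  s2rc <- revcomp(seq2)
  q2rc <- rev(phred_to_int(qual2))
  res <- merge_one(seq1, s2rc, phred_to_int(qual1), q2rc,
                   as.integer(min_overlap), max_mismatch_rate)
  if (!res$merged) return(res)
  list(merged = TRUE, seq = res$seq, qual = int_to_phred(res$qual),
       overlap = res$overlap, mismatches = res$mismatches)
}

# innie overlap scan; on failure, retry with the mates' roles swapped
# ("outie" geometry: the sequencer read through the amplicon ends, leaving
# sub-mink primer remnants outward of the overlap) and keep only the
# overlap consensus -- the overhangs lie beyond the amplicon.
merge_one <- function(s1, s2rc, q1, q2rc, min_overlap, max_mismatch_rate) {
  res <- .merge_overlap_cpp(s1, s2rc, q1, q2rc, min_overlap,
                            max_mismatch_rate)
  if (res$merged) return(res)
  out <- .merge_overlap_cpp(s2rc, s1, q2rc, q1, min_overlap,
                            max_mismatch_rate)
  if (!out$merged) return(res)
  off <- nchar(s2rc) - out$overlap
  out$seq <- substr(out$seq, off + 1L, off + out$overlap)
  out$qual <- out$qual[(off + 1L):(off + out$overlap)]
  out
}

# vectorized merge over a pair data.frame; returns merged df + failure index
merge_pairs_batch <- function(pairs, min_overlap, max_mismatch_rate) {
  n <- nrow(pairs)
  seqs <- character(n); quals <- character(n); ok <- logical(n)
  s2rc_all <- revcomp(pairs$seq2)
  for (i in seq_len(n)) {
    if (nchar(pairs$seq1[i]) == 0 || nchar(pairs$seq2[i]) == 0) next
    res <- merge_one(pairs$seq1[i], s2rc_all[i],
                     utf8ToInt(pairs$qual1[i]) - 33L,
                     rev(utf8ToInt(pairs$qual2[i]) - 33L),
                     as.integer(min_overlap), max_mismatch_rate)
    if (res$merged) {
      ok[i] <- TRUE
      seqs[i] <- res$seq
      quals[i] <- intToUtf8(res$qual + 33L)
    }
  }
  list(merged = data.frame(id = pairs$id[ok], seq = seqs[ok], qual = quals[ok],
                           stringsAsFactors = FALSE),
       failed = pairs[!ok, , drop = FALSE])
}

#' Merge read pairs with a stricter-retrim retry
#'
#' Both mates are quality-trimmed at `q1` and merged; pairs that fail are
#' re-trimmed at the stricter `q2` and merged once more. `merge_pass`
#' records which attempt succeeded; pairs failing both attempts are dropped
#' and counted in the loss ledger.
#'
#' @param pairs read-pair data.frame (after exogenous trimming).
#' @param q1,q2 first-pass and retry 3' quality thresholds (q2 >= q1).
#' @param min_overlap,max_mismatch_rate merge acceptance parameters.
#' @return list(merged = data.frame(id, seq, qual, merge_pass),
#'   ledger = data.frame(stage, count)).
#' @export
merge_with_retry <- function(pairs, q1 = 10L, q2 = 15L,
                             min_overlap = 12L, max_mismatch_rate = 0.1) {
  if (q2 < q1) stopf("q2 must be >= q1")
  t1a <- quality_trim_3p(pairs$seq1, pairs$qual1, q1)
  t1b <- quality_trim_3p(pairs$seq2, pairs$qual2, q1)
  first <- merge_pairs_batch(
    data.frame(id = pairs$id, seq1 = t1a$seq, qual1 = t1a$qual,
               seq2 = t1b$seq, qual2 = t1b$qual, stringsAsFactors = FALSE),
    min_overlap, max_mismatch_rate)

  retry_in <- pairs[match(first$failed$id, pairs$id), , drop = FALSE]
  t2a <- quality_trim_3p(retry_in$seq1, retry_in$qual1, q2)
  t2b <- quality_trim_3p(retry_in$seq2, retry_in$qual2, q2)
  second <- merge_pairs_batch(
    data.frame(id = retry_in$id, seq1 = t2a$seq, qual1 = t2a$qual,
               seq2 = t2b$seq, qual2 = t2b$qual, stringsAsFactors = FALSE),
    min_overlap, max_mismatch_rate)

  merged <- rbind(
    if (nrow(first$merged)) cbind(first$merged, merge_pass = "first"),
    if (nrow(second$merged)) cbind(second$merged, merge_pass = "retry"))
  if (is.null(merged))
    merged <- data.frame(id = character(0), seq = character(0),
                         qual = character(0), merge_pass = character(0),
                         stringsAsFactors = FALSE)
  ledger <- data.frame(
    stage = c("input_pairs", "merged_first", "merged_retry", "merge_failed"),
    count = c(nrow(pairs), nrow(first$merged), nrow(second$merged),
              nrow(second$failed)),
    stringsAsFactors = FALSE)
  list(merged = merged, ledger = ledger)
}

#' Retain merged reads within a length window (inclusive)
#'
#' @param merged merged-read data.frame (id, seq, qual, ...).
#' @param lo,hi inclusive length bounds.
#' @return list(retained, ledger).
#' @export
length_filter <- function(merged, lo = 200L, hi = 450L) {
  if (lo > hi) stopf("need lo <= hi")
  len <- nchar(merged$seq)
  keep <- len >= lo & len <= hi
  list(retained = merged[keep, , drop = FALSE],
       ledger = data.frame(stage = c("length_retained", "length_rejected"),
                           count = c(sum(keep), sum(!keep)),
                           stringsAsFactors = FALSE))
}

#' Run the whole read-processing stage
#'
#' Exogenous trimming, then merge with retry (which applies the 3' quality
#' trims), then length retention, with a combined loss ledger.
#'
#' @param pairs raw read-pair data.frame.
#' @param exogenous primer/adapter sequences; defaults to the synthetic
#'   primer pair.
#' @param k,mink,q1,q2,lo,hi,min_overlap,max_mismatch_rate stage parameters.
#' @return list(merged, ledger).
#' @export
process_reads <- function(pairs, exogenous = unlist(primer_set()),
                          k = 15L, mink = 11L, q1 = 10L, q2 = 15L,
                          lo = 200L, hi = 450L,
                          min_overlap = 12L, max_mismatch_rate = 0.1) {
  trimmed <- trim_exogenous(pairs, exogenous, k, mink)
  mr <- merge_with_retry(trimmed, q1, q2, min_overlap, max_mismatch_rate)
  lf <- length_filter(mr$merged, lo, hi)
  list(merged = lf$retained, ledger = rbind(mr$ledger, lf$ledger))
}
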