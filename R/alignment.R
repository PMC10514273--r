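#' Local alignment and the CIGAR/MD stringency filter
#'
#' The centrepiece filter of the pipeline: merged reads are aligned locally
#' to the plant reference and an alignment is accepted only when, over the
#' aligned length (M+I+D columns), at least 98% of columns are identical,
#' the alignment carries at most three gap positions (each nonzero end skip
#' counting as one additional gap), and no end skip exceeds five positions.
#' The same rule applies unchanged to SAM produced by an external aligner.
#'
#' @name alignment_filter
NULL

#' Stringency and aligner parameter sets
#'
#' `stringency_params()` carries the acceptance rule thresholds;
#' `aligner_params()` the local-alignment scoring (bowtie2-like: match
#' bonus 2, mismatch -6, affine gaps -5 open / -3 extend) and the
#' score floor `score_floor_const + score_floor_slope * ln(read length)`
#' below which a read is reported unmapped.
#'
#' @param min_identity minimum fraction of identical aligned columns.
#' @param max_gap_positions maximum effective gap positions.
#' @param max_end_skip maximum soft-clipped positions at either end.
#' @return a named list of parameters.
#' @export
stringency_params <- function(min_identity = 0.98, max_gap_positions = 3L,
                              max_end_skip = 5L) {
  stopifnot(min_identity > 0, min_identity <= 1,
            max_gap_positions >= 0, max_end_skip >= 0)
  list(min_identity = min_identity,
       max_gap_positions = as.integer(max_gap_positions),
       max_end_skip = as.integer(max_end_skip))
}

#' @rdname stringency_params
#' @param match,mismatch,gap_open,gap_extend alignment scores
#'   (mismatch and gap penalties <= 0 <= match).
#' @param score_floor_const,score_floor_slope affine-in-log-length floor.
#' @export
aligner_params <- function(match = 2, mismatch = -6,
                           gap_open = -5, gap_extend = -3,
                           score_floor_const = 80, score_floor_slope = 8) {
  stopifnot(match >= 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend,
       score_floor_const = score_floor_const,
       score_floor_slope = score_floor_slope)
}

score_floor <- function(ap, len) {
  ap$score_floor_const + ap$score_floor_slope * log(len)
}

#' Parse a CIGAR string into its operations
#'
#' @param cigar CIGAR string over ops M, I, D, S.
#' @return data.frame(op, len).
#' @export
parse_cigar <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDS])", cigar)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(cigar))
    stopf("malformed CIGAR: %s", cigar)
  tok <- regmatches(cigar, gregexpr("\\d+[MIDS]", cigar))[[1]]
  data.frame(op = substr(tok, nchar(tok), nchar(tok)),
             len = as.integer(substr(tok, 1, nchar(tok) - 1L)),
             stringsAsFactors = FALSE)
}

# parse an MD string into mismatch and deletion counts
parse_md <- function(md) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Z]+|[A-Z]", md))[[1]]
  if (paste(toks, collapse = "") != md) stopf("malformed MD string: %s", md)
  matched <- sum(as.integer(toks[grepl("^\\d+$", toks)]))
  mismatched <- sum(grepl("^[A-Z]$", toks))
  deleted <- sum(nchar(sub("^\\^", "", toks[startsWith(toks, "^")])))
  list(matched = matched, mismatched = mismatched, deleted = deleted)
}

#' Summarize an alignment record from its CIGAR and MD fields
#'
#' Computes the quantities the stringency rule is evaluated on: aligned
#' columns (M+I+D), matched/mismatched counts, gap positions (sum of I and D
#' lengths), and the soft-clip lengths at the two ends. Soft clips
#' contribute nothing to the aligned length.
#'
#' @param record list or one-row data.frame with `cigar` and `md` (and
#'   optionally `query_id` for error messages).
#' @return list: aligned_columns, matched, mismatched, gap_positions,
#'   left_skip, right_skip, identity.
#' @export
parse_alignment <- function(record) {
  id <- if (!is.null(record$query_id)) record$query_id else "<record>"
  ops <- parse_cigar(record$cigar)
  n <- nrow(ops)
  is_s <- ops$op == "S"
  if (any(is_s & !(seq_len(n) %in% c(1L, n))))
    stopf("record %s: internal soft clip in CIGAR %s", id, record$cigar)
  left_skip <- if (is_s[1]) ops$len[1] else 0L
  right_skip <- if (n > 1 && is_s[n]) ops$len[n] else 0L
  m_len <- sum(ops$len[ops$op == "M"])
  i_len <- sum(ops$len[ops$op == "I"])
  d_len <- sum(ops$len[ops$op == "D"])
  md <- parse_md(record$md)
  if (md$matched + md$mismatched != m_len)
    stopf("record %s: MD (%s) inconsistent with CIGAR %s (M length %d)",
          id, record$md, record$cigar, m_len)
  if (md$deleted != d_len)
    stopf("record %s: MD deletions (%d) inconsistent with CIGAR D length %d",
          id, md$deleted, d_len)
  aligned <- m_len + i_len + d_len
  list(aligned_columns = aligned,
       matched = md$matched,
       mismatched = md$mismatched,
       gap_positions = i_len + d_len,
       left_skip = left_skip,
       right_skip = right_skip,
       identity = md$matched / aligned)
}

#' Apply the alignment stringency rule
#'
#' Rejects when either end skip exceeds `max_end_skip`; otherwise each
#' nonzero end skip counts as one gap of size 1, and the alignment is
#' accepted iff identity >= `min_identity` and effective gap positions <=
#' `max_gap_positions`. The reason names the first failed criterion.
#'
#' @param stats output of [parse_alignment()].
#' @param p a [stringency_params()] list.
#' @return list(accept = logical, reason = character).
#' @export
accept_alignment <- function(stats, p = stringency_params()) {
  if (stats$left_skip > p$max_end_skip || stats$right_skip > p$max_end_skip)
    return(list(accept = FALSE, reason = "end_skip"))
  if (stats$identity < p$min_identity)
    return(list(accept = FALSE, reason = "identity"))
  eff_gaps <- stats$gap_positions +
    (stats$left_skip > 0) + (stats$right_skip > 0)
  if (eff_gaps > p$max_gap_positions)
    return(list(accept = FALSE, reason = "gaps"))
  list(accept = TRUE, reason = "ok")
}

#' Locally align a query to one reference entry
#'
#' Optimal local alignment under affine gap scoring, reported with a SAM
#' CIGAR (soft clips for unaligned query ends) and MD string. The query is
#' unmapped when the best score falls below the score floor.
#'
#' @param query nucleotide string.
#' @param ref_entry one reference row (accession, sequence) or a plain
#'   sequence string.
#' @param ap an [aligner_params()] list.
#' @param query_id id recorded on the result.
#' @return list record: query_id, accession, mapped, score, ref_start,
#'   cigar, md, seq.
#' @export
local_align <- function(query, ref_entry, ap = aligner_params(),
                        query_id = "q") {
  if (nchar(query) == 0) stopf("empty query")
  refseq <- if (is.character(ref_entry)) ref_entry else ref_entry$sequence
  acc <- if (is.character(ref_entry)) "ref" else ref_entry$accession
  res <- .sw_align_cpp(query, refseq, ap$match, ap$mismatch,
                       ap$gap_open, ap$gap_extend)
  if (!res$mapped || res$score < score_floor(ap, nchar(query)))
    return(list(query_id = query_id, accession = acc, mapped = FALSE,
                score = res$score, seq = query))
  list(query_id = query_id, accession = acc, mapped = TRUE,
       score = res$score, ref_start = res$ref_start,
       cigar = res$cigar, md = res$md, seq = query)
}

#' Map merged reads to the reference with best-hit assignment
#'
#' Reads are dereplicated, shortlisted against candidate references by
#' shared k-mer counts (exact substring hits shortcut the DP entirely), and
#' each read is assigned to the highest-scoring reference whose alignment
#' passes the stringency rule; score ties break to the lexicographically
#' smallest accession. The ledger counts unmapped, rejected-by-filter and
#' accepted reads.
#'
#' @param merged merged-read data.frame (id, seq).
#' @param ref reference database.
#' @param ap,sp aligner and stringency parameter lists.
#' @param n_candidates references shortlisted per read (k-mer prescreen).
#' @param kmer prescreen k-mer size.
#' @return list(assignments = data.frame(query_id, accession, genus,
#'   species, score, identity), records = accepted records (SAM-writable),
#'   decisions = per-read decision table, ledger).
#' @export
map_sample <- function(merged, ref, ap = aligner_params(),
                       sp = stringency_params(),
                       n_candidates = 5L, kmer = 12L) {
  if (nrow(ref) == 0) stopf("empty reference")
  stopifnot(nrow(merged) == 0 || all(nchar(merged$seq) > 0))
  n <- nrow(merged)
  uniq <- unique(merged$seq)
  hits <- .kmer_hits_cpp(uniq, ref$sequence, as.integer(kmer))
  ord_acc <- order(ref$accession)

  per_uniq <- vector("list", length(uniq))
  for (u in seq_along(uniq)) {
    q <- uniq[u]
    h <- hits[u, ]
    cand <- order(h, decreasing = TRUE)
    take <- min(n_candidates, length(cand))
    # keep every reference tied with the last shortlisted hit count
    cutoff <- h[cand[take]]
    cand <- cand[h[cand] >= cutoff & h[cand] > 0]
    best <- NULL
    for (j in cand[order(ref$accession[cand])]) {
      refseq <- ref$sequence[j]
      pos <- regexpr(q, refseq, fixed = TRUE)
      if (pos > 0) {
        L <- nchar(q)
        rec <- list(query_id = NA_character_, accession = ref$accession[j],
                    mapped = TRUE, score = ap$match * L, ref_start = as.integer(pos),
                    cigar = paste0(L, "M"), md = as.character(L), seq = q)
      } else {
        rec <- local_align(q, ref[j, ], ap)
      }
      if (!rec$mapped) next
      st <- parse_alignment(rec)
      ac <- accept_alignment(st, sp)
      cand_rec <- list(rec = rec, stats = st, accept = ac$accept,
                       reason = ac$reason)
      if (is.null(best)) best <- cand_rec
      else {
        # prefer accepted over not, then higher score, then smaller accession
        b <- best
        better <- (cand_rec$accept && !b$accept) ||
          (cand_rec$accept == b$accept &&
             (cand_rec$rec$score > b$rec$score ||
                (cand_rec$rec$score == b$rec$score &&
                   cand_rec$rec$accession < b$rec$accession)))
        if (better) best <- cand_rec
      }
    }
    per_uniq[[u]] <- best
  }

  # expand unique-sequence decisions back to reads
  ui <- match(merged$seq, uniq)
  status <- character(n); acc <- character(n)
  score <- numeric(n); ident <- numeric(n)
  cigar <- character(n); md <- character(n); rstart <- integer(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    b <- per_uniq[[ui[i]]]
    if (is.null(b)) {
      status[i] <- "unmapped"; reason[i] <- "unmapped"
    } else if (!b$accept) {
      status[i] <- "rejected"; reason[i] <- b$reason
      acc[i] <- b$rec$accession; score[i] <- b$rec$score
      ident[i] <- b$stats$identity
    } else {
      status[i] <- "accepted"; reason[i] <- "ok"
      acc[i] <- b$rec$accession; score[i] <- b$rec$score
      ident[i] <- b$stats$identity
      cigar[i] <- b$rec$cigar; md[i] <- b$rec$md
      rstart[i] <- b$rec$ref_start
    }
  }
  keep <- status == "accepted"
  tax <- ref[match(acc[keep], ref$accession), ]
  assignments <- data.frame(query_id = merged$id[keep],
                            accession = acc[keep],
                            genus = tax$genus, species = tax$species,
                            score = score[keep], identity = ident[keep],
                            stringsAsFactors = FALSE)
  records <- data.frame(query_id = merged$id[keep], accession = acc[keep],
                        ref_start = rstart[keep], cigar = cigar[keep],
                        md = md[keep], score = score[keep],
                        seq = merged$seq[keep], stringsAsFactors = FALSE)
  decisions <- data.frame(query_id = merged$id, accession = acc,
                          score = score, identity = ident,
                          status = status, reason = reason,
                          stringsAsFactors = FALSE)
  ledger <- data.frame(stage = c("unmapped", "rejected_by_filter", "accepted"),
                       count = c(sum(status == "unmapped"),
                                 sum(status == "rejected"), sum(keep)),
                       stringsAsFactors = FALSE)
  list(assignments = assignments, records = records,
       decisions = decisions, ledger = ledger)
}

#' Apply the stringency filter to external SAM records
#'
#' Runs [parse_alignment()] + [accept_alignment()] over records read with
#' [read_sam()], e.g. real output from an external local aligner.
#'
#' @param records SAM record data.frame.
#' @param sp a [stringency_params()] list.
#' @return data.frame with per-record identity, gap positions, skips,
#'   accepted flag and reason.
#' @export
filter_sam_records <- function(records, sp = stringency_params()) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    st <- parse_alignment(records[i, ])
    ac <- accept_alignment(st, sp)
    data.frame(query_id = records$query_id[i],
               accession = records$accession[i],
               identity = st$identity, gap_positions = st$gap_positions,
               left_skip = st$left_skip, right_skip = st$right_skip,
               accepted = ac$accept, reason = ac$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
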