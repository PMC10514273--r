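#' File interfaces: FASTA, FASTQ, taxonomy and SAM
#'
#' FASTA/FASTQ go through Biostrings. SAM records are read and written as
#' plain text lines, restricted to what the alignment filter needs (mapped
#' records with CIGAR and an MD tag); this keeps the filter applicable to
#' output from any external local aligner.
#'
#' @name io
NULL

#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   PhredQuality QualityScaledDNAStringSet readQualityScaledDNAStringSet
#'   writeQualityScaledXStringSet quality
NULL

#' Write / read a reference database as FASTA + taxonomy TSV
#'
#' @param ref reference data.frame ([generate_reference()]).
#' @param fasta_path,taxonomy_path output paths.
#' @return `read_reference` returns the reference data.frame.
#' @export
write_reference <- function(ref, fasta_path, taxonomy_path) {
  seqs <- Biostrings::DNAStringSet(stats::setNames(ref$sequence, ref$accession))
  Biostrings::writeXStringSet(seqs, fasta_path)
  write_tsv_file(ref[, c("accession", "genus", "species",
                         "growth_form", "native")], taxonomy_path)
  invisible(fasta_path)
}

#' @rdname write_reference
#' @export
read_reference <- function(fasta_path, taxonomy_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  tax <- read_tsv_file(taxonomy_path)
  stopifnot(setequal(names(seqs), tax$accession))
  tax$sequence <- as.character(seqs)[tax$accession]
  tax
}

#' Write / read paired FASTQ files
#'
#' @param pairs read-pair data.frame (id, seq1, qual1, seq2, qual2).
#' @param r1_path,r2_path mate FASTQ paths (".gz" suffix compresses).
#' @return `read_read_pairs` returns a read-pair data.frame.
#' @export
write_read_pairs <- function(pairs, r1_path, r2_path) {
  w <- function(seqs, quals, ids, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
      Biostrings::PhredQuality(quals))
    Biostrings::writeQualityScaledXStringSet(
      x, path, compress = grepl("\\.gz$", path))
  }
  w(pairs$seq1, pairs$qual1, pairs$id, r1_path)
  w(pairs$seq2, pairs$qual2, pairs$id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' @rdname write_read_pairs
#' @export
read_read_pairs <- function(r1_path, r2_path) {
  r <- function(path) {
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    list(id = names(x), seq = as.character(x),
         qual = as.character(Biostrings::quality(x)))
  }
  a <- r(r1_path); b <- r(r2_path)
  stopifnot(identical(a$id, b$id))
  data.frame(id = a$id, seq1 = unname(a$seq), qual1 = unname(a$qual),
             seq2 = unname(b$seq), qual2 = unname(b$qual),
             stringsAsFactors = FALSE)
}

#' Write merged reads as FASTQ
#'
#' @param merged merged-read data.frame (id, seq, qual).
#' @param path output FASTQ path.
#' @export
write_merged_fastq <- function(merged, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(merged$seq, merged$id)),
    Biostrings::PhredQuality(merged$qual))
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write accepted alignment records as SAM
#'
#' Emits @HD/@SQ headers and one line per mapped record with MAPQ 255,
#' an AS (alignment score) and an MD tag.
#'
#' @param records alignment record data.frame from [map_sample()]'s
#'   `records` element, or any data.frame with query_id, accession,
#'   ref_start, cigar, md, score, seq columns.
#' @param ref reference database (for @SQ lengths).
#' @param path output SAM path.
#' @export
write_sam <- function(records, ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_len(nrow(ref)))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ref$accession[i],
                       nchar(ref$sequence[i])), con)
  if (nrow(records) > 0) {
    lines <- sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tAS:i:%d\tMD:Z:%s",
                     records$query_id, records$accession,
                     as.integer(records$ref_start), records$cigar,
                     records$seq, as.integer(round(records$score)),
                     records$md)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read mapped SAM records
#'
#' Header lines are skipped; unmapped records (flag 0x4 or CIGAR `*`) are
#' dropped. Records without an MD tag are recomputed against `ref` when it
#' is supplied, otherwise reading fails naming the record, because the
#' stringency filter cannot be evaluated without mismatch information.
#'
#' @param path SAM file path.
#' @param ref optional reference database used to recompute missing MD tags.
#' @return data.frame with query_id, accession, ref_start, cigar, md, score,
#'   seq.
#' @export
read_sam <- function(path, ref = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(data.frame(query_id = character(0), accession = character(0),
                      ref_start = integer(0), cigar = character(0),
                      md = character(0), score = numeric(0),
                      seq = character(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_one <- function(f) {
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) == 4L || f[6] == "*") return(NULL)
    opt <- f[-(1:11)]
    md <- sub("^MD:Z:", "", grep("^MD:Z:", opt, value = TRUE))
    as_tag <- sub("^AS:i:", "", grep("^AS:i:", opt, value = TRUE))
    data.frame(query_id = f[1], accession = f[3],
               ref_start = as.integer(f[4]), cigar = f[6],
               md = if (length(md)) md[1] else NA_character_,
               score = if (length(as_tag)) as.numeric(as_tag[1]) else NA_real_,
               seq = f[10], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Filter(Negate(is.null), lapply(fields, parse_one)))
  miss <- which(is.na(out$md))
  if (length(miss) > 0) {
    if (is.null(ref))
      stopf("SAM records lacking MD tag (e.g. %s); supply `ref` to recompute",
            out$query_id[miss[1]])
    for (i in miss) {
      rseq <- ref$sequence[match(out$accession[i], ref$accession)]
      if (is.na(rseq))
        stopf("cannot recompute MD for %s: accession %s not in reference",
              out$query_id[i], out$accession[i])
      out$md[i] <- compute_md(out$seq[i], rseq, out$ref_start[i], out$cigar[i])
    }
  }
  out
}

# derive the MD string for a record from its CIGAR and the reference
compute_md <- function(seq, refseq, ref_start, cigar) {
  ops <- parse_cigar(cigar)
  qpos <- 1L; rpos <- ref_start
  md <- ""; run <- 0L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op == "S") {
      qpos <- qpos + len
    } else if (op == "M") {
      for (k in seq_len(len)) {
        qb <- substr(seq, qpos, qpos); rb <- substr(refseq, rpos, rpos)
        if (qb == rb) run <- run + 1L
        else { md <- paste0(md, run, rb); run <- 0L }
        qpos <- qpos + 1L; rpos <- rpos + 1L
      }
    } else if (op == "I") {
      qpos <- qpos + len
    } else if (op == "D") {
      md <- paste0(md, run, "^", substr(refseq, rpos, rpos + len - 1L))
      run <- 0L
      rpos <- rpos + len
    }
  }
  paste0(md, run)
}
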