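#' @useDynLib ppmdiet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor isoreg pt qt quantile rbinom rmultinom rnorm runif sd
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of A/C/G/T(/N) strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Convert Phred+33 quality strings to integer scores and back
#'
#' @param x quality string(s) / integer vector of scores.
#' @return integer vector (list for vector input) / single string.
#' @export
phred_to_int <- function(x) {
  if (length(x) == 1L) return(utf8ToInt(x) - 33L)
  lapply(x, function(s) utf8ToInt(s) - 33L)
}

#' @rdname phred_to_int
#' @export
int_to_phred <- function(x) intToUtf8(x + 33L)

random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

# substitute bases at `positions` in `seq` with random different bases
mutate_bases <- function(seq, positions) {
  if (length(positions) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Write / read tab-separated tables with a header row
#'
#' Thin wrappers fixing the conventions used throughout the package
#' (header, no quoting, no row names).
#'
#' @param x data.frame. @param path file path.
#' @return `read_tsv_file` returns a data.frame.
#' @export
write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

# samples x taxa matrix from a data.frame with sample_id first column
df_to_matrix <- function(df) {
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

matrix_to_df <- function(m) {
  data.frame(sample_id = rownames(m), as.data.frame(m, check.names = FALSE),
             check.names = FALSE, row.names = NULL)
}
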