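# Shared low-level helpers: percentage rounding, k-mer sets, TSV I/O.

#' Percentage of a count, rounded half-up to one decimal
#'
#' Reporting convention for occupancy and linkage fractions: percentages are
#' rounded half-up (not banker's rounding) to one decimal place, so
#' 131/3146 prints as 4.2 and 2360/3146 as 75.0.
#'
#' @param count numerator count.
#' @param total denominator count (> 0).
#' @param digits decimal places to keep (default 1).
#' @return numeric percentage.
#' @export
#' @examples
#' occupancy_percent(131, 3146)   # 4.2
#' occupancy_percent(2360, 3146)  # 75.0
occupancy_percent <- function(count, total, digits = 1L) {
  stopifnot(total > 0, count >= 0)
  round_half_up(100 * count / total, digits)
}

round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Canonical k-mer set of a nucleotide sequence
#'
#' All k-mers of the sequence, each replaced by the lexicographically smaller
#' of itself and its reverse complement, deduplicated. K-mers containing
#' non-ACGT characters are dropped.
#'
#' @param seq a single character string or \code{DNAString}.
#' @param k k-mer size (>= 1).
#' @return character vector of distinct canonical k-mers (empty if the
#'   sequence is shorter than \code{k}).
#' @export
kmer_set <- function(seq, k = 21L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0L) return(character(0))
  rc <- revcomp_chr(kmers)
  unique(pmin(kmers, rc))
}

# vectorized reverse complement on character k-mers
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' @noRd
write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

# stable sample of x of size `size` (avoids sample()'s scalar surprise)
sample_vec <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
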