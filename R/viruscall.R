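# Ensemble virus calling from per-contig predictor scores, plus k-mer
# containment screening against putative laboratory-contaminant genomes.

#' Default thresholds for the four-criterion ensemble virus call
#'
#' The ensemble decision combines VirSorter categories, DeepVirFinder score
#' and p-value, and MARVEL probability. A contig is called viral if it meets
#' any of: (i) VirSorter category 1, 2, 4 or 5; (ii) DeepVirFinder score
#' >= 0.9 and p < 0.05; (iii) MARVEL probability >= 90; (iv) DeepVirFinder
#' score >= 0.7 and p < 0.05 and MARVEL probability >= 70.
#'
#' @return named list of threshold values.
#' @export
virus_call_thresholds <- function() {
  list(
    virsorter_categories = c(1L, 2L, 4L, 5L),
    dvf_score_strict = 0.9, dvf_score_relaxed = 0.7,
    dvf_p_max = 0.05,
    marvel_strict = 90, marvel_relaxed = 70,
    min_len = 5000L, circular_min_len = 1500L, circular_max_len = 5000L
  )
}

#' Classify contigs as viral from ensemble predictor scores
#'
#' Applies the four-criterion union rule to a per-contig score table. Each
#' criterion is evaluated independently; an absent (NA) score makes its
#' criterion fail, it is never an error. Boundary comparisons are literal:
#' a DeepVirFinder p-value of exactly 0.05 fails the \code{< 0.05} test.
#'
#' Eligibility reflects the assembly-side length rule: contigs of length
#' >= 5 kb, or circular contigs of 1.5–5.0 kb, are eligible for downstream
#' analysis.
#'
#' @param scores data.frame with columns \code{contig_id}, \code{length},
#'   \code{circular} (logical), \code{virsorter_category} (integer 1–6 or
#'   NA), \code{dvf_score} (0–1 or NA), \code{dvf_p} (0–1 or NA),
#'   \code{marvel_prob} (percent 0–100 or NA).
#' @param thresholds list as returned by \code{\link{virus_call_thresholds}}.
#' @return data.frame with one row per contig: \code{contig_id},
#'   \code{is_virus}, \code{criteria_met} (comma-joined subset of
#'   \code{i,ii,iii,iv}), \code{eligible}.
#' @export
#' @examples
#' sc <- data.frame(contig_id = "c1", length = 12000, circular = FALSE,
#'                  virsorter_category = 2, dvf_score = NA, dvf_p = NA,
#'                  marvel_prob = NA)
#' classify_virus(sc)
classify_virus <- function(scores, thresholds = virus_call_thresholds()) {
  required <- c("contig_id", "length", "circular", "virsorter_category",
                "dvf_score", "dvf_p", "marvel_prob")
  missing_cols <- setdiff(required, names(scores))
  if (length(missing_cols) > 0)
    stop("score table missing columns: ", paste(missing_cols, collapse = ", "))
  validate_range <- function(x, lo, hi, field) {
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad))
      stop("out-of-range value in field '", field, "': ",
           paste(x[bad], collapse = ", "))
  }
  validate_range(scores$dvf_score, 0, 1, "dvf_score")
  validate_range(scores$dvf_p, 0, 1, "dvf_p")
  validate_range(scores$marvel_prob, 0, 100, "marvel_prob")
  validate_range(scores$virsorter_category, 1, 6, "virsorter_category")

  th <- thresholds
  vs <- scores$virsorter_category
  ds <- scores$dvf_score
  dp <- scores$dvf_p
  mv <- scores$marvel_prob
  c_i   <- !is.na(vs) & vs %in% th$virsorter_categories
  c_ii  <- !is.na(ds) & !is.na(dp) & ds >= th$dvf_score_strict & dp < th$dvf_p_max
  c_iii <- !is.na(mv) & mv >= th$marvel_strict
  c_iv  <- !is.na(ds) & !is.na(dp) & !is.na(mv) &
    ds >= th$dvf_score_relaxed & dp < th$dvf_p_max & mv >= th$marvel_relaxed

  crit <- cbind(i = c_i, ii = c_ii, iii = c_iii, iv = c_iv)
  met <- apply(crit, 1L, function(row) paste(colnames(crit)[row], collapse = ","))
  circ <- as.logical(scores$circular)
  eligible <- scores$length >= th$min_len |
    (circ & scores$length >= th$circular_min_len &
       scores$length <= th$circular_max_len)

  data.frame(
    contig_id = as.character(scores$contig_id),
    is_virus = c_i | c_ii | c_iii | c_iv,
    criteria_met = met,
    eligible = eligible,
    stringsAsFactors = FALSE
  )
}

#' Screen contigs against putative laboratory-contaminant genomes
#'
#' Flags a contig as a putative contaminant when the fraction of its
#' canonical k-mers contained in any blocklist genome reaches \code{tau}.
#' This is a presence screen against known lab phage genomes, parameterized
#' by k-mer size and containment threshold.
#'
#' @param contigs named character vector or \code{DNAStringSet} of contig
#'   sequences.
#' @param blocklist named character vector or \code{DNAStringSet} of
#'   contaminant genomes (may be empty).
#' @param k k-mer size (>= 11).
#' @param tau containment threshold in (0, 1]; a contig is flagged when its
#'   maximal containment is \code{>= tau}.
#' @return data.frame \code{contig_id}, \code{max_containment},
#'   \code{contaminant}.
#' @export
screen_contaminants <- function(contigs, blocklist = character(0),
                                k = 21L, tau = 0.5) {
  if (k < 11L) stop("k must be >= 11")
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  ids <- names(contigs) %||% as.character(seq_along(contigs))
  contigs <- setNames(as.character(contigs), ids)
  blocklist <- as.character(blocklist)
  block_sets <- lapply(blocklist, kmer_set, k = k)
  containment <- vapply(contigs, function(s) {
    ks <- kmer_set(s, k = k)
    if (length(ks) == 0L) {
      warning("contig shorter than k; not flagged")
      return(0)
    }
    if (length(block_sets) == 0L) return(0)
    max(vapply(block_sets, function(b) sum(ks %in% b) / length(ks),
               numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(
    contig_id = ids,
    max_containment = containment,
    contaminant = containment >= tau & vapply(contigs, nchar, 0L,
                                              USE.NAMES = FALSE) >= k,
    stringsAsFactors = FALSE
  )
}
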