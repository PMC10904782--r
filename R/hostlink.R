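# Virus-host linkage from four evidence types (CRISPR spacer, tRNA,
# sequence similarity, nucleotide composition) and lineage-level
# virus/host abundance ratios.

as_dna <- function(x) {
  if (is(x, "DNAString")) x else Biostrings::DNAString(toupper(as.character(x)))
}

#' Match CRISPR spacers against a virus sequence
#'
#' A spacer links a host to the virus when the spacer (or its reverse
#' complement) occurs in the virus sequence with at most
#' \code{max_mismatch} substitutions. Spacers shorter than \code{min_len}
#' are not considered.
#'
#' @param virus virus sequence (character or \code{DNAString}).
#' @param spacers character vector (optionally named) of spacer sequences.
#' @param max_mismatch maximum substitutions allowed (default 1).
#' @param min_len minimum spacer length considered (default 25).
#' @return list with \code{match} (logical) and \code{matched} (names or
#'   indices of matching spacers).
#' @export
match_crispr <- function(virus, spacers, max_mismatch = 1L, min_len = 25L) {
  v <- as_dna(virus)
  spacers <- as.character(spacers)
  ids <- names(spacers) %||% as.character(seq_along(spacers))
  keep <- nchar(spacers) >= min_len
  hit <- vapply(which(keep), function(i) {
    p <- Biostrings::DNAString(toupper(spacers[i]))
    Biostrings::countPattern(p, v, max.mismatch = max_mismatch) > 0 ||
      Biostrings::countPattern(Biostrings::reverseComplement(p), v,
                               max.mismatch = max_mismatch) > 0
  }, logical(1))
  matched <- ids[which(keep)[hit]]
  list(match = length(matched) > 0, matched = matched)
}

#' Match host tRNA sequences against a virus sequence
#'
#' True when any tRNA of length >= 60 occurs exactly, full length, on
#' either strand of the virus.
#'
#' @param virus virus sequence.
#' @param trnas character vector of tRNA sequences.
#' @return logical.
#' @export
match_trna <- function(virus, trnas) {
  v <- as_dna(virus)
  trnas <- as.character(trnas)
  trnas <- trnas[nchar(trnas) >= 60]
  for (t in trnas) {
    p <- Biostrings::DNAString(toupper(t))
    if (Biostrings::countPattern(p, v) > 0 ||
        Biostrings::countPattern(Biostrings::reverseComplement(p), v) > 0)
      return(TRUE)
  }
  FALSE
}

#' k-mer containment of a virus in a host genome
#'
#' Fraction of the virus's distinct canonical k-mers that also occur in the
#' host genome.
#'
#' @param virus,mag sequences (character or \code{DNAString}); both at
#'   least \code{k} long.
#' @param k k-mer size (default 21).
#' @return fraction in [0, 1].
#' @export
similarity_score <- function(virus, mag, k = 21L) {
  vk <- kmer_set(virus, k)
  if (length(vk) == 0) stop("virus shorter than k")
  mk <- kmer_set(mag, k)
  sum(vk %in% mk) / length(vk)
}

#' Tetranucleotide composition distance between two sequences
#'
#' L1 distance between canonical (strand-collapsed) tetranucleotide
#' frequency vectors. Each sequence's 4-mer counts are pooled with the
#' counts of its reverse complement, then normalized to sum to 1; the
#' distance is the sum of absolute frequency differences (range 0–2).
#'
#' @param virus,mag sequences, each at least 4 bp (>= 5 kb recommended for
#'   stable estimates).
#' @return non-negative distance.
#' @export
composition_distance <- function(virus, mag) {
  tnf <- function(s) {
    d <- as_dna(s)
    f <- Biostrings::oligonucleotideFrequency(d, width = 4) +
      Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(d),
                                           width = 4)
    if (sum(f) == 0) stop("sequence too short for tetranucleotide profile")
    f / sum(f)
  }
  sum(abs(tnf(virus) - tnf(mag)))
}

#' Compute the four evidence types for every virus x MAG pair
#'
#' @param viruses named character vector (or \code{DNAStringSet}) of virus
#'   sequences.
#' @param mags list of MAG records; each element a list with
#'   \code{sequence}, \code{spacers} (character vector), \code{trnas}
#'   (character vector). Names are MAG ids.
#' @param k k-mer size for the similarity screen.
#' @param max_mismatch,min_spacer_len CRISPR matching parameters.
#' @return data.frame with one row per pair: \code{virus_id}, \code{mag_id},
#'   \code{crispr_match}, \code{trna_match}, \code{similarity_score},
#'   \code{composition_distance}.
#' @export
host_evidence <- function(viruses, mags, k = 21L, max_mismatch = 1L,
                          min_spacer_len = 25L) {
  vids <- names(viruses)
  mids <- names(mags)
  stopifnot(!is.null(vids), !is.null(mids))
  rows <- list()
  for (vid in vids) {
    vseq <- as.character(viruses[[vid]])
    for (mid in mids) {
      m <- mags[[mid]]
      rows[[length(rows) + 1L]] <- data.frame(
        virus_id = vid, mag_id = mid,
        crispr_match = match_crispr(vseq, m$spacers %||% character(0),
                                    max_mismatch, min_spacer_len)$match,
        trna_match = match_trna(vseq, m$trnas %||% character(0)),
        similarity_score = similarity_score(vseq, m$sequence, k),
        composition_distance = composition_distance(vseq, m$sequence),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Aggregate per-pair evidence into ranked host predictions
#'
#' Each evidence type contributes a fixed weight when it fires:
#' \code{aggregate = w_crispr*[crispr] + w_trna*[trna] +
#' w_sim*[similarity >= s_min] + w_comp*[composition <= d_max]}. Pairs with
#' aggregate at or above \code{threshold} are reported per virus,
#' best-first; ties are broken by smaller composition distance, then MAG id.
#'
#' @param evidence data.frame from \code{\link{host_evidence}}.
#' @param weights numeric vector \code{c(crispr, trna, similarity,
#'   composition)}; default \code{c(3, 2, 2, 1)}.
#' @param threshold minimum aggregate to report (default 3).
#' @param s_min similarity score needed for the similarity evidence to fire
#'   (default 0.5).
#' @param d_max maximum composition distance for the composition evidence
#'   (default 0.1).
#' @return data.frame of retained predictions with \code{aggregate} and
#'   per-virus \code{rank}.
#' @export
aggregate_predictions <- function(evidence, weights = c(3, 2, 2, 1),
                                  threshold = 3, s_min = 0.5, d_max = 0.1) {
  if (any(weights < 0)) stop("weights must be >= 0")
  agg <- weights[1] * evidence$crispr_match +
    weights[2] * evidence$trna_match +
    weights[3] * (evidence$similarity_score >= s_min) +
    weights[4] * (evidence$composition_distance <= d_max)
  ev <- cbind(evidence, aggregate = agg)
  ev <- ev[ev$aggregate >= threshold, , drop = FALSE]
  if (nrow(ev) == 0) {
    ev$rank <- integer(0)
    return(ev)
  }
  parts <- lapply(split(ev, ev$virus_id), function(g) {
    g <- g[order(-g$aggregate, g$composition_distance, g$mag_id), ,
           drop = FALSE]
    g$rank <- seq_len(nrow(g))
    g
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Lineage-specific virus/host abundance ratios
#'
#' For each lineage (e.g. phylum) and sample: the summed abundance of
#' vOTUs linked to hosts of that lineage divided by the summed abundance of
#' the lineage's MAGs. A lineage with zero host abundance in a sample is
#' flagged \code{undefined} rather than returning an infinite ratio.
#'
#' @param virus_abund virus x sample abundance matrix.
#' @param links data.frame \code{virus_id}, \code{mag_id} (best host per
#'   virus).
#' @param mag_abund MAG x sample abundance matrix.
#' @param mag_taxonomy data.frame with \code{mag_id} and the lineage column.
#' @param rank taxonomy column to aggregate at (default "phylum").
#' @return data.frame \code{lineage}, \code{sample_id}, \code{virus_abund},
#'   \code{host_abund}, \code{ratio}, \code{defined}.
#' @export
virus_host_ratio <- function(virus_abund, links, mag_abund, mag_taxonomy,
                             rank = "phylum") {
  if (!rank %in% names(mag_taxonomy))
    stop("taxonomy table lacks rank column: ", rank)
  lin_of_mag <- setNames(mag_taxonomy[[rank]], mag_taxonomy$mag_id)
  links <- links[links$mag_id %in% names(lin_of_mag), , drop = FALSE]
  links$lineage <- lin_of_mag[links$mag_id]
  lineages <- sort(unique(lin_of_mag))
  samples <- colnames(mag_abund)
  rows <- list()
  for (lin in lineages) {
    lin_mags <- names(lin_of_mag)[lin_of_mag == lin]
    lin_viruses <- unique(links$virus_id[links$lineage == lin])
    lin_mags <- intersect(lin_mags, rownames(mag_abund))
    lin_viruses <- intersect(lin_viruses, rownames(virus_abund))
    for (s in samples) {
      hab <- sum(mag_abund[lin_mags, s])
      vab <- if (length(lin_viruses) > 0) sum(virus_abund[lin_viruses, s]) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        lineage = lin, sample_id = s, virus_abund = vab, host_abund = hab,
        ratio = if (hab > 0) vab / hab else NA_real_,
        defined = hab > 0, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
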