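# Gene-level pN/pS from per-site variant tables with NG86-style
# fractional expected-site counting.

BASES <- c("A", "C", "G", "T")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

check_gene <- function(seq, gene_id = "gene") {
  seq <- toupper(as.character(seq))
  if (nchar(seq) %% 3 != 0)
    stop("gene ", gene_id, " length not divisible by 3")
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  clean <- !grepl("[^ACGT]", codons)
  aas <- rep(NA_character_, length(codons))
  aas[clean] <- vapply(codons[clean], translate_codon, character(1))
  internal_stop <- which(aas == "*")
  internal_stop <- internal_stop[internal_stop < length(codons)]
  if (length(internal_stop) > 0)
    warning("gene ", gene_id, " has internal stop codon(s) at codon ",
            paste(internal_stop, collapse = ", "))
  list(seq = seq, codons = codons, aas = aas)
}

#' Expected synonymous and nonsynonymous site counts of a coding gene
#'
#' NG86-style fractional site counting: for each codon, each of the nine
#' possible single-nucleotide changes is classified by translation;
#' position \code{i} of the codon contributes \code{syn_i/3} synonymous and
#' \code{(3-syn_i)/3} nonsynonymous sites. Changes creating a stop codon
#' count as nonsynonymous. Codons containing ambiguous bases contribute
#' one nonsynonymous site per position, with a warning. The two counts
#' always sum to the gene length.
#'
#' @param seq in-frame coding sequence, 5'->3', length divisible by 3.
#' @param gene_id label used in messages.
#' @return named numeric vector \code{c(N_sites, S_sites)}.
#' @export
#' @examples
#' expected_sites("TGG")  # Trp: N_sites 3, S_sites 0
expected_sites <- function(seq, gene_id = "gene") {
  g <- check_gene(seq, gene_id)
  n_sites <- 0
  s_sites <- 0
  for (ci in seq_along(g$codons)) {
    codon <- g$codons[ci]
    ref_aa <- g$aas[ci]
    if (is.na(ref_aa)) {
      warning("gene ", gene_id, " codon ", ci,
              " has ambiguous base(s); positions counted nonsynonymous")
      n_sites <- n_sites + 3
      next
    }
    for (p in 1:3) {
      syn <- 0L
      for (b in setdiff(BASES, substr(codon, p, p))) {
        mut <- codon
        substr(mut, p, p) <- b
        mut_aa <- translate_codon(mut)
        if (!is.na(mut_aa) && mut_aa != "*" && mut_aa == ref_aa)
          syn <- syn + 1L
      }
      s_sites <- s_sites + syn / 3
      n_sites <- n_sites + (3L - syn) / 3
    }
  }
  c(N_sites = n_sites, S_sites = s_sites)
}

#' Classify observed SNPs as synonymous or nonsynonymous
#'
#' Each SNP is applied alone to its codon against the reference background;
#' it is synonymous iff the translated amino acid is unchanged (a change to
#' or from a stop codon is nonsynonymous). Multiple alternate alleles at a
#' position are each counted once; exact duplicate records are collapsed.
#'
#' @param seq in-frame coding sequence.
#' @param snps data.frame with \code{position} (1-based within gene),
#'   \code{ref}, \code{alt}; \code{ref} must match the sequence.
#' @param gene_id label used in messages.
#' @return named integer vector \code{c(N_obs, S_obs)}.
#' @export
classify_snps <- function(seq, snps, gene_id = "gene") {
  g <- check_gene(seq, gene_id)
  if (is.null(snps) || nrow(snps) == 0)
    return(c(N_obs = 0L, S_obs = 0L))
  snps <- unique(snps[, c("position", "ref", "alt")])
  if (any(snps$position < 1 | snps$position > nchar(g$seq)))
    stop("SNP position outside gene ", gene_id)
  ref_at <- substring(g$seq, snps$position, snps$position)
  bad <- ref_at != toupper(snps$ref)
  if (any(bad))
    stop("ref allele mismatch in gene ", gene_id, " at position(s) ",
         paste(snps$position[bad], collapse = ", "))
  if (any(toupper(snps$alt) == toupper(snps$ref)))
    stop("alt equal to ref in gene ", gene_id)
  n_obs <- 0L
  s_obs <- 0L
  for (i in seq_len(nrow(snps))) {
    pos <- snps$position[i]
    ci <- (pos - 1L) %/% 3L + 1L
    codon <- g$codons[ci]
    off <- (pos - 1L) %% 3L + 1L
    mut <- codon
    substr(mut, off, off) <- toupper(snps$alt[i])
    ref_aa <- g$aas[ci]
    mut_aa <- translate_codon(mut)
    syn <- !is.na(ref_aa) && !is.na(mut_aa) && ref_aa != "*" &&
      mut_aa != "*" && ref_aa == mut_aa
    if (syn) s_obs <- s_obs + 1L else n_obs <- n_obs + 1L
  }
  c(N_obs = n_obs, S_obs = s_obs)
}

#' Gene-level pN/pS from a variant table
#'
#' \code{pN/pS = (N_obs/N_sites) / (S_obs/S_sites)}. Status is
#' \code{"defined"} when computable, \code{"zero_syn_undefined"} when there
#' are nonsynonymous but no synonymous SNPs (ratio unbounded),
#' \code{"no_snps"} when the gene carries no SNPs (the ratio is then NA),
#' and \code{"undefined_sites"} when an expected-site count is zero. A gene
#' with only synonymous SNPs has pN/pS = 0, the signature of strong
#' purifying selection.
#'
#' @inheritParams classify_snps
#' @return one-row data.frame: \code{gene_id}, \code{N_obs}, \code{S_obs},
#'   \code{N_sites}, \code{S_sites}, \code{pnps}, \code{status}.
#' @export
pnps <- function(seq, snps, gene_id = "gene") {
  sites <- expected_sites(seq, gene_id)
  obs <- classify_snps(seq, snps, gene_id)
  n_sites <- sites[["N_sites"]]; s_sites <- sites[["S_sites"]]
  n_obs <- obs[["N_obs"]]; s_obs <- obs[["S_obs"]]
  if (n_sites == 0 || s_sites == 0) {
    status <- "undefined_sites"; value <- NA_real_
  } else if (n_obs == 0 && s_obs == 0) {
    status <- "no_snps"; value <- NA_real_
  } else if (s_obs == 0) {
    status <- "zero_syn_undefined"; value <- NA_real_
  } else {
    status <- "defined"
    value <- (n_obs / n_sites) / (s_obs / s_sites)
  }
  data.frame(gene_id = gene_id, N_obs = n_obs, S_obs = s_obs,
             N_sites = n_sites, S_sites = s_sites, pnps = value,
             status = status, stringsAsFactors = FALSE)
}

#' pN/pS for many genes from a combined variant table
#'
#' @param genes named character vector of in-frame coding sequences.
#' @param variants data.frame with \code{gene_id}, \code{position},
#'   \code{ref}, \code{alt} (VCF-like: CHROM=gene_id, POS, REF, ALT).
#' @return data.frame with one row per gene (genes without variants get
#'   status \code{no_snps}).
#' @export
pnps_table <- function(genes, variants) {
  stopifnot(!is.null(names(genes)))
  unknown <- setdiff(unique(variants$gene_id), names(genes))
  if (length(unknown) > 0)
    stop("variants reference unknown genes: ", paste(unknown, collapse = ", "))
  out <- lapply(names(genes), function(gid) {
    snps <- variants[variants$gene_id == gid, , drop = FALSE]
    pnps(genes[[gid]], snps, gene_id = gid)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
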