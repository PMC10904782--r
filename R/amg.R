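# AMG curation: host-boundary trimming, genomic-context rules, KO/PFAM
# consistency, methane-metabolism module exclusivity, habitat association.

GENE_CATEGORIES <- c("hallmark", "phage", "cellular", "hypothetical",
                     "transposon", "amg_candidate")

#' Load a KO -> pathway-module map
#'
#' Reads a three-column TSV (\code{ko}, \code{module_id}, \code{is_mm}) into
#' the structure used by \code{\link{classify_mm}}. With no path, the
#' bundled minimal methane-metabolism snapshot is loaded (methanogenesis
#' from CO2 / acetate / methylamines, methane oxidation, coenzyme
#' F420-related synthesis, plus a few non-MM modules for shared KOs). The
#' bundled map is a small curated example; supply a full KEGG-derived table
#' for production use.
#'
#' @param path TSV path, or \code{NULL} for the bundled map.
#' @param ko_pfam_path optional TSV (\code{ko}, \code{pfam_acc}) giving the
#'   PFAM accessions consistent with each KO; defaults to the bundled
#'   cross-map.
#' @return list with \code{ko_to_modules} (named list of character vectors),
#'   \code{mm_modules} (character), \code{ko_to_pfams} (named list).
#' @export
load_pathway_map <- function(path = NULL, ko_pfam_path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "mm_pathway_map.tsv", package = "vamp",
                        mustWork = TRUE)
  if (is.null(ko_pfam_path))
    ko_pfam_path <- system.file("extdata", "ko_pfam_map.tsv",
                                package = "vamp", mustWork = TRUE)
  tab <- read_tsv_strict(path)
  stopifnot(all(c("ko", "module_id", "is_mm") %in% names(tab)))
  pf <- read_tsv_strict(ko_pfam_path)
  stopifnot(all(c("ko", "pfam_acc") %in% names(pf)))
  mm <- sort(unique(tab$module_id[as.logical(tab$is_mm)]))
  list(
    ko_to_modules = lapply(split(tab$module_id, tab$ko), unique),
    mm_modules = mm,
    ko_to_pfams = lapply(split(pf$pfam_acc, pf$ko), unique)
  )
}

validate_genes <- function(genes) {
  req <- c("contig_id", "gene_index", "start", "end", "strand", "category")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols) > 0)
    stop("gene table missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- !genes$category %in% GENE_CATEGORIES
  if (any(bad))
    stop("unknown gene categories: ",
         paste(unique(genes$category[bad]), collapse = ", "))
  if (any(genes$start > genes$end)) stop("gene with start > end")
  invisible(genes)
}

#' Trim putative host regions from the ends of a viral contig
#'
#' Emulates boundary assessment of host-virus chimeras: from each contig
#' end, the maximal terminal run of at least \code{min_run} genes that
#' contains no hallmark gene, ends (innermost) on a cellular gene, and
#' whose cellular-category fraction is at least \code{host_frac} is marked
#' host-like and trimmed. Interior genes are never trimmed.
#'
#' @param genes data.frame of one contig's genes ordered by
#'   \code{gene_index} (columns \code{gene_index}, \code{category} used).
#' @param min_run minimum terminal run length to trim (default 3).
#' @param host_frac minimum cellular-gene fraction of the run (default 0.7).
#' @return list with \code{contig_id}, \code{kept} (integer range of gene
#'   indices, or NULL if everything was trimmed), \code{trimmed_left},
#'   \code{trimmed_right}.
#' @export
trim_host_boundary <- function(genes, min_run = 3L, host_frac = 0.7) {
  validate_genes(genes)
  genes <- genes[order(genes$gene_index), , drop = FALSE]
  n <- nrow(genes)
  cat_ <- genes$category
  run_len <- function(cats) {
    # largest L >= min_run such that cats[1:L] has no hallmark, cellular
    # fraction >= host_frac, and the innermost gene is cellular (the trim
    # stops at the last cellular gene); cats given outermost-first
    best <- 0L
    for (L in seq_along(cats)) {
      if (cats[L] == "hallmark") break
      if (L >= min_run && cats[L] == "cellular" &&
          mean(cats[seq_len(L)] == "cellular") >= host_frac)
        best <- L
    }
    best
  }
  left <- run_len(cat_)
  right <- run_len(rev(cat_))
  if (left + right >= n) {
    kept <- NULL   # whole contig host-like
  } else {
    kept <- c(genes$gene_index[left + 1L], genes$gene_index[n - right])
  }
  list(contig_id = genes$contig_id[1], kept = kept,
       trimmed_left = left, trimmed_right = right)
}

#' Curate one AMG candidate against its genomic context
#'
#' Accumulates rejection reasons independently; the candidate is accepted
#' only with an empty reason set. Reasons:
#' \describe{
#'   \item{not_flanked}{no phage or hallmark gene within \code{window}
#'     genes on each side, or the candidate is the first/last gene of the
#'     kept (non-host) interval.}
#'   \item{transposon_context}{a transposon-category gene within the window
#'     on either side.}
#'   \item{no_ko}{no KEGG KO assigned.}
#'   \item{annotation_inconsistent}{KO present but PFAM accession absent or
#'     not among the PFAMs consistent with that KO.}
#'   \item{in_host_region}{candidate lies outside the kept interval of the
#'     boundary trim.}
#' }
#'
#' @param candidate_index gene_index of the candidate (category must be
#'   \code{amg_candidate}).
#' @param genes data.frame of all genes on the candidate's contig.
#' @param trim result of \code{\link{trim_host_boundary}} for the contig.
#' @param pathway_map as from \code{\link{load_pathway_map}}.
#' @param window flanking window in genes on each side (default 5).
#' @return data.frame row: \code{contig_id}, \code{gene_index},
#'   \code{kegg_ko}, \code{status}, \code{rejection_reasons} (comma-joined),
#'   \code{mm_class}.
#' @export
curate_amg <- function(candidate_index, genes, trim, pathway_map,
                       window = 5L) {
  validate_genes(genes)
  genes <- genes[order(genes$gene_index), , drop = FALSE]
  pos <- match(candidate_index, genes$gene_index)
  if (is.na(pos)) stop("candidate gene_index ", candidate_index,
                       " not found on contig")
  if (genes$category[pos] != "amg_candidate")
    stop("gene ", candidate_index, " is not an amg_candidate")
  n <- nrow(genes)
  reasons <- character(0)

  viral_like <- genes$category %in% c("phage", "hallmark")
  left_win <- seq(max(1L, pos - window), length.out = min(window, pos - 1L))
  right_win <- seq(pos + 1L, length.out = min(window, n - pos))
  flanked <- length(left_win) > 0 && any(viral_like[left_win]) &&
    length(right_win) > 0 && any(viral_like[right_win])

  kept <- trim$kept
  in_kept <- !is.null(kept) &&
    candidate_index >= kept[1] && candidate_index <= kept[2]
  if (!in_kept) reasons <- c(reasons, "in_host_region")
  kept_edge <- in_kept &&
    (candidate_index == kept[1] || candidate_index == kept[2])
  if (!flanked || kept_edge) reasons <- c(reasons, "not_flanked")

  if (any(genes$category[c(left_win, right_win)] == "transposon"))
    reasons <- c(reasons, "transposon_context")

  ko <- genes$kegg_ko[pos] %||% NA_character_
  pfam <- genes$pfam_acc[pos] %||% NA_character_
  if (is.na(ko) || ko == "") {
    reasons <- c(reasons, "no_ko")
    ko <- NA_character_
  } else {
    allowed <- pathway_map$ko_to_pfams[[ko]]
    if (is.na(pfam) || pfam == "" || is.null(allowed) || !pfam %in% allowed)
      reasons <- c(reasons, "annotation_inconsistent")
  }

  reasons <- sort(unique(reasons))
  mm_class <- if (is.na(ko)) "non_mm" else classify_mm(ko, pathway_map)
  data.frame(
    contig_id = genes$contig_id[1],
    gene_index = candidate_index,
    kegg_ko = ko,
    status = if (length(reasons) == 0) "accepted" else "rejected",
    rejection_reasons = paste(reasons, collapse = ","),
    mm_class = mm_class,
    stringsAsFactors = FALSE
  )
}

#' Curate all AMG candidates in a gene-annotation table
#'
#' Runs \code{\link{trim_host_boundary}} per contig and
#' \code{\link{curate_amg}} for every \code{amg_candidate} gene.
#'
#' @param genes data.frame of gene annotations across contigs.
#' @param pathway_map as from \code{\link{load_pathway_map}}.
#' @param window flanking window (default 5).
#' @param min_run,host_frac boundary-trim parameters.
#' @return data.frame of AMG calls (possibly zero rows).
#' @export
curate_all_amgs <- function(genes, pathway_map, window = 5L,
                            min_run = 3L, host_frac = 0.7) {
  validate_genes(genes)
  out <- lapply(split(genes, genes$contig_id), function(g) {
    cand <- g$gene_index[g$category == "amg_candidate"]
    if (length(cand) == 0) return(NULL)
    trim <- trim_host_boundary(g, min_run = min_run, host_frac = host_frac)
    do.call(rbind, lapply(cand, curate_amg, genes = g, trim = trim,
                          pathway_map = pathway_map, window = window))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(contig_id = character(0), gene_index = integer(0),
                      kegg_ko = character(0), status = character(0),
                      rejection_reasons = character(0),
                      mm_class = character(0))
  rownames(out) <- NULL
  out
}

#' Classify a KO's methane-metabolism pathway exclusivity
#'
#' \code{exclusive_mm} when every module the KO belongs to is a
#' methane-metabolism module; \code{shared_mm} when it belongs to MM and
#' non-MM modules; \code{non_mm} otherwise (including KOs absent from the
#' map, with a warning).
#'
#' @param ko KEGG KO accession (e.g. "K00577").
#' @param pathway_map as from \code{\link{load_pathway_map}}.
#' @return one of \code{"exclusive_mm"}, \code{"shared_mm"}, \code{"non_mm"}.
#' @export
classify_mm <- function(ko, pathway_map) {
  mods <- pathway_map$ko_to_modules[[ko]]
  if (is.null(mods) || length(mods) == 0) {
    warning("KO not in pathway map: ", ko)
    return("non_mm")
  }
  in_mm <- mods %in% pathway_map$mm_modules
  if (all(in_mm)) "exclusive_mm"
  else if (any(in_mm)) "shared_mm"
  else "non_mm"
}

#' Habitat association of accepted methane-metabolism AMGs
#'
#' Builds the distinct-AMG (by KO) x habitat count matrix over accepted
#' MM AMG calls and summarizes habitat breadth: how many distinct AMGs each
#' habitat carries and how many KOs occur in exactly one vs several
#' habitats.
#'
#' @param amg_calls data.frame from \code{\link{curate_all_amgs}}.
#' @param contig_habitats named character vector mapping contig_id to
#'   habitat label; every contig with an accepted MM call must be present.
#' @return list with \code{matrix} (KO x habitat counts of carrying
#'   contigs), \code{amgs_per_habitat}, \code{n_single_habitat},
#'   \code{n_multi_habitat}, \code{breadth} (named per-KO habitat counts).
#' @export
habitat_association <- function(amg_calls, contig_habitats) {
  acc <- amg_calls[amg_calls$status == "accepted" &
                     amg_calls$mm_class %in% c("exclusive_mm", "shared_mm"), ,
                   drop = FALSE]
  if (nrow(acc) == 0) {
    return(list(matrix = matrix(0, 0, 0), amgs_per_habitat = integer(0),
                n_single_habitat = 0L, n_multi_habitat = 0L,
                breadth = integer(0)))
  }
  missing_h <- setdiff(unique(acc$contig_id), names(contig_habitats))
  if (length(missing_h) > 0)
    stop("contigs without habitat label: ", paste(missing_h, collapse = ", "))
  hab <- contig_habitats[acc$contig_id]
  kos <- sort(unique(acc$kegg_ko))
  habs <- sort(unique(hab))
  m <- matrix(0L, length(kos), length(habs), dimnames = list(kos, habs))
  for (i in seq_len(nrow(acc))) {
    m[acc$kegg_ko[i], hab[i]] <- m[acc$kegg_ko[i], hab[i]] + 1L
  }
  breadth <- rowSums(m > 0)
  list(
    matrix = m,
    amgs_per_habitat = colSums(m > 0),
    n_single_habitat = sum(breadth == 1L),
    n_multi_habitat = sum(breadth > 1L),
    breadth = breadth
  )
}
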