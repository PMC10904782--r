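# vOTU clustering: merge local-alignment fragments into pairwise ANI /
# aligned-fraction estimates, threshold edges, greedy centroid clustering.

#' Merge alignment fragments for one contig pair into an ANI estimate
#'
#' Fragments are sorted by query start; bases covered by an earlier fragment
#' are trimmed from later ones so every query base is counted once. ANI is
#' the length-weighted mean identity over the trimmed fragments. Aligned
#' fractions are the merged covered bases divided by contig length, computed
#' independently on query and target coordinates.
#'
#' @param fragments data.frame with columns \code{q_start}, \code{q_end},
#'   \code{t_start}, \code{t_end} (1-based inclusive; target interval may be
#'   given on either strand) and \code{percent_identity} (0–100), all rows
#'   for the same ordered (query, target) pair.
#' @param len_q,len_t contig lengths in bp.
#' @return list with \code{ani} (percent), \code{af_q}, \code{af_t}; or
#'   \code{NULL} when \code{fragments} has no rows (no edge).
#' @export
#' @examples
#' fr <- data.frame(q_start = c(1, 401), q_end = c(400, 1000),
#'                  t_start = c(1, 401), t_end = c(400, 1000),
#'                  percent_identity = c(98, 93))
#' merge_fragments(fr, 1000, 1000)  # ani 95, af 1
merge_fragments <- function(fragments, len_q, len_t) {
  if (is.null(fragments) || nrow(fragments) == 0L) return(NULL)
  stopifnot(all(fragments$q_start <= fragments$q_end),
            all(fragments$q_end <= len_q))
  ord <- order(fragments$q_start, fragments$q_end)
  fragments <- fragments[ord, , drop = FALSE]
  covered_end <- 0L
  total_len <- 0
  weighted_id <- 0
  for (i in seq_len(nrow(fragments))) {
    s <- max(fragments$q_start[i], covered_end + 1L)
    e <- fragments$q_end[i]
    if (s <= e) {
      len <- e - s + 1L
      total_len <- total_len + len
      weighted_id <- weighted_id + len * fragments$percent_identity[i]
      covered_end <- max(covered_end, e)
    } else {
      covered_end <- max(covered_end, e)
    }
  }
  if (total_len == 0) return(NULL)
  t_lo <- pmin(fragments$t_start, fragments$t_end)
  t_hi <- pmax(fragments$t_start, fragments$t_end)
  t_cov <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(t_lo, t_hi))))
  q_cov <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(fragments$q_start, fragments$q_end))))
  list(ani = weighted_id / total_len,
       af_q = q_cov / len_q,
       af_t = min(1, t_cov / len_t))
}

#' Compute pairwise ANI records from a BLAST-like fragment table
#'
#' Groups a tabular fragment set (outfmt-6 style) by unordered contig pair
#' and merges each group with \code{\link{merge_fragments}}. Fragments of a
#' contig against itself are ignored.
#'
#' @param fragments data.frame with columns \code{query_id}, \code{target_id},
#'   \code{q_start}, \code{q_end}, \code{t_start}, \code{t_end},
#'   \code{percent_identity}.
#' @param lengths named numeric vector of contig lengths.
#' @return data.frame \code{a}, \code{b}, \code{ani}, \code{af_a},
#'   \code{af_b} with one row per unordered pair seen in the table.
#' @export
pairwise_ani <- function(fragments, lengths) {
  fragments <- fragments[fragments$query_id != fragments$target_id, ,
                         drop = FALSE]
  if (nrow(fragments) == 0L)
    return(data.frame(a = character(0), b = character(0), ani = numeric(0),
                      af_a = numeric(0), af_b = numeric(0)))
  unknown <- setdiff(unique(c(fragments$query_id, fragments$target_id)),
                     names(lengths))
  if (length(unknown) > 0)
    stop("fragment table references contigs without lengths: ",
         paste(unknown, collapse = ", "))
  a <- pmin(fragments$query_id, fragments$target_id)
  b <- pmax(fragments$query_id, fragments$target_id)
  key <- paste(a, b, sep = "\r")
  groups <- split(seq_len(nrow(fragments)), key)
  rows <- lapply(groups, function(idx) {
    fr <- fragments[idx, , drop = FALSE]
    qa <- fr$query_id[1]; tb <- fr$target_id[1]
    # orient all fragments so 'query' side is the lexicographically smaller id
    flip <- fr$query_id != min(qa, tb)
    if (any(flip)) {
      fr[flip, c("q_start", "q_end", "t_start", "t_end")] <-
        fr[flip, c("t_start", "t_end", "q_start", "q_end")]
      # flipped target coords may be reverse-strand; normalize query interval
      qs <- pmin(fr$q_start, fr$q_end); qe <- pmax(fr$q_start, fr$q_end)
      fr$q_start <- qs; fr$q_end <- qe
    }
    id_a <- min(qa, tb); id_b <- max(qa, tb)
    m <- merge_fragments(fr, lengths[[id_a]], lengths[[id_b]])
    if (is.null(m)) return(NULL)
    data.frame(a = id_a, b = id_b, ani = m$ani, af_a = m$af_q,
               af_b = m$af_t, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Threshold pairwise ANI records into cluster edges
#'
#' An edge joins two contigs when their merged-fragment ANI is at least
#' \code{min_ani} percent and the aligned fraction on the shorter contig
#' (the larger of the two per-contig fractions) is at least \code{min_af}.
#' Self-pairs are implicit edges and need not be listed.
#'
#' @param anis data.frame as returned by \code{\link{pairwise_ani}}.
#' @param min_ani ANI threshold in percent (default 95).
#' @param min_af aligned-fraction threshold (default 0.80).
#' @return data.frame \code{a}, \code{b} of retained edges.
#' @export
build_edges <- function(anis, min_ani = 95, min_af = 0.80) {
  if (is.null(anis) || nrow(anis) == 0L)
    return(data.frame(a = character(0), b = character(0)))
  keep <- anis$ani >= min_ani & pmax(anis$af_a, anis$af_b) >= min_af
  out <- anis[keep, c("a", "b"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy centroid clustering of viral contigs into vOTUs
#'
#' Contigs are processed longest-first (ties broken by contig id); each
#' becomes a new centroid unless it has an edge to an existing centroid, in
#' which case it joins the earliest-created (longest) such centroid. The
#' longest member is the representative seed of each vOTU.
#'
#' @param lengths named numeric vector of contig lengths (all contigs to
#'   cluster, including those without edges).
#' @param edges data.frame \code{a}, \code{b} of symmetric similarity edges.
#' @param method \code{"greedy"} (default, centroid rule) or
#'   \code{"single"} (single-linkage connected components, for sensitivity
#'   analysis).
#' @return data.frame \code{representative_id}, \code{member_ids}
#'   (comma-joined, representative first), \code{n_members}.
#' @export
greedy_cluster <- function(lengths, edges, method = c("greedy", "single")) {
  method <- match.arg(method)
  ids <- names(lengths)
  if (is.null(ids) || any(ids == ""))
    stop("lengths must be a fully named vector")
  ord <- order(-as.numeric(lengths), ids)
  ids_ord <- ids[ord]
  edge_key <- character(0)
  if (!is.null(edges) && nrow(edges) > 0)
    edge_key <- c(paste(edges$a, edges$b, sep = "\r"),
                  paste(edges$b, edges$a, sep = "\r"))

  if (method == "single") {
    # union-find over edges
    parent <- setNames(ids_ord, ids_ord)
    findp <- function(x) {
      while (parent[[x]] != x) {
        parent[[x]] <<- parent[[parent[[x]]]]
        x <- parent[[x]]
      }
      x
    }
    if (length(edge_key) > 0) {
      for (i in seq_len(nrow(edges))) {
        ra <- findp(edges$a[i]); rb <- findp(edges$b[i])
        if (ra != rb) parent[[rb]] <- ra
      }
    }
    comp <- vapply(ids_ord, findp, character(1))
    members_by <- split(ids_ord, comp)
  } else {
    centroids <- character(0)
    membership <- setNames(character(length(ids_ord)), ids_ord)
    for (cid in ids_ord) {
      hit <- NA_character_
      for (ct in centroids) {
        if (paste(cid, ct, sep = "\r") %in% edge_key) { hit <- ct; break }
      }
      if (is.na(hit)) {
        centroids <- c(centroids, cid)
        membership[[cid]] <- cid
      } else {
        membership[[cid]] <- hit
      }
    }
    members_by <- split(names(membership), membership)
  }

  clusters <- lapply(members_by, function(mem) {
    mem <- mem[order(-as.numeric(lengths[mem]), mem)]
    data.frame(representative_id = mem[1],
               member_ids = paste(mem, collapse = ","),
               n_members = length(mem), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, clusters)
  out <- out[order(out$representative_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster viral contigs into vOTUs from a fragment table
#'
#' Convenience wrapper: \code{\link{pairwise_ani}} then
#' \code{\link{build_edges}} then \code{\link{greedy_cluster}}.
#'
#' @inheritParams pairwise_ani
#' @inheritParams build_edges
#' @inheritParams greedy_cluster
#' @return as \code{\link{greedy_cluster}}.
#' @export
cluster_votus <- function(fragments, lengths, min_ani = 95, min_af = 0.80,
                          method = "greedy") {
  anis <- pairwise_ani(fragments, lengths)
  edges <- build_edges(anis, min_ani = min_ani, min_af = min_af)
  greedy_cluster(lengths, edges, method = method)
}
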