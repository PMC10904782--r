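# End-to-end orchestration: screen -> cluster -> ecology -> amg ->
# hostlink -> pnps over an in-memory or on-disk bundle, with a run
# manifest of counts and output checksums.

#' Default stage parameters for \code{\link{run_pipeline}}
#'
#' @return named list of all tunable stage parameters: virus-call
#'   thresholds, contaminant screen (\code{k}, \code{tau}), clustering
#'   (\code{min_ani}, \code{min_af}), AMG curation (\code{window},
#'   \code{min_run}, \code{host_frac}), host linkage (\code{weights},
#'   \code{threshold}, \code{s_min}, \code{d_max}, \code{max_mismatch},
#'   \code{min_spacer_len}), and PERMANOVA (\code{n_permutations},
#'   \code{seed}).
#' @export
pipeline_params <- function() {
  list(
    thresholds = virus_call_thresholds(),
    screen = list(k = 21L, tau = 0.5),
    cluster = list(min_ani = 95, min_af = 0.80),
    amg = list(window = 5L, min_run = 3L, host_frac = 0.7),
    hostlink = list(weights = c(3, 2, 2, 1), threshold = 3, s_min = 0.5,
                    d_max = 0.1, k = 21L, max_mismatch = 1L,
                    min_spacer_len = 25L),
    permanova = list(n_permutations = 999L, seed = 1L)
  )
}

#' Validate a pipeline configuration / bundle
#'
#' Report-only check: lists missing components, out-of-range parameters
#' and absent seeds without stopping.
#'
#' @param bundle a \code{vamp_bundle} (or the list returned by
#'   \code{\link{read_bundle}}).
#' @param params stage parameters, see \code{\link{pipeline_params}}.
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(bundle, params = pipeline_params()) {
  problems <- character(0)
  need <- c("contigs", "genes", "scores", "fragments", "depths", "samples",
            "mags", "variants", "truth")
  missing_parts <- setdiff(need, names(bundle))
  if (length(missing_parts) > 0)
    problems <- c(problems,
                  paste0("missing bundle component: ", missing_parts))
  pr <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || any(x < lo | x > hi))
      paste0("parameter out of range: ", nm) else character(0)
  }
  problems <- c(problems,
                pr(params$cluster$min_af, 0, 1, "cluster$min_af"),
                pr(params$cluster$min_ani, 0, 100, "cluster$min_ani"),
                pr(params$screen$tau, 1e-9, 1, "screen$tau"),
                pr(params$amg$host_frac, 0, 1, "amg$host_frac"))
  if (is.null(params$permanova$seed))
    problems <- c(problems, "absent seed: permanova$seed")
  problems
}

#' Run the full inference chain over a community bundle
#'
#' Executes virus calling and contaminant screening, vOTU clustering,
#' abundance normalization and community tests, AMG curation with
#' MM-exclusivity and habitat association, virus-host linkage with lineage
#' abundance ratios, and per-gene pN/pS, in that order. Any stage whose
#' precomputed output is supplied via \code{precomputed} is skipped and
#' the supplied table used instead, so external tool outputs can be
#' substituted for the synthetic ones.
#'
#' @param bundle a \code{vamp_bundle} or \code{\link{read_bundle}} result.
#' @param params stage parameters, see \code{\link{pipeline_params}}.
#' @param precomputed optional named list of stage outputs to reuse
#'   (currently supported: \code{clusters}).
#' @return list of class \code{vamp_run}: per-stage outputs
#'   (\code{virus_calls}, \code{contaminants}, \code{clusters},
#'   \code{abundance}, \code{ecology}, \code{amg_calls}, \code{habitat},
#'   \code{host_evidence}, \code{host_predictions}, \code{host_links},
#'   \code{ratios}, \code{pnps}) and a \code{manifest} of counts.
#' @export
run_pipeline <- function(bundle, params = pipeline_params(),
                         precomputed = list()) {
  problems <- validate_config(bundle, params)
  if (length(problems) > 0)
    stop("invalid pipeline input:\n  ", paste(problems, collapse = "\n  "))

  ## stage 1: virus calling + contaminant screen
  calls <- classify_virus(bundle$scores, params$thresholds)
  contam <- screen_contaminants(bundle$contigs, bundle$blocklist,
                                k = params$screen$k, tau = params$screen$tau)
  calls$contaminant <- contam$contaminant[match(calls$contig_id,
                                                contam$contig_id)]
  virus_ids <- calls$contig_id[calls$is_virus & calls$eligible &
                                 !calls$contaminant]

  ## stage 2: vOTU clustering of retained viral contigs
  lengths <- setNames(nchar(bundle$contigs), names(bundle$contigs))
  lengths <- lengths[virus_ids]
  if (!is.null(precomputed$clusters)) {
    clusters <- precomputed$clusters
  } else {
    frag <- bundle$fragments
    frag <- frag[frag$query_id %in% virus_ids &
                   frag$target_id %in% virus_ids, , drop = FALSE]
    clusters <- cluster_votus(frag, lengths,
                              min_ani = params$cluster$min_ani,
                              min_af = params$cluster$min_af)
  }
  reps <- clusters$representative_id

  ## stage 3: abundance + ecology
  lib <- setNames(bundle$samples$library_bases, bundle$samples$sample_id)
  abundance <- normalize_coverage(bundle$depths, lib)
  eco <- NULL
  # samples with no observed feature carry no community signal; ecology
  # statistics are computed over the informative samples
  nonempty <- colSums(abundance) > 0
  ab_eco <- abundance[, nonempty, drop = FALSE]
  if (nrow(ab_eco) > 1 && ncol(ab_eco) > 1) {
    d <- bray_curtis(ab_eco)
    eco <- list(distance = d, pcoa = pcoa(d))
    site <- bundle$samples$site[match(colnames(ab_eco),
                                      bundle$samples$sample_id)]
    if (length(unique(site)) > 1) {
      eco$permanova_site <- permanova(
        d, site, n_permutations = params$permanova$n_permutations,
        seed = params$permanova$seed)
      eco$presence_site <- partition_presence(ab_eco, site)
    }
  }

  ## stage 4: AMG curation on retained viral contigs
  pathway_map <- load_pathway_map()
  vir_genes <- bundle$genes[bundle$genes$contig_id %in% virus_ids, ,
                            drop = FALSE]
  amg_calls <- curate_all_amgs(vir_genes, pathway_map,
                               window = params$amg$window,
                               min_run = params$amg$min_run,
                               host_frac = params$amg$host_frac)
  habitat <- NULL
  if (nrow(amg_calls) > 0 && length(bundle$habitats) > 0)
    habitat <- habitat_association(amg_calls, bundle$habitats)

  ## stage 5: host linkage on vOTU representatives
  host_ev <- NULL; host_pred <- NULL; links <- NULL; ratios <- NULL
  if (length(reps) > 0 && nrow(bundle$mags$taxonomy) > 0) {
    mags <- lapply(bundle$mags$taxonomy$mag_id, function(m) {
      list(sequence = bundle$mags$sequences[[m]],
           spacers = bundle$mags$spacers[[m]],
           trnas = bundle$mags$trnas[[m]])
    })
    names(mags) <- bundle$mags$taxonomy$mag_id
    hp <- params$hostlink
    host_ev <- host_evidence(bundle$contigs[reps], mags, k = hp$k,
                             max_mismatch = hp$max_mismatch,
                             min_spacer_len = hp$min_spacer_len)
    host_pred <- aggregate_predictions(host_ev, weights = hp$weights,
                                       threshold = hp$threshold,
                                       s_min = hp$s_min, d_max = hp$d_max)
    links <- host_pred[host_pred$rank == 1L, c("virus_id", "mag_id"),
                       drop = FALSE]
    if (nrow(abundance) > 0 && nrow(links) > 0)
      ratios <- virus_host_ratio(abundance, links, bundle$mags$abundance,
                                 bundle$mags$taxonomy, rank = "phylum")
  }

  ## stage 6: pN/pS on genes carrying variants
  pnps_res <- NULL
  if (nrow(bundle$variants) > 0) {
    gid_tab <- bundle$genes
    gid_tab$gene_id <- gene_id_of(gid_tab$contig_id, gid_tab$gene_index)
    wanted <- unique(bundle$variants$gene_id)
    gid_tab <- gid_tab[gid_tab$gene_id %in% wanted, , drop = FALSE]
    gene_seqs <- setNames(vapply(seq_len(nrow(gid_tab)), function(i) {
      extract_gene_seq(bundle$contigs, gid_tab[i, ])
    }, character(1)), gid_tab$gene_id)
    pnps_res <- pnps_table(gene_seqs, bundle$variants)
  }

  manifest <- list(
    n_contigs_in = length(bundle$contigs),
    n_viruses_called = sum(calls$is_virus),
    n_contaminants = sum(calls$contaminant),
    n_retained = length(virus_ids),
    n_votus = nrow(clusters),
    n_amg_candidates = nrow(amg_calls),
    n_amg_accepted = sum(amg_calls$status == "accepted"),
    n_host_links = if (is.null(links)) 0L else nrow(links),
    n_pnps_genes = if (is.null(pnps_res)) 0L else nrow(pnps_res)
  )

  structure(list(
    virus_calls = calls, contaminants = contam, clusters = clusters,
    abundance = abundance, ecology = eco, amg_calls = amg_calls,
    habitat = habitat, host_evidence = host_ev,
    host_predictions = host_pred, host_links = links, ratios = ratios,
    pnps = pnps_res, manifest = manifest, params = params
  ), class = "vamp_run")
}

#' @export
print.vamp_run <- function(x, ...) {
  cat("vamp pipeline run\n")
  m <- x$manifest
  cat(sprintf("  contigs in:        %d\n", m$n_contigs_in))
  cat(sprintf("  viruses called:    %d (%d contaminant)\n",
              m$n_viruses_called, m$n_contaminants))
  cat(sprintf("  retained viruses:  %d -> %d vOTUs\n",
              m$n_retained, m$n_votus))
  cat(sprintf("  AMG candidates:    %d (%d accepted)\n",
              m$n_amg_candidates, m$n_amg_accepted))
  cat(sprintf("  host links:        %d\n", m$n_host_links))
  cat(sprintf("  pN/pS genes:       %d\n", m$n_pnps_genes))
  invisible(x)
}

#' Write the tabular outputs of a pipeline run to a directory
#'
#' @param run a \code{vamp_run}.
#' @param dir target directory.
#' @return invisibly, named md5 checksums of the written files.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv_plain(run$virus_calls, p("virus_calls.tsv"))
  write_tsv_plain(run$clusters, p("votu_clusters.tsv"))
  ab <- data.frame(feature_id = rownames(run$abundance), run$abundance,
                   check.names = FALSE)
  write_tsv_plain(ab, p("abundance.tsv"))
  write_tsv_plain(run$amg_calls, p("amg_calls.tsv"))
  if (!is.null(run$host_predictions))
    write_tsv_plain(run$host_predictions, p("host_predictions.tsv"))
  if (!is.null(run$ratios))
    write_tsv_plain(run$ratios, p("virus_host_ratios.tsv"))
  if (!is.null(run$pnps))
    write_tsv_plain(run$pnps, p("pnps.tsv"))
  files <- setdiff(sort(list.files(dir)), "manifest.txt")
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- setNames(unname(sums), files)
  counts <- vapply(run$manifest, as.character, character(1))
  writeLines(c(paste0(files, ": ", manifest),
               paste0(names(counts), ": ", counts)),
             p("manifest.txt"))
  invisible(manifest)
}
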