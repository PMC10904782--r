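# Synthetic community generator: sequences and every downstream table with
# planted ground truth, so the full inference chain is testable end-to-end.

AMG_CONTEXTS <- c("flanked", "terminal", "transposon", "inconsistent",
                  "host_region", "no_ko")

NONSTOP_CODONS <- local({
  all3 <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0), c("A", "C", "G", "T"), paste0))
  all3[Biostrings::GENETIC_CODE[all3] != "*"]
})

SYNTH_PHYLA <- data.frame(
  domain = c("d__Archaea", "d__Bacteria", "d__Archaea", "d__Archaea",
             "d__Bacteria", "d__Bacteria"),
  phylum = c("Thermoproteota", "Chloroflexota", "Halobacteriota",
             "Methanobacteriota", "Desulfobacterota", "Proteobacteria"),
  stringsAsFactors = FALSE
)

#' Configuration of a synthetic community
#'
#' All knobs of the generator in one validated object. The defaults emulate
#' the study design the pipeline targets: two sediment coring sites sampled
#' at 50, 100 and 225 cm, each yielding a bulk metagenome and a virome
#' (12 samples), with library sizes drawn log-uniformly over a realistic
#' range of sequenced bases so coverage-per-gigabase normalization is
#' exercised with unequal libraries.
#'
#' @param seed integer; fixing it makes the generated bundle byte-identical
#'   across runs.
#' @param n_mags number of host MAGs.
#' @param n_viral_contigs number of true viral contigs (cluster-family
#'   members included).
#' @param n_decoy_contigs number of non-viral decoy contigs.
#' @param n_contaminants number of viral contigs copied from the
#'   contaminant blocklist genome (flagged by the contaminant screen).
#' @param habitats habitat labels assigned round-robin to viral contigs.
#' @param planted_amgs data.frame with columns \code{ko} and \code{context}
#'   (one of \code{flanked}, \code{terminal}, \code{transposon},
#'   \code{inconsistent}, \code{host_region}, \code{no_ko}); each row
#'   plants one AMG candidate on its own viral contig.
#' @param cluster_families data.frame with columns \code{size} and
#'   \code{divergence}; each row builds one family by copying a parent
#'   contig with per-site substitution at the given rate (no indels, so
#'   true ANI is analytic).
#' @param samples data.frame \code{sample_id}, \code{site}, \code{depth_cm},
#'   \code{type} (bulk/virome); library sizes are drawn at generation time.
#' @param library_base_range range (bases) for log-uniform library sizes.
#' @param snv_per_amg list \code{n_syn}, \code{n_nonsyn}: SNPs planted on
#'   each accepted (context \code{flanked}) AMG gene.
#' @param noise list \code{score_jitter} (sd of Gaussian jitter on
#'   predictor scores) and \code{annotation_dropout} (probability of
#'   erasing a gene's KO/PFAM), both in [0, 1].
#' @param shared_site_prob probability a vOTU occurs at both sites.
#' @param all_depth_prob probability a vOTU occurs at all three depths.
#' @param virome_prob probability a bulk-detected vOTU is also seen in the
#'   virome fraction.
#' @return validated list of class \code{vamp_config}.
#' @export
community_config <- function(seed = 1L,
                             n_mags = 6L,
                             n_viral_contigs = 20L,
                             n_decoy_contigs = 10L,
                             n_contaminants = 1L,
                             habitats = c("lake_sediment", "lake_water",
                                          "marine_water", "marine_sediment"),
                             planted_amgs = default_planted_amgs(),
                             cluster_families = data.frame(
                               size = c(4L, 2L), divergence = c(0.01, 0.02)),
                             samples = default_samples(),
                             library_base_range = c(3e9, 1.5e10),
                             snv_per_amg = list(n_syn = 4L, n_nonsyn = 1L),
                             noise = list(score_jitter = 0,
                                          annotation_dropout = 0),
                             shared_site_prob = 0.05,
                             all_depth_prob = 0.06,
                             virome_prob = 0.15) {
  cfg <- list(seed = as.integer(seed), n_mags = as.integer(n_mags),
              n_viral_contigs = as.integer(n_viral_contigs),
              n_decoy_contigs = as.integer(n_decoy_contigs),
              n_contaminants = as.integer(n_contaminants),
              habitats = habitats, planted_amgs = planted_amgs,
              cluster_families = cluster_families, samples = samples,
              library_base_range = library_base_range,
              snv_per_amg = snv_per_amg, noise = noise,
              shared_site_prob = shared_site_prob,
              all_depth_prob = all_depth_prob, virome_prob = virome_prob)
  validate_community_config(cfg)
  class(cfg) <- "vamp_config"
  cfg
}

validate_community_config <- function(cfg) {
  if (cfg$n_mags < 0 || cfg$n_viral_contigs < 0 || cfg$n_decoy_contigs < 0 ||
      cfg$n_contaminants < 0)
    stop("counts must be >= 0")
  rates <- c(cfg$noise$score_jitter, cfg$noise$annotation_dropout,
             cfg$shared_site_prob, cfg$all_depth_prob, cfg$virome_prob)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (nrow(cfg$planted_amgs) > 0) {
    bad <- !cfg$planted_amgs$context %in% AMG_CONTEXTS
    if (any(bad))
      stop("unknown planted AMG context(s): ",
           paste(unique(cfg$planted_amgs$context[bad]), collapse = ", "))
  }
  n_family <- if (nrow(cfg$cluster_families) > 0)
    sum(cfg$cluster_families$size) else 0L
  n_single <- cfg$n_viral_contigs - n_family
  if (n_single < 0)
    stop("cluster families require more contigs than n_viral_contigs")
  if (nrow(cfg$planted_amgs) > n_single)
    stop("more planted AMGs (", nrow(cfg$planted_amgs),
         ") than singleton viral contigs (", n_single, ")")
  if (any(cfg$cluster_families$divergence < 0 |
          cfg$cluster_families$divergence > 0.04))
    stop("family divergence must be in [0, 0.04] to keep true ANI >= 95%")
  if (cfg$n_mags == 0 && cfg$n_viral_contigs > 0)
    stop("viral contigs require at least one host MAG")
  invisible(cfg)
}

#' Default planted AMG set
#'
#' Ten plants covering every curation outcome: five accepted (\code{flanked})
#' candidates spanning exclusive-MM, shared-MM and non-MM KOs, plus one of
#' each rejection mode.
#'
#' @return data.frame \code{ko}, \code{context}.
#' @export
default_planted_amgs <- function() {
  data.frame(
    ko = c("K00577", "K10946", "K00600", "K00925", "K00845",
           "K12234", "K00625", "K00441", "K00198", "K08685"),
    context = c("flanked", "flanked", "flanked", "flanked", "flanked",
                "terminal", "transposon", "inconsistent", "host_region",
                "no_ko"),
    stringsAsFactors = FALSE
  )
}

#' Default sample sheet: 2 sites x 3 depths x 2 metagenome types
#' @return data.frame \code{sample_id}, \code{site}, \code{depth_cm},
#'   \code{type}.
#' @export
default_samples <- function() {
  grid <- expand.grid(type = c("bulk", "virome"),
                      depth_cm = c(50L, 100L, 225L),
                      site = c("muddy", "sandy"),
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%03d_%s", substr(grid$site, 1, 1),
                            grid$depth_cm, ifelse(grid$type == "bulk",
                                                  "B", "V"))
  grid[, c("sample_id", "site", "depth_cm", "type")]
}

random_seq <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

random_cds <- function(n_codons) {
  paste(sample(NONSTOP_CODONS, n_codons, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate, protect = integer(0)) {
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    chars[i] <- sample_vec(setdiff(BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

seq_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  100 * mean(ca == cb)
}

# Gene-category plan for one viral contig given its planted-AMG context
# (NULL context = plain virus). Returns list(categories, amg_pos).
gene_plan <- function(context = NULL, n_genes = 14L) {
  cats <- rep("phage", n_genes)
  cats[3L] <- "hallmark"
  cats[5L] <- "hypothetical"
  amg_pos <- NA_integer_
  if (is.null(context)) return(list(categories = cats, amg_pos = amg_pos))
  if (context %in% c("flanked", "inconsistent", "no_ko")) {
    amg_pos <- 7L
  } else if (context == "terminal") {
    amg_pos <- n_genes
  } else if (context == "transposon") {
    amg_pos <- 7L
    cats[9L] <- "transposon"
  } else if (context == "host_region") {
    # tail: phage phage cell cell AMG cell cell cell phage
    amg_pos <- n_genes - 4L
    cats[(n_genes - 6L):(n_genes - 5L)] <- "cellular"
    cats[(n_genes - 3L):(n_genes - 1L)] <- "cellular"
    cats[n_genes] <- "phage"
  }
  cats[amg_pos] <- "amg_candidate"
  list(categories = cats, amg_pos = amg_pos)
}

# Build one contig from a category plan. Returns list(seq, genes, amg_seq).
build_contig <- function(contig_id, plan, ko = NA_character_,
                         pfam = NA_character_, tail_insert = "") {
  n_genes <- length(plan$categories)
  pieces <- character(0)
  rows <- list()
  pos <- 0L
  for (gi in seq_len(n_genes)) {
    gap <- random_seq(sample(10:40, 1L))
    pieces <- c(pieces, gap)
    pos <- pos + nchar(gap)
    cds <- random_cds(sample(120:200, 1L))
    strand <- if (plan$categories[gi] == "amg_candidate") "+"
      else sample_vec(c("+", "-"), 1L)
    ins <- if (strand == "+") cds else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    start <- pos + 1L
    end <- pos + nchar(cds)
    pieces <- c(pieces, ins)
    pos <- end
    cat_ <- plan$categories[gi]
    rows[[gi]] <- data.frame(
      contig_id = contig_id, gene_index = gi, start = start, end = end,
      strand = strand, category = cat_,
      kegg_ko = if (!is.na(plan$amg_pos) && gi == plan$amg_pos) ko
        else NA_character_,
      pfam_acc = if (!is.na(plan$amg_pos) && gi == plan$amg_pos) pfam
        else NA_character_,
      product = switch(cat_, hallmark = "terminase large subunit",
                       phage = "phage structural protein",
                       cellular = "cellular metabolic protein",
                       hypothetical = "hypothetical protein",
                       transposon = "transposase",
                       amg_candidate = "putative auxiliary metabolic gene"),
      stringsAsFactors = FALSE
    )
  }
  tail_gap <- random_seq(sample(20:50, 1L))
  seqs <- paste(c(pieces, tail_gap, tail_insert), collapse = "")
  genes <- do.call(rbind, rows)
  amg_seq <- if (!is.na(plan$amg_pos)) {
    g <- genes[genes$gene_index == plan$amg_pos, ]
    substring(seqs, g$start, g$end)
  } else NA_character_
  list(seq = seqs, genes = genes, amg_seq = amg_seq)
}

#' Extract a gene's coding sequence from its contig
#'
#' @param contigs named character vector of contig sequences.
#' @param gene one row of a gene-annotation table (\code{contig_id},
#'   \code{start}, \code{end}, \code{strand}).
#' @return coding-strand sequence, 5'->3'.
#' @export
extract_gene_seq <- function(contigs, gene) {
  s <- substring(contigs[[gene$contig_id]], gene$start, gene$end)
  if (gene$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

gene_id_of <- function(contig_id, gene_index) {
  sprintf("%s_g%02d", contig_id, gene_index)
}

# enumerate all single-nt changes of a CDS, classified syn/nonsyn
enumerate_changes <- function(cds) {
  chars <- strsplit(cds, "")[[1]]
  rows <- list()
  for (pos in seq_along(chars)) {
    ci <- (pos - 1L) %/% 3L + 1L
    codon <- substring(cds, 3L * ci - 2L, 3L * ci)
    off <- (pos - 1L) %% 3L + 1L
    ref_aa <- Biostrings::GENETIC_CODE[[codon]]
    for (b in setdiff(BASES, chars[pos])) {
      mut <- codon
      substr(mut, off, off) <- b
      mut_aa <- Biostrings::GENETIC_CODE[[mut]]
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, ref = chars[pos], alt = b,
        synonymous = ref_aa != "*" && mut_aa != "*" && ref_aa == mut_aa,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic community with planted ground truth
#'
#' Produces contig sequences, gene annotations, predictor scores,
#' alignment fragments for the constructed cluster families, per-sample
#' depth tables, MAG records (taxonomy, sequences, tRNAs, CRISPR spacers,
#' abundances), variant tables, and truth tables covering every planted
#' entity. With zero noise the downstream stages recover the truth exactly.
#'
#' Construction guarantees: planted viral contigs carry scores passing at
#' least one ensemble criterion (cycling through the four); decoys fail all
#' four; each planted AMG sits in a gene context that satisfies or (per its
#' context) violates exactly one curation rule; cluster-family members are
#' per-site mutated copies of a parent so pairwise identity is known and
#' full-length alignment fragments are emitted exactly; each virus carries
#' a verbatim CRISPR spacer (and every second one a tRNA) of its true host
#' MAG; variant tables realize the requested synonymous / nonsynonymous
#' counts on accepted AMG genes.
#'
#' @param config a \code{\link{community_config}}.
#' @return list of class \code{vamp_bundle}: \code{contigs}, \code{genes},
#'   \code{scores}, \code{fragments}, \code{depths}, \code{samples},
#'   \code{mags} (taxonomy, sequences, spacers, trnas, abundance),
#'   \code{variants}, \code{blocklist}, \code{truth} (true_viruses,
#'   true_clusters, true_amgs, true_hosts), \code{config}.
#' @export
generate_community <- function(config = community_config()) {
  validate_community_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  ## ---- MAGs -------------------------------------------------------------
  mag_ids <- sprintf("MAG%03d", seq_len(config$n_mags))
  phyla <- SYNTH_PHYLA[rep(seq_len(nrow(SYNTH_PHYLA)),
                           length.out = config$n_mags), , drop = FALSE]
  mag_tax <- data.frame(mag_id = mag_ids, domain = phyla$domain,
                        phylum = phyla$phylum,
                        class = if (config$n_mags > 0)
                          paste0("c__", phyla$phylum, "_cls")
                          else character(0),
                        stringsAsFactors = FALSE)
  mag_seqs <- setNames(vapply(mag_ids, function(i) random_seq(12000),
                              character(1)), mag_ids)
  mag_spacers <- setNames(lapply(mag_ids, function(i) {
    setNames(vapply(1:3, function(j) random_seq(32), character(1)),
             sprintf("%s_sp%d", i, 1:3))
  }), mag_ids)
  mag_trnas <- setNames(lapply(mag_ids, function(i) {
    setNames(vapply(1:2, function(j) random_seq(72), character(1)),
             sprintf("%s_trna%d", i, 1:2))
  }), mag_ids)

  ## ---- viral contigs ----------------------------------------------------
  fam <- config$cluster_families
  n_family_members <- if (nrow(fam) > 0) sum(fam$size) else 0L
  n_single <- config$n_viral_contigs - n_family_members
  plants <- config$planted_amgs

  contigs <- character(0)
  genes <- list()
  fragments <- list()
  true_clusters <- list()
  true_amgs <- list()
  true_hosts <- list()
  variants <- list()
  habitats_of <- character(0)

  add_host_plant <- function(idx) {
    # evidence for the true host: verbatim spacer; tRNA on even contigs
    mag <- mag_ids[(idx - 1L) %% config$n_mags + 1L]
    insert <- mag_spacers[[mag]][[(idx - 1L) %% 3L + 1L]]
    if (idx %% 2L == 0L) insert <- paste0(insert, random_seq(15),
                                          mag_trnas[[mag]][[1L]])
    list(mag = mag, insert = insert)
  }

  vc_idx <- 0L
  singleton_ids <- character(0)
  for (si in seq_len(n_single)) {
    vc_idx <- vc_idx + 1L
    cid <- sprintf("VC%03d", vc_idx)
    plant <- if (si <= nrow(plants)) plants[si, ] else NULL
    host <- add_host_plant(vc_idx)
    if (is.null(plant)) {
      plan <- gene_plan(NULL)
      built <- build_contig(cid, plan, tail_insert = host$insert)
    } else {
      ctx <- plant$context
      ko <- if (ctx == "no_ko") NA_character_ else plant$ko
      pfam <- if (ctx == "inconsistent") "PF99999" else {
        pf <- read_tsv_strict(system.file("extdata", "ko_pfam_map.tsv",
                                          package = "vamp", mustWork = TRUE))
        hit <- pf$pfam_acc[pf$ko == plant$ko]
        if (length(hit) > 0) hit[1] else "PF00000"
      }
      plan <- gene_plan(ctx)
      built <- build_contig(cid, plan, ko = ko, pfam = pfam,
                            tail_insert = host$insert)
      snv <- config$snv_per_amg
      expected <- if (ctx == "flanked") "accepted" else "rejected"
      true_amgs[[length(true_amgs) + 1L]] <- data.frame(
        contig_id = cid, gene_index = plan$amg_pos, ko = plant$ko,
        context = ctx, expected_status = expected,
        gene_id = gene_id_of(cid, plan$amg_pos), stringsAsFactors = FALSE)
      if (ctx == "flanked" && (snv$n_syn + snv$n_nonsyn) > 0) {
        ch <- enumerate_changes(built$amg_seq)
        syn_pool <- ch[ch$synonymous, , drop = FALSE]
        syn_pick <- syn_pool[sample.int(nrow(syn_pool),
                                        min(snv$n_syn, nrow(syn_pool))), ,
                             drop = FALSE]
        # one variant per position, so truth counts stay exact
        non_pool <- ch[!ch$synonymous &
                         !ch$position %in% syn_pick$position, , drop = FALSE]
        non_pick <- non_pool[sample.int(nrow(non_pool),
                                        min(snv$n_nonsyn, nrow(non_pool))), ,
                             drop = FALSE]
        pick <- rbind(syn_pick, non_pick)
        variants[[length(variants) + 1L]] <- data.frame(
          gene_id = gene_id_of(cid, plan$amg_pos),
          position = pick$position, ref = pick$ref, alt = pick$alt,
          synonymous_truth = pick$synonymous,
          support = sample(5:40, nrow(pick), replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    contigs[cid] <- built$seq
    genes[[length(genes) + 1L]] <- built$genes
    singleton_ids <- c(singleton_ids, cid)
    true_clusters[[length(true_clusters) + 1L]] <-
      data.frame(contig_id = cid, cluster_rep = cid, stringsAsFactors = FALSE)
    true_hosts[[length(true_hosts) + 1L]] <-
      data.frame(virus_id = cid, mag_id = host$mag, stringsAsFactors = FALSE)
  }

  for (fi in seq_len(nrow(fam))) {
    vc_idx <- vc_idx + 1L
    parent_id <- sprintf("VC%03d", vc_idx)
    host <- add_host_plant(vc_idx)
    plan <- gene_plan(NULL)
    built <- build_contig(parent_id, plan, tail_insert = host$insert)
    contigs[parent_id] <- built$seq
    genes[[length(genes) + 1L]] <- built$genes
    member_ids <- parent_id
    protect <- seq(nchar(built$seq) - nchar(host$insert) + 1L,
                   nchar(built$seq))
    for (mi in seq_len(fam$size[fi] - 1L)) {
      child_id <- sprintf("%s.m%d", parent_id, mi)
      child_seq <- mutate_seq(built$seq, fam$divergence[fi],
                              protect = protect)
      contigs[child_id] <- child_seq
      g <- built$genes
      g$contig_id <- child_id
      genes[[length(genes) + 1L]] <- g
      member_ids <- c(member_ids, child_id)
    }
    for (a in seq_along(member_ids)) {
      for (b in seq_along(member_ids)) {
        if (b <= a) next
        ida <- member_ids[a]; idb <- member_ids[b]
        fragments[[length(fragments) + 1L]] <- data.frame(
          query_id = ida, target_id = idb,
          percent_identity = round(seq_identity(contigs[[ida]],
                                                contigs[[idb]]), 4),
          q_start = 1L, q_end = nchar(contigs[[ida]]),
          t_start = 1L, t_end = nchar(contigs[[idb]]),
          stringsAsFactors = FALSE)
      }
    }
    for (m in member_ids) {
      true_clusters[[length(true_clusters) + 1L]] <-
        data.frame(contig_id = m, cluster_rep = parent_id,
                   stringsAsFactors = FALSE)
      true_hosts[[length(true_hosts) + 1L]] <-
        data.frame(virus_id = m, mag_id = host$mag, stringsAsFactors = FALSE)
    }
  }

  viral_ids <- names(contigs)
  habitats_of <- setNames(
    config$habitats[(seq_along(viral_ids) - 1L) %% length(config$habitats) + 1L],
    viral_ids)

  ## ---- contaminant blocklist and planted contaminant contigs ------------
  blocklist <- c(lab_phage_1 = random_seq(7000))
  contam_ids <- character(0)
  if (config$n_contaminants > 0) {
    for (ci in seq_len(config$n_contaminants)) {
      cid <- sprintf("CONTAM%02d", ci)
      contigs[cid] <- blocklist[[1]]
      contam_ids <- c(contam_ids, cid)
      g <- data.frame(contig_id = cid, gene_index = 1L, start = 1L,
                      end = 300L, strand = "+", category = "phage",
                      kegg_ko = NA_character_, pfam_acc = NA_character_,
                      product = "phage structural protein",
                      stringsAsFactors = FALSE)
      genes[[length(genes) + 1L]] <- g
    }
  }

  ## ---- decoys ------------------------------------------------------------
  decoy_ids <- sprintf("DEC%03d", seq_len(config$n_decoy_contigs))
  for (d in decoy_ids) {
    len <- sample(5200:9000, 1L)
    contigs[d] <- random_seq(len)
    n_g <- 6L
    starts <- round(seq(50, len - 400, length.out = n_g))
    genes[[length(genes) + 1L]] <- data.frame(
      contig_id = d, gene_index = seq_len(n_g), start = starts,
      end = starts + 299L, strand = "+",
      category = sample(c("cellular", "hypothetical"), n_g, replace = TRUE),
      kegg_ko = NA_character_, pfam_acc = NA_character_,
      product = "cellular metabolic protein", stringsAsFactors = FALSE)
  }

  genes_proto <- data.frame(
    contig_id = character(0), gene_index = integer(0), start = integer(0),
    end = integer(0), strand = character(0), category = character(0),
    kegg_ko = character(0), pfam_acc = character(0), product = character(0))
  genes <- if (length(genes) > 0) do.call(rbind, genes) else genes_proto
  rownames(genes) <- NULL

  ## ---- annotation dropout noise ------------------------------------------
  dropout <- config$noise$annotation_dropout
  if (dropout > 0 && nrow(genes) > 0) {
    drop <- runif(nrow(genes)) < dropout
    genes$kegg_ko[drop] <- NA_character_
    genes$pfam_acc[drop] <- NA_character_
  }

  ## ---- predictor scores ---------------------------------------------------
  score_rows <- list()
  jitter <- config$noise$score_jitter
  jit <- function(x, scale = 1) {
    if (jitter == 0) return(x)
    x + rnorm(length(x), 0, jitter * scale)
  }
  all_virus_ids <- c(viral_ids, contam_ids)
  for (i in seq_along(all_virus_ids)) {
    cid <- all_virus_ids[i]
    mode <- (i - 1L) %% 4L + 1L
    row <- data.frame(contig_id = cid, length = nchar(contigs[[cid]]),
                      circular = FALSE, virsorter_category = NA_integer_,
                      dvf_score = NA_real_, dvf_p = NA_real_,
                      marvel_prob = NA_real_, stringsAsFactors = FALSE)
    if (mode == 1L) {
      row$virsorter_category <- sample_vec(c(1L, 2L, 4L, 5L), 1L)
    } else if (mode == 2L) {
      row$dvf_score <- min(1, max(0, jit(0.96, 0.05)))
      row$dvf_p <- 0.01
    } else if (mode == 3L) {
      row$marvel_prob <- min(100, max(0, jit(96, 5)))
    } else {
      row$virsorter_category <- 6L
      row$dvf_score <- min(1, max(0, jit(0.78, 0.05)))
      row$dvf_p <- 0.01
      row$marvel_prob <- min(100, max(0, jit(78, 5)))
    }
    score_rows[[length(score_rows) + 1L]] <- row
  }
  for (d in decoy_ids) {
    score_rows[[length(score_rows) + 1L]] <- data.frame(
      contig_id = d, length = nchar(contigs[[d]]), circular = FALSE,
      virsorter_category = sample_vec(c(3L, 6L, NA_integer_), 1L),
      dvf_score = round(min(1, max(0, jit(0.4, 0.05))), 4),
      dvf_p = 0.5, marvel_prob = round(min(100, max(0, jit(40, 5))), 4),
      stringsAsFactors = FALSE)
  }
  scores <- if (length(score_rows) > 0) do.call(rbind, score_rows)
    else data.frame(contig_id = character(0), length = integer(0),
                    circular = logical(0), virsorter_category = integer(0),
                    dvf_score = numeric(0), dvf_p = numeric(0),
                    marvel_prob = numeric(0))
  scores$dvf_score <- round(scores$dvf_score, 4)
  scores$marvel_prob <- round(scores$marvel_prob, 4)
  rownames(scores) <- NULL

  ## ---- samples, occupancy, depth tables -----------------------------------
  samples <- config$samples
  samples$library_bases <- round(exp(runif(
    nrow(samples), log(config$library_base_range[1]),
    log(config$library_base_range[2]))))
  reps <- unique(vapply(true_clusters, function(x) x$cluster_rep[1],
                        character(1)))
  sites <- unique(samples$site)
  depths_cm <- unique(samples$depth_cm)
  depth_rows <- list()
  for (r in reps) {
    both_sites <- runif(1) < config$shared_site_prob
    home_site <- sample_vec(sites, 1L)
    occ_sites <- if (both_sites) sites else home_site
    u <- runif(1)
    occ_depths <- if (u < config$all_depth_prob) depths_cm
      else if (u < config$all_depth_prob + 0.75)
        sample_vec(depths_cm, 1L)
      else sample_vec(depths_cm, 2L)
    in_virome <- runif(1) < config$virome_prob
    for (k in seq_len(nrow(samples))) {
      s <- samples[k, ]
      if (!(s$site %in% occ_sites) || !(s$depth_cm %in% occ_depths)) next
      if (s$type == "virome" && !in_virome) next
      depth_rows[[length(depth_rows) + 1L]] <- data.frame(
        feature_id = r, sample_id = s$sample_id,
        depth = round(exp(rnorm(1, log(8), 0.8)), 4),
        stringsAsFactors = FALSE)
    }
  }
  depths <- if (length(depth_rows) > 0) do.call(rbind, depth_rows)
    else data.frame(feature_id = character(0), sample_id = character(0),
                    depth = numeric(0))

  mag_abund <- matrix(round(runif(config$n_mags * nrow(samples), 0.5, 30), 4),
                      nrow = config$n_mags, ncol = nrow(samples),
                      dimnames = list(mag_ids, samples$sample_id))

  ## ---- assemble -----------------------------------------------------------
  truth <- list(
    true_viruses = data.frame(
      contig_id = c(all_virus_ids, decoy_ids),
      is_virus = c(rep(TRUE, length(all_virus_ids)),
                   rep(FALSE, length(decoy_ids))),
      contaminant = c(rep(FALSE, length(viral_ids)),
                      rep(TRUE, length(contam_ids)),
                      rep(FALSE, length(decoy_ids))),
      stringsAsFactors = FALSE),
    true_clusters = if (length(true_clusters) > 0)
      do.call(rbind, true_clusters)
      else data.frame(contig_id = character(0), cluster_rep = character(0)),
    true_amgs = if (length(true_amgs) > 0) do.call(rbind, true_amgs)
      else data.frame(contig_id = character(0), gene_index = integer(0),
                      ko = character(0), context = character(0),
                      expected_status = character(0), gene_id = character(0)),
    true_hosts = if (length(true_hosts) > 0) do.call(rbind, true_hosts)
      else data.frame(virus_id = character(0), mag_id = character(0))
  )
  variants <- if (length(variants) > 0) do.call(rbind, variants)
    else data.frame(gene_id = character(0), position = integer(0),
                    ref = character(0), alt = character(0),
                    synonymous_truth = logical(0), support = integer(0))
  fragments <- if (length(fragments) > 0) do.call(rbind, fragments)
    else data.frame(query_id = character(0), target_id = character(0),
                    percent_identity = numeric(0), q_start = integer(0),
                    q_end = integer(0), t_start = integer(0),
                    t_end = integer(0))
  rownames(variants) <- rownames(fragments) <- NULL

  structure(list(
    config = config,
    contigs = contigs,
    genes = genes,
    scores = scores,
    fragments = fragments,
    depths = depths,
    samples = samples,
    habitats = habitats_of,
    mags = list(taxonomy = mag_tax, sequences = mag_seqs,
                spacers = mag_spacers, trnas = mag_trnas,
                abundance = mag_abund),
    variants = variants,
    blocklist = blocklist,
    truth = truth
  ), class = "vamp_bundle")
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' Emits FASTA for sequences and headered TSVs for every table, plus a
#' \code{manifest.txt} listing md5 checksums of all written files.
#'
#' @param bundle a \code{vamp_bundle}.
#' @param dir target directory (created if absent).
#' @return invisibly, the manifest as a named character vector.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta <- function(x, path) {
    if (length(x) == 0) {
      ok <- file.create(path)
      if (!ok) stop("cannot write file: ", path)
      return(invisible(path))
    }
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(x)), path, width = 80L)
  }
  p <- function(f) file.path(dir, f)
  write_fasta(bundle$contigs, p("contigs.fasta"))
  write_fasta(bundle$blocklist, p("blocklist.fasta"))
  write_fasta(bundle$mags$sequences, p("mag_sequences.fasta"))
  write_fasta(unlist(unname(bundle$mags$spacers)), p("mag_spacers.fasta"))
  write_fasta(unlist(unname(bundle$mags$trnas)), p("mag_trnas.fasta"))
  write_tsv_plain(bundle$genes, p("genes.tsv"))
  write_tsv_plain(bundle$scores, p("scores.tsv"))
  write_tsv_plain(bundle$fragments, p("fragments.tsv"))
  write_tsv_plain(bundle$depths, p("depths.tsv"))
  write_tsv_plain(bundle$samples, p("samples.tsv"))
  write_tsv_plain(bundle$mags$taxonomy, p("mag_taxonomy.tsv"))
  ab <- data.frame(mag_id = rownames(bundle$mags$abundance),
                   bundle$mags$abundance, check.names = FALSE)
  write_tsv_plain(ab, p("mag_abundance.tsv"))
  write_tsv_plain(bundle$variants, p("variants.tsv"))
  write_tsv_plain(data.frame(contig_id = names(bundle$habitats),
                             habitat = unname(bundle$habitats)),
                  p("habitats.tsv"))
  for (nm in names(bundle$truth))
    write_tsv_plain(bundle$truth[[nm]], p(paste0(nm, ".tsv")))
  files <- sort(list.files(dir, full.names = FALSE))
  files <- setdiff(files, "manifest.txt")
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- setNames(unname(sums), files)
  writeLines(paste0(files, ": ", manifest), p("manifest.txt"))
  invisible(manifest)
}

#' Read a written bundle back into memory
#'
#' Inverse of \code{\link{write_bundle}} (the config and the spacer/tRNA
#' grouping by MAG are reconstructed from file contents).
#'
#' @param dir directory written by \code{\link{write_bundle}}.
#' @return list with the same table components as a \code{vamp_bundle}.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  read_fasta <- function(path) {
    if (file.size(path) == 0) return(setNames(character(0), character(0)))
    x <- Biostrings::readDNAStringSet(path)
    setNames(as.character(x), names(x))
  }
  regroup <- function(x, ids) {
    grp <- sub("_(sp|trna)[0-9]+$", "", names(x))
    out <- lapply(ids, function(i) x[grp == i])
    setNames(out, ids)
  }
  tax <- read_tsv_strict(p("mag_taxonomy.tsv"))
  spacers <- read_fasta(p("mag_spacers.fasta"))
  trnas <- read_fasta(p("mag_trnas.fasta"))
  ab <- read_tsv_strict(p("mag_abundance.tsv"))
  abm <- as.matrix(ab[, -1, drop = FALSE])
  rownames(abm) <- ab$mag_id
  hab <- read_tsv_strict(p("habitats.tsv"))
  list(
    contigs = read_fasta(p("contigs.fasta")),
    genes = read_tsv_strict(p("genes.tsv")),
    scores = read_tsv_strict(p("scores.tsv")),
    fragments = read_tsv_strict(p("fragments.tsv")),
    depths = read_tsv_strict(p("depths.tsv")),
    samples = read_tsv_strict(p("samples.tsv")),
    habitats = setNames(hab$habitat, hab$contig_id),
    mags = list(taxonomy = tax,
                sequences = read_fasta(p("mag_sequences.fasta")),
                spacers = regroup(spacers, tax$mag_id),
                trnas = regroup(trnas, tax$mag_id),
                abundance = abm),
    variants = read_tsv_strict(p("variants.tsv")),
    blocklist = read_fasta(p("blocklist.fasta")),
    truth = list(
      true_viruses = read_tsv_strict(p("true_viruses.tsv")),
      true_clusters = read_tsv_strict(p("true_clusters.tsv")),
      true_amgs = read_tsv_strict(p("true_amgs.tsv")),
      true_hosts = read_tsv_strict(p("true_hosts.tsv"))
    )
  )
}
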