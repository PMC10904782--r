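mk_genes <- function(categories, contig = "vc1", ko = NA, pfam = NA,
                     amg_pos = which(categories == "amg_candidate")[1]) {
  n <- length(categories)
  data.frame(
    contig_id = contig, gene_index = seq_len(n),
    start = (seq_len(n) - 1) * 400 + 1, end = seq_len(n) * 400 - 100,
    strand = "+", category = categories,
    kegg_ko = ifelse(seq_len(n) == amg_pos, ko, NA),
    pfam_acc = ifelse(seq_len(n) == amg_pos, pfam, NA),
    product = "x", stringsAsFactors = FALSE)
}

pm <- load_pathway_map()

test_that("boundary trim removes cellular-dominated terminal runs only", {
  # all phage/hallmark: nothing trimmed
  g <- mk_genes(c("phage", "hallmark", rep("phage", 8)))
  tr <- trim_host_boundary(g)
  expect_equal(tr$trimmed_left, 0)
  expect_equal(tr$trimmed_right, 0)
  expect_equal(tr$kept, c(1, 10))

  # four leading cellular genes are trimmed
  g <- mk_genes(c(rep("cellular", 4), rep("phage", 6)))
  tr <- trim_host_boundary(g)
  expect_equal(tr$trimmed_left, 4)
  expect_equal(tr$kept, c(5, 10))

  # a terminal run of 2 is below min_run
  g <- mk_genes(c(rep("phage", 8), "cellular", "cellular"))
  expect_equal(trim_host_boundary(g)$trimmed_right, 0)

  # hallmark genes anchor the viral region and stop the run
  g <- mk_genes(c("cellular", "hallmark", "cellular", rep("phage", 7)))
  expect_equal(trim_host_boundary(g)$trimmed_left, 0)

  # a cellular block buffered by enough phage genes stays untrimmed
  # (the terminal run would dilute below the cellular-fraction threshold)
  g <- mk_genes(c("phage", "phage", rep("cellular", 3), rep("phage", 5)))
  tr <- trim_host_boundary(g)
  expect_equal(tr$trimmed_left + tr$trimmed_right, 0)
})

test_that("curation accepts only candidates passing every rule", {
  cats <- rep("phage", 14)
  cats[3] <- "hallmark"
  cats[7] <- "amg_candidate"
  ok <- mk_genes(cats, ko = "K00577", pfam = "PF09472")
  tr <- trim_host_boundary(ok)
  call <- curate_amg(7, ok, tr, pm)
  expect_equal(call$status, "accepted")
  expect_equal(call$rejection_reasons, "")
  expect_equal(call$mm_class, "exclusive_mm")

  # terminal candidate: one side has no genes
  cats2 <- c(rep("phage", 13), "amg_candidate")
  g <- mk_genes(cats2, ko = "K00577", pfam = "PF09472")
  call <- curate_amg(14, g, trim_host_boundary(g), pm)
  expect_equal(call$status, "rejected")
  expect_equal(call$rejection_reasons, "not_flanked")

  # transposase within the window
  cats3 <- cats
  cats3[9] <- "transposon"
  g <- mk_genes(cats3, ko = "K00577", pfam = "PF09472")
  call <- curate_amg(7, g, trim_host_boundary(g), pm)
  expect_equal(call$rejection_reasons, "transposon_context")

  # KO/PFAM disagreement
  g <- mk_genes(cats, ko = "K00577", pfam = "PF99999")
  call <- curate_amg(7, g, trim_host_boundary(g), pm)
  expect_equal(call$rejection_reasons, "annotation_inconsistent")

  # PFAM missing entirely is treated as inconsistent
  g <- mk_genes(cats, ko = "K00577", pfam = NA)
  call <- curate_amg(7, g, trim_host_boundary(g), pm)
  expect_equal(call$rejection_reasons, "annotation_inconsistent")

  # no KO at all
  g <- mk_genes(cats, ko = NA, pfam = "PF09472")
  call <- curate_amg(7, g, trim_host_boundary(g), pm)
  expect_equal(call$rejection_reasons, "no_ko")

  # candidate inside a trimmed host region
  cats4 <- rep("phage", 14)
  cats4[3] <- "hallmark"
  cats4[8:9] <- "cellular"
  cats4[10] <- "amg_candidate"
  cats4[11:13] <- "cellular"
  g <- mk_genes(cats4, ko = "K00577", pfam = "PF09472", amg_pos = 10)
  tr <- trim_host_boundary(g)
  expect_equal(tr$trimmed_right, 7)
  call <- curate_amg(10, g, tr, pm)
  expect_equal(call$rejection_reasons, "in_host_region")

  expect_error(curate_amg(99, ok, tr, pm), "not found")
  expect_error(curate_amg(1, ok, tr, pm), "not an amg_candidate")
})

test_that("every rejection is single-cause and toggling the cause flips the call", {
  bundle <- generate_community(community_config(seed = 3))
  pmap <- load_pathway_map()
  truth <- bundle$truth$true_amgs
  rejected <- truth[truth$expected_status == "rejected", ]
  for (i in seq_len(nrow(rejected))) {
    g <- bundle$genes[bundle$genes$contig_id == rejected$contig_id[i], ]
    tr <- trim_host_boundary(g)
    call <- curate_amg(rejected$gene_index[i], g, tr, pmap)
    expect_equal(call$status, "rejected")
    reasons <- strsplit(call$rejection_reasons, ",")[[1]]
    expect_length(reasons, 1)

    # repair the one violated condition and re-curate
    ctx <- rejected$context[i]
    g2 <- g
    if (ctx == "terminal") {
      extra <- g2[nrow(g2), ]
      extra$gene_index <- extra$gene_index + 1
      extra$category <- "phage"
      extra$kegg_ko <- NA
      extra$pfam_acc <- NA
      g2 <- rbind(g2, extra)
    } else if (ctx == "transposon") {
      g2$category[g2$category == "transposon"] <- "phage"
    } else if (ctx == "inconsistent") {
      ko <- g2$kegg_ko[g2$gene_index == rejected$gene_index[i]]
      g2$pfam_acc[g2$gene_index == rejected$gene_index[i]] <-
        pmap$ko_to_pfams[[ko]][1]
    } else if (ctx == "no_ko") {
      g2$kegg_ko[g2$gene_index == rejected$gene_index[i]] <- rejected$ko[i]
      g2$pfam_acc[g2$gene_index == rejected$gene_index[i]] <-
        pmap$ko_to_pfams[[rejected$ko[i]]][1]
    } else if (ctx == "host_region") {
      g2$category[g2$category == "cellular"] <- "phage"
    }
    call2 <- curate_amg(rejected$gene_index[i], g2, trim_host_boundary(g2),
                        pmap)
    expect_equal(call2$status, "accepted")
  }
})

test_that("MM exclusivity classification is a total trichotomy", {
  expect_equal(classify_mm("K00577", pm), "exclusive_mm")  # MM modules only
  expect_equal(classify_mm("K00600", pm), "shared_mm")     # MM + other
  expect_equal(classify_mm("K00845", pm), "non_mm")        # no MM module
  expect_warning(cls <- classify_mm("K99999", pm), "not in pathway map")
  expect_equal(cls, "non_mm")

  for (ko in names(pm$ko_to_modules)) {
    cls <- classify_mm(ko, pm)
    expect_true(cls %in% c("exclusive_mm", "shared_mm", "non_mm"))
    mods <- pm$ko_to_modules[[ko]]
    in_mm <- mods %in% pm$mm_modules
    expect_equal(cls, if (all(in_mm)) "exclusive_mm"
                 else if (any(in_mm)) "shared_mm" else "non_mm")
  }
})

test_that("habitat association conserves tallies and counts breadth", {
  calls <- data.frame(
    contig_id = c("v1", "v2", "v3", "v4", "v5"),
    gene_index = 1, kegg_ko = c("K00577", "K00577", "K10946", "K00600",
                                "K00845"),
    status = c("accepted", "accepted", "accepted", "accepted", "accepted"),
    rejection_reasons = "", stringsAsFactors = FALSE)
  calls$mm_class <- vapply(calls$kegg_ko, classify_mm, character(1),
                           pathway_map = pm)
  habs <- c(v1 = "rumen", v2 = "marine_water", v3 = "rumen", v4 = "rumen",
            v5 = "rumen")
  ha <- habitat_association(calls, habs)
  # K00845 is non-MM and excluded from the MM AMG matrix
  expect_setequal(rownames(ha$matrix), c("K00577", "K10946", "K00600"))
  expect_equal(sum(ha$matrix), 4)   # grand total = accepted MM gene calls
  expect_equal(ha$breadth[["K00577"]], 2)
  expect_equal(ha$n_multi_habitat, 1)
  expect_equal(ha$n_single_habitat, 2)
  expect_equal(unname(ha$amgs_per_habitat["rumen"]), 3)

  # contig order does not matter
  ha2 <- habitat_association(calls[5:1, ], habs)
  expect_equal(ha$matrix, ha2$matrix)

  expect_error(habitat_association(calls, habs[-1]), "without habitat")

  # single accepted AMG in one habitat
  ha3 <- habitat_association(calls[1, ], habs[1])
  expect_equal(sum(ha3$matrix), 1)
  expect_equal(ha3$breadth[["K00577"]], 1)
})
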