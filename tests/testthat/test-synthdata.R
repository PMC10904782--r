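test_that("fixed seed gives byte-identical written bundles", {
  cfg <- community_config(seed = 5, n_viral_contigs = 10,
                          n_decoy_contigs = 4,
                          planted_amgs = default_planted_amgs()[1:3, ],
                          cluster_families = data.frame(size = 3,
                                                        divergence = 0.01))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_bundle(generate_community(cfg), d1)
  m2 <- write_bundle(generate_community(cfg), d2)
  expect_equal(m1, m2)   # identical md5 checksums for every file

  # a different seed changes the sequences
  cfg2 <- cfg
  cfg2$seed <- 6L
  d3 <- withr::local_tempdir()
  m3 <- write_bundle(generate_community(cfg2), d3)
  expect_false(identical(m1[["contigs.fasta"]], m3[["contigs.fasta"]]))
})

test_that("generated tables are internally consistent", {
  b <- generate_community(community_config(seed = 8))
  # every gene interval lies within its contig
  lens <- nchar(b$contigs)
  expect_true(all(b$genes$start >= 1))
  expect_true(all(b$genes$end <= lens[b$genes$contig_id]))
  expect_true(all(b$genes$start <= b$genes$end))
  # gene_index strictly increasing per contig
  for (g in split(b$genes, b$genes$contig_id))
    expect_true(all(diff(g$gene_index) > 0))
  # scores cover every contig exactly once
  expect_setequal(b$scores$contig_id, names(b$contigs))
  expect_equal(anyDuplicated(b$scores$contig_id), 0)
  # variant positions lie within their gene and match the reference base
  gid <- gsub("_g[0-9]+$", "", b$variants$gene_id)
  idx <- as.integer(sub("^.*_g", "", b$variants$gene_id))
  for (i in seq_len(nrow(b$variants))) {
    g <- b$genes[b$genes$contig_id == gid[i] & b$genes$gene_index == idx[i], ]
    seqs <- extract_gene_seq(b$contigs, g)
    expect_lte(b$variants$position[i], nchar(seqs))
    expect_equal(substring(seqs, b$variants$position[i],
                           b$variants$position[i]), b$variants$ref[i])
  }
  # truth tables cover all planted entities
  expect_setequal(b$truth$true_clusters$contig_id,
                  b$truth$true_viruses$contig_id[
                    b$truth$true_viruses$is_virus &
                      !b$truth$true_viruses$contaminant])
  expect_equal(nrow(b$truth$true_amgs), nrow(b$config$planted_amgs))
})

test_that("planted predictor scores pass and decoys fail the ensemble rule", {
  b <- generate_community(community_config(seed = 12))
  calls <- classify_virus(b$scores)
  truth <- b$truth$true_viruses
  merged <- merge(calls, truth, by = "contig_id")
  expect_equal(merged$is_virus.x, merged$is_virus.y)
})

test_that("constructed cluster families sit above the 95/80 thresholds", {
  cfg <- community_config(seed = 13, n_viral_contigs = 6,
                          planted_amgs = default_planted_amgs()[0, ],
                          cluster_families = data.frame(size = 4,
                                                        divergence = 0.01))
  b <- generate_community(cfg)
  fam <- b$truth$true_clusters
  fam <- fam[fam$cluster_rep != fam$contig_id |
               fam$cluster_rep %in% fam$cluster_rep[duplicated(fam$cluster_rep)], ]
  members <- unique(c(fam$contig_id, fam$cluster_rep))
  expect_length(members, 4)
  # verify true ANI by brute-force positionwise comparison of each pair
  for (i in seq_along(members)) {
    for (j in seq_along(members)) {
      if (j <= i) next
      a <- strsplit(b$contigs[[members[i]]], "")[[1]]
      c2 <- strsplit(b$contigs[[members[j]]], "")[[1]]
      ani <- 100 * mean(a == c2)
      expect_gte(ani, 95)
      frag <- b$fragments[
        (b$fragments$query_id == members[i] &
           b$fragments$target_id == members[j]) |
          (b$fragments$query_id == members[j] &
             b$fragments$target_id == members[i]), ]
      expect_equal(nrow(frag), 1)
      expect_equal(frag$percent_identity, ani, tolerance = 1e-4)
    }
  }
  # downstream clustering recovers one vOTU of size 4
  cl <- cluster_votus(b$fragments, setNames(nchar(b$contigs)[members],
                                            members))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 4)
})

test_that("a written bundle reads back equal to the in-memory bundle", {
  b <- generate_community(community_config(
    seed = 14, n_viral_contigs = 8, n_decoy_contigs = 3,
    planted_amgs = default_planted_amgs()[1:2, ]))
  d <- withr::local_tempdir()
  write_bundle(b, d)
  r <- read_bundle(d)
  expect_equal(r$contigs, b$contigs)
  expect_equal(r$genes, b$genes)
  expect_equal(r$scores, b$scores)
  expect_equal(r$fragments, b$fragments)
  expect_equal(r$depths, b$depths)
  expect_equal(r$samples, b$samples)
  expect_equal(r$habitats, b$habitats)
  expect_equal(r$mags$taxonomy, b$mags$taxonomy)
  expect_equal(r$mags$sequences, b$mags$sequences)
  expect_equal(r$mags$abundance, b$mags$abundance)
  expect_equal(lapply(r$mags$spacers, unname),
               lapply(b$mags$spacers, unname), ignore_attr = TRUE)
  expect_equal(r$variants, b$variants)
  expect_equal(r$truth$true_amgs, b$truth$true_amgs)
  expect_equal(r$truth$true_hosts, b$truth$true_hosts)
})

test_that("degenerate and contradictory configurations are handled", {
  # empty community: valid empty-but-headered tables
  cfg <- community_config(seed = 1, n_mags = 0, n_viral_contigs = 0,
                          n_decoy_contigs = 0, n_contaminants = 0,
                          planted_amgs = default_planted_amgs()[0, ],
                          cluster_families = data.frame(size = integer(0),
                                                        divergence = numeric(0)))
  b <- generate_community(cfg)
  expect_length(b$contigs, 0)
  expect_equal(nrow(b$genes), 0)
  d <- withr::local_tempdir()
  write_bundle(b, d)
  r <- read_bundle(d)
  expect_equal(nrow(r$scores), 0)

  # configuration errors
  expect_error(community_config(noise = list(score_jitter = 2,
                                             annotation_dropout = 0)),
               "rates")
  expect_error(community_config(n_viral_contigs = -1), "counts")
  expect_error(community_config(
    planted_amgs = data.frame(ko = "K00577",
                              context = "flanked_and_terminal")),
    "context")
  expect_error(community_config(n_viral_contigs = 2,
                                cluster_families = data.frame(
                                  size = 5, divergence = 0.01)),
               "more contigs")
  expect_error(community_config(
    n_viral_contigs = 1,
    cluster_families = data.frame(size = integer(0),
                                  divergence = numeric(0)),
    planted_amgs = default_planted_amgs()), "planted AMGs")
})
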