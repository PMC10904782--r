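# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive results through different code paths
# (brute force, enumeration, other packages) than the implementation.

# brute-force greedy clustering from an explicit adjacency matrix
oracle_greedy <- function(lengths, adj) {
  ids <- names(lengths)
  ord <- ids[order(-as.numeric(lengths), ids)]
  centroid_of <- character(0)
  for (id in ord) {
    assigned <- FALSE
    for (ct in unique(centroid_of)) {
      if (adj[id, ct]) {
        centroid_of[id] <- ct
        assigned <- TRUE
        break
      }
    }
    if (!assigned) centroid_of[id] <- id
  }
  split(names(centroid_of), centroid_of)
}

# exhaustive PERMANOVA: enumerate every ordering of the labels
oracle_permanova_p <- function(d, labels) {
  n <- nrow(d)
  f_of <- function(lab) {
    d2 <- d^2
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      if (length(idx) > 1) {
        sub <- d2[idx, idx]
        ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    a <- length(unique(lab))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  perms <- gtools_permutations(n)
  f_obs <- f_of(labels)
  f_all <- apply(perms, 1, function(idx) f_of(labels[idx]))
  mean(f_all >= f_obs - 1e-12)
}

# all permutations of 1..n as rows (recursive, independent of the package)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out <- rbind(out, block)
  }
  out
}

# codon-wise expected sites and SNP classification via seqinr translation
oracle_sites <- function(seq) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  n_codons <- length(chars) / 3
  n_sites <- 0
  s_sites <- 0
  for (ci in seq_len(n_codons)) {
    codon <- chars[(3 * ci - 2):(3 * ci)]
    ref_aa <- seqinr::translate(codon)
    for (p in 1:3) {
      syn <- 0
      for (b in setdiff(bases, codon[p])) {
        mut <- codon
        mut[p] <- b
        aa <- seqinr::translate(mut)
        if (aa != "*" && aa == ref_aa) syn <- syn + 1
      }
      s_sites <- s_sites + syn / 3
      n_sites <- n_sites + (3 - syn) / 3
    }
  }
  c(N = n_sites, S = s_sites)
}

oracle_classify <- function(seq, snps) {
  chars <- strsplit(seq, "")[[1]]
  n <- 0L
  s <- 0L
  for (i in seq_len(nrow(snps))) {
    pos <- snps$position[i]
    ci <- (pos - 1) %/% 3 + 1
    codon <- chars[(3 * ci - 2):(3 * ci)]
    ref_aa <- seqinr::translate(codon)
    mut <- codon
    mut[(pos - 1) %% 3 + 1] <- snps$alt[i]
    mut_aa <- seqinr::translate(mut)
    if (ref_aa != "*" && mut_aa != "*" && ref_aa == mut_aa) s <- s + 1L
    else n <- n + 1L
  }
  c(N = n, S = s)
}

# exact k-mer containment by direct tabulation
oracle_containment <- function(contig, genome, k) {
  extract <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- substring(s, 1:(n - k + 1), k:n)
    rc <- vapply(km, function(x) {
      paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    unique(pmin(km, rc))
  }
  ck <- extract(contig)
  gk <- extract(genome)
  sum(ck %in% gk) / length(ck)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random in-frame CDS without stop codons
random_cds_test <- function(n_codons) {
  codons <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0), c("A", "C", "G", "T"), paste0))
  aa <- vapply(codons, function(cd) seqinr::translate(strsplit(cd, "")[[1]]),
               character(1))
  paste(sample(codons[aa != "*"], n_codons, replace = TRUE), collapse = "")
}
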