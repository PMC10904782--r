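test_that("coverage normalization scales depth by library gigabases", {
  d <- data.frame(feature_id = c("v1", "v1", "v2"),
                  sample_id = c("s1", "s2", "s1"),
                  depth = c(10, 10, 0))
  m <- normalize_coverage(d, c(s1 = 2e9, s2 = 0.5e9))
  expect_equal(m["v1", "s1"], 5)
  expect_equal(m["v1", "s2"], 20)   # 4x smaller library -> 4x larger value
  expect_equal(m["v2", "s1"], 0)
  expect_equal(m["v2", "s2"], 0)    # absent feature defaults to 0
  expect_error(normalize_coverage(d, c(s1 = 2e9)), "unknown samples")
  expect_error(normalize_coverage(d, c(s1 = 0, s2 = 1e9)), "library_bases")
})

test_that("presence partition reproduces printed shared/unique arithmetic", {
  # 3146 features, 131 on both of two sites -> 4.2% shared
  m <- matrix(0, 3146, 2, dimnames = list(sprintf("v%04d", 1:3146),
                                          c("muddy", "sandy")))
  m[1:131, ] <- 1
  m[132:2000, 1] <- 1
  m[2001:3146, 2] <- 1
  pp <- partition_presence(m, c("muddy", "sandy"))
  expect_equal(pp$n_in_all, 131)
  expect_equal(pp$pct_in_all, 4.2)
  expect_equal(pp$n_unique, 3146 - 131)
  expect_equal(pp$pct_unique, 95.8)
})

test_that("presence partition matches brute-force tabulation on random data", {
  set.seed(9)
  for (rep_i in 1:10) {
    nf <- sample(20:100, 1)
    ns <- 9
    groups <- sample(c("g1", "g2", "g3"), ns, replace = TRUE)
    while (length(unique(groups)) < 2)
      groups <- sample(c("g1", "g2", "g3"), ns, replace = TRUE)
    m <- matrix(rbinom(nf * ns, 1, 0.4) * runif(nf * ns), nf, ns,
                dimnames = list(sprintf("f%03d", 1:nf), sprintf("s%d", 1:ns)))
    pp <- partition_presence(m, groups)
    lv <- sort(unique(groups))
    brute <- t(apply(m, 1, function(row) {
      vapply(lv, function(g) any(row[groups == g] > 0), logical(1))
    }))
    ng <- rowSums(brute)
    expect_equal(pp$n_in_all, sum(ng == length(lv)))
    expect_equal(pp$n_unique, sum(ng == 1))
    expect_equal(pp$n_features, sum(ng > 0))
    expect_equal(unname(pp$group_counts), unname(colSums(brute)))
  }
  # all features everywhere: unique count 0
  m <- matrix(1, 5, 4)
  colnames(m) <- sprintf("s%d", 1:4)
  rownames(m) <- sprintf("f%d", 1:5)
  expect_equal(partition_presence(m, c("a", "a", "b", "b"))$n_unique, 0)
  expect_error(partition_presence(m, rep("a", 4)), "two groups")
})

test_that("Bray-Curtis matches hand arithmetic and vegan", {
  m <- cbind(s1 = c(1, 2, 0), s2 = c(0, 2, 4))
  rownames(m) <- c("f1", "f2", "f3")
  d <- bray_curtis(m)
  expect_equal(d["s1", "s2"], 5 / 9)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))

  # identical samples -> 0; disjoint supports -> 1
  m2 <- cbind(a = c(1, 2), b = c(1, 2), c = c(0, 5))
  d2 <- bray_curtis(rbind(m2, 0))
  expect_equal(d2["a", "b"], 0)
  expect_lt(d2["a", "c"], 1)
  m3 <- cbind(a = c(3, 0), b = c(0, 7))
  expect_equal(bray_curtis(m3)["a", "b"], 1)

  expect_error(bray_curtis(cbind(a = c(-1, 2), b = c(1, 1))), "non-negative")
  expect_warning(d0 <- bray_curtis(cbind(a = c(0, 0), b = c(0, 0))),
                 "all-zero")
  expect_equal(d0["a", "b"], 0)

  skip_if_not_installed("vegan")
  set.seed(4)
  m4 <- matrix(runif(60), 10, 6,
               dimnames = list(sprintf("f%d", 1:10), sprintf("s%d", 1:6)))
  expect_equal(as.matrix(vegan::vegdist(t(m4), method = "bray")),
               bray_curtis(m4), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("distances stay in [0,1] on random abundance matrices", {
  set.seed(5)
  for (rep_i in 1:20) {
    m <- matrix(rexp(50) * rbinom(50, 1, 0.6), 10, 5)
    colnames(m) <- sprintf("s%d", 1:5)
    suppressWarnings(d <- bray_curtis(m))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
  }
})

test_that("PCoA satisfies classical-scaling properties", {
  # two samples at distance 1: coordinates +-0.5 on axis 1
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- pcoa(d)
  expect_equal(sort(p$coordinates[, 1]), c(-0.5, 0.5), ignore_attr = TRUE)

  # points on a line: axis 1 carries all variance, axis 2 none
  x <- c(0, 1, 2, 5, 9)
  dl <- as.matrix(dist(x))
  p <- pcoa(dl)
  expect_equal(p$eigenvalues[1] / sum(pmax(p$eigenvalues, 0)), 1,
               tolerance = 1e-8)

  # Euclidean distances are reproduced by the embedding
  set.seed(6)
  pts <- matrix(rnorm(24), 8, 3)
  de <- as.matrix(dist(pts))
  p <- pcoa(de)
  rec <- as.matrix(dist(p$coordinates))
  expect_equal(unname(rec), unname(de), tolerance = 1e-8)

  # duplicate samples -> coincident coordinates
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(4, 0, 1))
  suppressWarnings(db <- bray_curtis(m))
  p <- pcoa(db)
  expect_equal(p$coordinates["a", ], p$coordinates["b", ])

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PERMANOVA pseudo-F agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(7)
  m <- matrix(rexp(80), 10, 8)
  colnames(m) <- sprintf("s%d", 1:8)
  labels <- rep(c("g1", "g2"), each = 4)
  m[1:5, labels == "g1"] <- m[1:5, labels == "g1"] + 2
  d <- bray_curtis(m)
  ours <- permanova(d, labels, n_permutations = 99, seed = 1)
  va <- vegan::adonis2(stats::as.dist(d) ~ grp,
                       data = data.frame(grp = labels), permutations = 99)
  expect_equal(ours$pseudo_F, va$F[1], tolerance = 1e-10)
  expect_equal(ours$ss_total, va$SumOfSqs[nrow(va)], tolerance = 1e-10)
})

test_that("exhaustive PERMANOVA matches enumeration, including 2+2 separation", {
  # perfectly separated 2+2 design: exhaustive p = 1/3
  m <- cbind(a1 = c(10, 0), a2 = c(10, 0), b1 = c(0, 10), b2 = c(0, 10))
  d <- bray_curtis(m)
  res <- permanova(d, c("A", "A", "B", "B"), n_permutations = "exhaustive")
  expect_equal(res$p_value, 1 / 3)

  # random designs up to n = 7 agree with the independent enumerator
  set.seed(8)
  for (n in c(5, 6, 7)) {
    m <- matrix(rexp(n * 6), 6, n)
    colnames(m) <- sprintf("s%d", 1:n)
    labels <- sample(rep(c("A", "B"), length.out = n))
    d <- bray_curtis(m)
    res <- permanova(d, labels, n_permutations = "exhaustive")
    expect_equal(res$p_value, oracle_permanova_p(d, labels))
  }
})

test_that("PERMANOVA F is invariant to joint sample/label permutation", {
  set.seed(10)
  m <- matrix(rexp(48), 8, 6)
  colnames(m) <- sprintf("s%d", 1:6)
  labels <- c("A", "A", "A", "B", "B", "B")
  d <- bray_curtis(m)
  f1 <- permanova(d, labels, n_permutations = 9, seed = 1)$pseudo_F
  perm <- sample(6)
  f2 <- permanova(d[perm, perm], labels[perm], n_permutations = 9,
                  seed = 1)$pseudo_F
  expect_equal(f1, f2)

  # p bounded below by 1/(n_perm + 1)
  expect_gte(permanova(d, labels, n_permutations = 99, seed = 2)$p_value,
             1 / 100)
  expect_error(permanova(d, rep("A", 6), n_permutations = 9, seed = 1),
               "two groups")
})
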