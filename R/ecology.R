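# Abundance ecology: coverage-per-gigabase normalization, occupancy
# partitions, Bray-Curtis distances, PCoA, PERMANOVA.

#' Normalize mean coverage depths to coverage per gigabase
#'
#' Each feature's mean read depth in a sample is scaled by that sample's
#' library size: \code{value = depth * 1e9 / library_bases}, i.e. coverage
#' per gigabase of sequencing. Features absent from a sample's depth table
#' are 0.
#'
#' @param depths long data.frame with columns \code{feature_id},
#'   \code{sample_id}, \code{depth} (mean coverage depth, >= 0).
#' @param library_bases named numeric vector of sequenced bases per sample;
#'   every sample in \code{depths} must be present.
#' @return numeric matrix, features x samples, normalized coverage.
#' @export
#' @examples
#' d <- data.frame(feature_id = "v1", sample_id = "s1", depth = 10)
#' normalize_coverage(d, c(s1 = 2e9))  # 5
normalize_coverage <- function(depths, library_bases) {
  stopifnot(all(c("feature_id", "sample_id", "depth") %in% names(depths)))
  if (any(library_bases <= 0)) stop("library_bases must be > 0")
  unknown <- setdiff(unique(depths$sample_id), names(library_bases))
  if (length(unknown) > 0)
    stop("depth table references unknown samples: ",
         paste(unknown, collapse = ", "))
  if (any(depths$depth < 0)) stop("negative depth")
  features <- sort(unique(depths$feature_id))
  samples <- names(library_bases)
  m <- matrix(0, nrow = length(features), ncol = length(samples),
              dimnames = list(features, samples))
  m[cbind(match(depths$feature_id, features),
          match(depths$sample_id, samples))] <- depths$depth
  sweep(m, 2L, library_bases, function(d, lib) d * 1e9 / lib)
}

#' Partition feature occupancy across sample groups
#'
#' Presence is abundance > 0. For each feature, the set of groups it occurs
#' in is tabulated; the summary counts features present in every group,
#' features unique to exactly one group, and reports percentages rounded
#' half-up to one decimal, matching the reporting convention for shared /
#' unique vOTU fractions.
#'
#' @param mat feature x sample abundance matrix.
#' @param groups factor or character vector of group labels, one per sample
#'   (column), with at least two distinct groups.
#' @return list with \code{pattern} (data.frame \code{feature_id},
#'   \code{n_groups}, \code{groups} comma-joined), \code{n_features},
#'   \code{n_in_all}, \code{pct_in_all}, \code{n_unique}, \code{pct_unique},
#'   and \code{group_counts} (features present per group).
#' @export
partition_presence <- function(mat, groups) {
  groups <- as.character(groups)
  if (length(groups) != ncol(mat))
    stop("one group label per sample column required")
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("f%d", seq_len(nrow(mat)))
  lv <- sort(unique(groups))
  if (length(lv) < 2) stop("grouping must define at least two groups")
  present <- mat > 0
  # feature x group presence
  occ <- vapply(lv, function(g) {
    rowSums(present[, groups == g, drop = FALSE]) > 0
  }, logical(nrow(mat)))
  occ <- matrix(occ, nrow = nrow(mat),
                dimnames = list(rownames(mat), lv))
  n_groups <- rowSums(occ)
  seen <- n_groups > 0
  pattern <- data.frame(
    feature_id = rownames(mat),
    n_groups = n_groups,
    groups = apply(occ, 1L, function(row) paste(lv[row], collapse = ",")),
    stringsAsFactors = FALSE
  )
  n_feat <- sum(seen)
  n_all <- sum(n_groups == length(lv))
  n_uni <- sum(n_groups == 1L)
  list(
    pattern = pattern,
    n_features = n_feat,
    n_in_all = n_all,
    pct_in_all = if (n_feat > 0) occupancy_percent(n_all, n_feat) else NA_real_,
    n_unique = n_uni,
    pct_unique = if (n_feat > 0) occupancy_percent(n_uni, n_feat) else NA_real_,
    group_counts = colSums(occ)
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' \code{d(i,j) = sum |x_i - x_j| / sum (x_i + x_j)} over features, computed
#' on the columns of a feature x sample abundance matrix. A pair of samples
#' that are both all-zero has no defined dissimilarity; it is reported as 0
#' with a warning.
#'
#' @param mat feature x sample matrix of non-negative abundances.
#' @return symmetric sample x sample distance matrix (base matrix, zero
#'   diagonal).
#' @export
bray_curtis <- function(mat) {
  if (any(mat < 0)) stop("Bray-Curtis requires non-negative abundances")
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  warned <- FALSE
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      num <- sum(abs(mat[, i] - mat[, j]))
      den <- sum(mat[, i] + mat[, j])
      if (den == 0) {
        if (!warned) {
          warning("sample pair with all-zero abundances; distance set to 0")
          warned <- TRUE
        }
        val <- 0
      } else {
        val <- num / den
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers the squared distance matrix and eigendecomposes it;
#' coordinates are returned for axes with positive eigenvalues, ordered by
#' decreasing eigenvalue. Negative eigenvalues (non-Euclidean distances)
#' are dropped from the coordinates but reported.
#'
#' @param d square symmetric distance matrix with zero diagonal.
#' @param k maximum number of components to keep (default all positive
#'   axes).
#' @return list with \code{coordinates} (samples x axes), \code{eigenvalues}
#'   (all, descending), \code{negative_eigenvalues}, and
#'   \code{variance_explained} (fraction of the positive-eigenvalue sum).
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  n <- nrow(d)
  if (is.null(k)) k <- n - 1L
  # cmdscale warns when fewer than k eigenvalues are positive; we report
  # the eigenvalue spectrum ourselves
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = min(k, n - 1L), eig = TRUE))
  eig <- fit$eig
  pos <- eig > 1e-10
  coords <- fit$points
  if (!is.null(coords) && ncol(coords) > 0) {
    keep <- seq_len(min(ncol(coords), sum(pos)))
    coords <- coords[, keep, drop = FALSE]
    colnames(coords) <- paste0("PCo", keep)
  }
  list(
    coordinates = coords,
    eigenvalues = eig,
    negative_eigenvalues = eig[eig < -1e-10],
    variance_explained = if (any(pos)) eig[pos] / sum(eig[pos]) else numeric(0)
  )
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-way pseudo-F computed directly from the distance matrix
#' (Anderson-style): \code{SS_total = sum_{i<j} d_ij^2 / n},
#' \code{SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g},
#' \code{F = (SS_between/(a-1)) / (SS_within/(n-a))}. Significance is
#' assessed by permuting the group labels. The permutation p-value includes
#' the observed statistic: \code{p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)}.
#' With \code{n_permutations = "exhaustive"} all \code{n!} label orderings
#' are enumerated and \code{p = mean(F_perm >= F_obs)} (the identity
#' ordering counts in numerator and denominator).
#'
#' @param d square symmetric distance matrix with zero diagonal.
#' @param labels group labels, one per sample; at least two groups.
#' @param n_permutations number of random permutations (default 999) or
#'   \code{"exhaustive"}.
#' @param seed integer seed for the permutation draw (required for random
#'   permutations).
#' @return list of class \code{vamp_permanova}: \code{pseudo_F},
#'   \code{p_value}, \code{n_permutations}, \code{seed}, \code{ss_between},
#'   \code{ss_within}, \code{ss_total}, \code{df_between}, \code{df_within}.
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = NULL) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  n <- nrow(d)
  if (length(labels) != n) stop("one label per sample required")
  if (length(unique(labels)) < 2)
    stop("PERMANOVA requires at least two groups")
  d2 <- d^2

  f_stat <- function(lab) {
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      if (length(idx) > 1) {
        sub <- d2[idx, idx, drop = FALSE]
        ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    a <- length(unique(lab))
    ssa <- sst - ssw
    list(F = (ssa / (a - 1)) / (ssw / (n - a)),
         ssa = ssa, ssw = ssw, sst = sst, a = a)
  }

  obs <- f_stat(labels)
  exhaustive <- identical(n_permutations, "exhaustive")
  if (exhaustive) {
    perms <- all_permutations(n)
    f_perm <- vapply(seq_len(ncol(perms)), function(i) {
      f_stat(labels[perms[, i]])$F
    }, numeric(1))
    p <- mean(f_perm >= obs$F - 1e-12)
    n_perm_used <- ncol(perms)
    seed_used <- NA_integer_
  } else {
    if (is.null(seed)) stop("seed required for random permutations")
    n_permutations <- as.integer(n_permutations)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_permutations)) {
      f <- f_stat(labels[sample.int(n)])$F
      if (f >= obs$F - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_permutations)
    n_perm_used <- n_permutations
    seed_used <- seed
  }
  structure(list(
    pseudo_F = obs$F, p_value = p, n_permutations = n_perm_used,
    seed = seed_used, ss_between = obs$ssa, ss_within = obs$ssw,
    ss_total = obs$sst, df_between = obs$a - 1, df_within = n - obs$a
  ), class = "vamp_permanova")
}

#' @export
print.vamp_permanova <- function(x, ...) {
  cat("PERMANOVA (one-way, distance-based)\n")
  cat(sprintf("  pseudo-F = %.4f (df %d, %d)\n", x$pseudo_F,
              x$df_between, x$df_within))
  cat(sprintf("  p = %.4g (%s permutations)\n", x$p_value,
              format(x$n_permutations)))
  invisible(x)
}

# all permutations of 1..n as a matrix (n x n!); n kept small by callers
all_permutations <- function(n) {
  if (n > 9) stop("exhaustive enumeration limited to n <= 9")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  cols <- lapply(seq_len(n), function(pos) {
    rbind_insert(sub, n, pos)
  })
  do.call(cbind, cols)
}

rbind_insert <- function(perms, val, pos) {
  n <- nrow(perms) + 1L
  out <- matrix(0L, n, ncol(perms))
  for (j in seq_len(ncol(perms))) {
    col <- perms[, j]
    out[, j] <- append(col, val, after = pos - 1L)
  }
  out
}

# save/restore .Random.seed so seeded stages don't disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
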