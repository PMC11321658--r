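#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: q_(i) = min over j >= i of p_(j) * m / j, capped at 1.
#' Implemented here (rather than delegated) so the network and association
#' stages share one audited routine.
#'
#' @param p numeric vector of p-values (NA allowed, passed through).
#' @return vector of q-values in the original order.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(q)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(pv[o] * m / (m:1)))[ro]
  q
}

#' Drop rare OTUs
#'
#' Discards OTUs whose grand-total count across all samples is below a
#' fraction of the table's total sequence count (default 0.001 percent,
#' i.e. 1e-5).
#'
#' @param table an `otu_table`.
#' @param min_fraction threshold as a fraction of total sequences.
#' @return filtered `otu_table`.
#' @export
filter_rare_otus <- function(table, min_fraction = 1e-5) {
  stopifnot(inherits(table, "otu_table"))
  tot <- colSums(table$counts)
  grand <- sum(tot)
  if (grand <= 0) stop("empty table: total count is zero")
  keep <- tot >= min_fraction * grand
  if (!any(keep)) stop("prevalence filter removed every OTU")
  subset_otu_table(table, otus = which(keep))
}

# one multivariate-hypergeometric draw per resample, vectorized over
# resamples: sequential conditional binomial/hypergeometric by OTU
mvhyper_resamples <- function(counts, d, n_resamples) {
  nz <- which(counts > 0)
  out <- matrix(0, nrow = n_resamples, ncol = length(counts))
  remaining_draw <- rep.int(d, n_resamples)
  remaining_total <- sum(counts[nz])
  for (j in nz) {
    remaining_total <- remaining_total - counts[j]
    take <- stats::rhyper(n_resamples, m = counts[j], n = remaining_total,
                          k = remaining_draw)
    out[, j] <- take
    remaining_draw <- remaining_draw - take
    if (remaining_total == 0) break
  }
  out
}

#' Averaged, rounded rarefaction
#'
#' Resamples each sample without replacement to a common target depth
#' `d = floor(depth_fraction * min(sample depths))`, repeats `n_resamples`
#' times, and averages the resampled counts. Because each resample draws
#' exactly `d` reads, the pre-rounding mean depth of every sample is `d`
#' exactly. The averaged entries are finally rounded half-to-even.
#'
#' @param table an `otu_table` (all depths > 0).
#' @param n_resamples number of resampling rounds (default 100).
#' @param depth_fraction fraction of the minimum depth (default 0.9).
#' @param seed optional integer seed.
#' @return object of class `rarefied_table`: `table` (rounded `otu_table`),
#'   `mean_counts` (pre-rounding averages), `target_depth`.
#' @export
rarefy_averaged <- function(table, n_resamples = 100, depth_fraction = 0.9,
                            seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (!is.null(seed)) set.seed(seed)
  depths <- sample_depths(table)
  if (any(depths <= 0))
    stop("zero-depth sample(s): ",
         paste(names(depths)[depths <= 0], collapse = ", "))
  d <- floor(depth_fraction * min(depths))
  if (d < 1) stop("target depth < 1; increase depth_fraction or depth")
  n <- nrow(table$counts)
  mean_counts <- matrix(0, n, ncol(table$counts),
                        dimnames = dimnames(table$counts))
  for (i in seq_len(n)) {
    res <- mvhyper_resamples(table$counts[i, ], d, n_resamples)
    mean_counts[i, ] <- colMeans(res)
  }
  rounded <- round(mean_counts)
  structure(list(table = otu_table(rounded),
                 mean_counts = mean_counts,
                 target_depth = d,
                 n_resamples = n_resamples),
            class = "rarefied_table")
}

#' @export
print.rarefied_table <- function(x, ...) {
  cat("Rarefied table: target depth", x$target_depth, "over",
      x$n_resamples, "resamples\n")
  print(x$table)
  invisible(x)
}

ace_index <- function(x, rare_cutoff = 10) {
  x <- x[x > 0]
  s_abund <- sum(x > rare_cutoff)
  rare <- x[x <= rare_cutoff]
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  if (s_rare == 0) return(s_abund)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) {
    # all rare reads are singletons; fall back to Chao1-style correction
    f2 <- sum(x == 2)
    return(length(x) + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  i <- seq_len(rare_cutoff)
  fi <- vapply(i, function(k) sum(rare == k), 0)
  g2 <- max(s_rare / c_ace * sum(i * (i - 1) * fi) /
              (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * g2
}

#' Alpha diversity indices
#'
#' Computes, per sample: observed richness, Shannon (base-2 logarithm by
#' default), Simpson (1 - sum p^2), Chao1 with the standard F2 = 0
#' bias correction, and ACE with the rare/abundant split at 10 reads.
#'
#' @param table an `otu_table` (integer counts; Chao1/ACE assume counts,
#'   not proportions).
#' @param base logarithm base for Shannon (default 2).
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(table, base = 2) {
  stopifnot(inherits(table, "otu_table"))
  m <- table$counts
  d <- rowSums(m)
  if (any(d <= 0))
    stop("zero-depth sample(s): ", paste(rownames(m)[d <= 0], collapse = ", "))
  shannon <- apply(m, 1, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p, base = base))
  })
  simpson <- apply(m, 1, function(x) {
    p <- x / sum(x)
    1 - sum(p^2)
  })
  chao1 <- apply(m, 1, function(x) {
    s_obs <- sum(x > 0)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    if (f2 > 0) s_obs + f1^2 / (2 * f2)
    else s_obs + f1 * (f1 - 1) / 2
  })
  ace <- apply(m, 1, ace_index)
  data.frame(sample_id = table$sample_ids,
             observed = rowSums(m > 0),
             shannon = shannon, simpson = simpson,
             chao1 = chao1, ace = ace,
             row.names = NULL)
}

#' Bray-Curtis dissimilarity matrix
#'
#' Computed on relative abundances, so entries lie in [0, 1]; identical
#' compositions give 0 and disjoint supports give 1.
#'
#' @param table an `otu_table` or abundance matrix (samples x features).
#' @return symmetric `dist`-free plain matrix with zero diagonal, classed
#'   `distance_matrix`.
#' @export
bray_curtis <- function(table) {
  p <- relative_abundance(table)
  d <- as.matrix(stats::dist(p, method = "manhattan")) / 2
  structure(d, class = c("distance_matrix", class(d)))
}

#' Principal coordinate analysis
#'
#' Classical metric scaling by double-centering the squared distance
#' matrix (Gower) and eigendecomposition. Axes are ordered by eigenvalue;
#' negative eigenvalues are reported, not silently dropped, and only
#' positive-eigenvalue axes receive coordinates.
#'
#' @param d square symmetric distance matrix.
#' @param k maximum number of axes to return (default all positive axes).
#' @return list with `points` (coordinates), `eigenvalues` (all, sorted
#'   decreasing), `gram` (the double-centered matrix).
#' @export
pcoa_ordination <- function(d, k = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("PCoA needs at least 3 samples")
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  pos <- which(e$values > 1e-10)
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  pts <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), nrow = k)
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_len(k))
  list(points = pts, eigenvalues = e$values, gram = b)
}

permanova_stats <- function(d2, labels_int, k, group_sizes) {
  n <- length(labels_int)
  z <- matrix(0, n, k)
  z[cbind(seq_len(n), labels_int)] <- 1
  ss_t <- sum(d2) / (2 * n)
  gsum <- diag(crossprod(z, d2 %*% z))
  ss_w <- sum(gsum / (2 * group_sizes))
  ss_a <- ss_t - ss_w
  f <- (ss_a / (k - 1)) / (ss_w / (n - k))
  c(f = f, r2 = ss_a / ss_t)
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F from among/within sums of squared distances with a free
#' permutation test: p = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1). When an
#' explicit `permutations` matrix is supplied (each row a permutation of
#' sample indices, e.g. a full enumeration), the p-value is the fraction
#' of supplied permutations with F >= F_obs.
#'
#' @param d square symmetric distance matrix.
#' @param labels grouping factor; every group needs >= 2 members.
#' @param n_perm number of random permutations (default 999).
#' @param seed optional seed.
#' @param permutations optional integer matrix of explicit permutations.
#' @param factor_name label used in the result (defaults to the
#'   deparsed `labels` argument).
#' @return list with `factor`, `pseudo_f`, `r2`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = NULL,
                      permutations = NULL, factor_name = NULL) {
  if (is.null(factor_name)) {
    factor_name <- deparse1(substitute(labels))
    if (nchar(factor_name) > 40) factor_name <- "labels"
  }
  d <- as.matrix(d)
  labels <- as.factor(labels)
  if (length(labels) != nrow(d)) stop("labels length must match matrix")
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2))
    stop("group(s) of size 1: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  d2 <- d^2
  li <- as.integer(labels)
  k <- nlevels(labels)
  gs <- as.numeric(sizes)
  obs <- permanova_stats(d2, li, k, gs)
  eps <- 1e-12
  if (is.null(permutations)) {
    n <- length(li)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      fp <- permanova_stats(d2, li[sample.int(n)], k, gs)["f"]
      if (fp >= obs["f"] - eps) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
    np <- n_perm
  } else {
    fs <- apply(permutations, 1, function(pm)
      permanova_stats(d2, li[pm], k, gs)["f"])
    p <- mean(fs >= obs["f"] - eps)
    np <- nrow(permutations)
  }
  list(factor = factor_name,
       pseudo_f = unname(obs["f"]), r2 = unname(obs["r2"]),
       p_value = p, n_perm = np)
}

#' Mantel test
#'
#' Pearson correlation between the upper triangles of two distance
#' matrices over matched samples, with a row/column permutation test on
#' the second matrix.
#'
#' @param dist_a,dist_b square symmetric matrices of equal dimension.
#' @param n_perm number of permutations (default 999).
#' @param seed optional seed.
#' @param permutations optional explicit permutation matrix (rows are
#'   index permutations); switches to exact enumeration as in
#'   [permanova()].
#' @return list with `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999, seed = NULL,
                        permutations = NULL) {
  a <- as.matrix(dist_a)
  b <- as.matrix(dist_b)
  if (!all(dim(a) == dim(b)))
    stop("distance matrices differ in size: ", nrow(a), " vs ", nrow(b))
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(a)
  r_obs <- stats::cor(a[ut], b[ut])
  eps <- 1e-12
  if (is.null(permutations)) {
    n <- nrow(a)
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      pm <- sample.int(n)
      rp <- stats::cor(a[ut], b[pm, pm][ut])
      if (rp >= r_obs - eps) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
    np <- n_perm
  } else {
    rs <- apply(permutations, 1, function(pm)
      stats::cor(a[ut], b[pm, pm][ut]))
    p <- mean(rs >= r_obs - eps)
    np <- nrow(permutations)
  }
  list(r = r_obs, p_value = p, n_perm = np)
}

#' Pairwise Wilcoxon tests with Bonferroni-Holm correction
#'
#' Convenience wrapper used on any per-sample metric (alpha diversity,
#' MAZ, genus abundance) across groups.
#'
#' @param values numeric vector.
#' @param groups grouping factor.
#' @return data.frame of group pairs with raw and Holm-adjusted p-values.
#' @export
pairwise_wilcox_holm <- function(values, groups) {
  groups <- as.factor(groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  p <- apply(pairs, 2, function(pr) {
    stats::wilcox.test(values[groups == pr[1]],
                       values[groups == pr[2]], exact = FALSE)$p.value
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             p_value = p, p_holm = stats::p.adjust(p, method = "holm"))
}
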