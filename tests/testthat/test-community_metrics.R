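test_that("FASTQ QC applies each discard rule", {
  path <- withr::local_tempfile(fileext = ".fastq")
  good <- strrep("ACGT", 50)                      # 200 bp clean
  write_fastq(path,
              seqs = c(good,
                       strrep("A", 149),          # too short (also homopolymer)
                       good,                      # low quality
                       paste0(strrep("ACGT", 49), "ACGN"),  # ambiguous
                       paste0(strrep("C", 9), strrep("ACGT", 48))), # 9-mer run
              quals = c(phred_string(30, 200), phred_string(30, 149),
                        phred_string(19, 200), phred_string(30, 200),
                        phred_string(30, 201)))
  out <- withr::local_tempfile(fileext = ".fastq")
  res <- qc_filter_reads(path, out)
  expect_equal(res$n_total, 5)
  expect_equal(res$n_kept, 1)
  expect_equal(res$fail_length, 1)
  expect_equal(res$fail_quality, 1)
  expect_equal(res$fail_ambiguous, 1)
  expect_equal(res$fail_homopolymer, 2)  # the 149 bp poly-A also counts
  expect_equal(length(readLines(out)), 4)

  # boundary: 150 bp at mean Q exactly 20 with 8 bp run survives
  path2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(path2, paste0(strrep("G", 8), strrep("ACGT", 35), "AC"),
              phred_string(20, 150))
  expect_equal(qc_filter_reads(path2)$n_kept, 1)
})

test_that("QC tallies on a planted batch match a per-read enumeration oracle", {
  set.seed(5)
  n <- 1000
  lens <- sample(c(140L, 160L, 200L), n, replace = TRUE)
  qs <- sample(c(15L, 25L, 35L), n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), lens[i], replace = TRUE),
               collapse = "")
    if (runif(1) < 0.1) s <- paste0(s, strrep("T", 10))
    if (runif(1) < 0.1) substr(s, 5, 5) <- "N"
    s
  }, "")
  quals <- vapply(seq_len(n), function(i) phred_string(qs[i], nchar(seqs[i])), "")
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(path, seqs, quals)
  res <- qc_filter_reads(path)
  # independent rule-by-rule oracle
  o_len <- sum(nchar(seqs) < 150)
  o_q <- sum(qs < 20)
  o_amb <- sum(grepl("N", seqs, fixed = TRUE))
  o_homo <- sum(grepl("([ACGT])\\1{8,}", seqs))
  o_keep <- sum(nchar(seqs) >= 150 & qs >= 20 &
                  !grepl("N", seqs, fixed = TRUE) &
                  !grepl("([ACGT])\\1{8,}", seqs))
  expect_equal(res$fail_length, o_len)
  expect_equal(res$fail_quality, o_q)
  expect_equal(res$fail_ambiguous, o_amb)
  expect_equal(res$fail_homopolymer, o_homo)
  expect_equal(res$n_kept, o_keep)
})

test_that("truncated FASTQ fails at the record index", {
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), path)
  expect_error(qc_filter_reads(path), "truncated")
})

test_that("rare-OTU filter uses the 0.001% grand-total threshold", {
  m <- matrix(c(9, 10, 999981), 1, 3,
              dimnames = list("s1", c("below", "at", "big")))
  kept <- filter_rare_otus(otu_table(m))
  expect_setequal(kept$otu_ids, c("at", "big"))
  tab <- toy_table(5, 30, seed = 9)
  expect_identical(filter_rare_otus(tab)$counts, tab$counts)  # all abundant
  # brute-force scan oracle on a skewed random table
  set.seed(10)
  m2 <- matrix(rnbinom(10 * 200, mu = 60, size = 0.05), 10, 200,
               dimnames = list(paste0("s", 1:10), paste0("o", 1:200)))
  tab2 <- otu_table(m2)
  kept2 <- filter_rare_otus(tab2, min_fraction = 1e-3)
  oracle <- colnames(m2)[colSums(m2) >= 1e-3 * sum(m2)]
  expect_identical(kept2$otu_ids, oracle)
})

test_that("rarefaction hits the exact pre-rounding depth and hypergeometric means", {
  # single-OTU sample at depth 1000 -> forced count 900
  one <- otu_table(matrix(1000, 1, 1, dimnames = list("s1", "o1")))
  rt1 <- rarefy_averaged(one, n_resamples = 10, seed = 1)
  expect_equal(rt1$target_depth, 900)
  expect_equal(unname(rt1$table$counts[1, 1]), 900)

  # two OTUs (600, 400), d = 900: expectations (540, 360)
  two <- otu_table(matrix(c(600, 400), 1, 2,
                          dimnames = list("s1", c("a", "b"))))
  rt2 <- rarefy_averaged(two, n_resamples = 100, seed = 2)
  expect_equal(unname(rowSums(rt2$mean_counts)), 900)  # exact, pre-rounding
  # Var of one draw = n*p*q*(N-n)/(N-1); SE of 100-resample mean
  v <- 900 * 0.6 * 0.4 * (1000 - 900) / 999
  se <- sqrt(v / 100)
  expect_lt(abs(rt2$mean_counts[1, "a"] - 540), 3 * se)
  expect_lt(abs(rt2$mean_counts[1, "b"] - 360), 3 * se)

  # determinism + exact depths on a larger table
  tab <- toy_table(6, 40, lambda = 50, seed = 12)
  ra <- rarefy_averaged(tab, n_resamples = 20, seed = 7)
  rb <- rarefy_averaged(tab, n_resamples = 20, seed = 7)
  expect_identical(ra$table$counts, rb$table$counts)
  expect_equal(unname(rowSums(ra$mean_counts)),
               rep(ra$target_depth, nrow(tab$counts)))
})

test_that("alpha diversity matches closed forms and is column-order invariant", {
  uni <- otu_table(matrix(c(25, 25, 25, 25), 1,
                          dimnames = list("s", paste0("o", 1:4))))
  ad <- alpha_diversity(uni)
  expect_equal(ad$shannon, 2)          # log2(4) bits
  expect_equal(ad$simpson, 0.75)
  single <- otu_table(matrix(50, 1, 1, dimnames = list("s", "o")))
  ad1 <- alpha_diversity(single)
  expect_equal(ad1$shannon, 0)
  expect_equal(ad1$simpson, 0)
  # S_obs = 5, F1 = 2, F2 = 1 -> Chao1 = 5 + 4/2 = 7
  x <- otu_table(matrix(c(1, 1, 2, 5, 9), 1,
                        dimnames = list("s", paste0("o", 1:5))))
  expect_equal(alpha_diversity(x)$chao1, 7)
  # natural-log option
  expect_equal(alpha_diversity(uni, base = exp(1))$shannon, log(4))
  # column order invariance
  tab <- toy_table(4, 25, seed = 13)
  shuf <- subset_otu_table(tab, otus = sample(25))
  cols <- c("observed", "shannon", "simpson", "chao1", "ace")
  expect_equal(alpha_diversity(tab)[cols], alpha_diversity(shuf)[cols])
})

test_that("ACE agrees with vegan::estimateR where defined", {
  # (vegan's S.chao1 is the bias-corrected variant, so only ACE is a
  # valid oracle for the classic formulas used here)
  skip_if_not_installed("vegan")
  set.seed(14)
  m <- matrix(rnbinom(6 * 80, mu = 5, size = 0.4), 6, 80,
              dimnames = list(paste0("s", 1:6), paste0("o", 1:80)))
  m <- m[rowSums(m) > 0, ]
  ad <- alpha_diversity(otu_table(m))
  est <- vegan::estimateR(m)
  ok <- is.finite(est["S.ACE", ])
  expect_equal(ad$ace[ok], unname(est["S.ACE", ok]), tolerance = 1e-8)
})

test_that("Bray-Curtis has the right extremes and matches vegan", {
  same <- otu_table(matrix(c(5, 5, 10, 10, 3, 3), 2,
                           dimnames = list(c("a", "b"), NULL)))
  d <- bray_curtis(same)
  expect_equal(unname(d["a", "b"]), 0)
  disj <- otu_table(matrix(c(5, 0, 0, 7), 2,
                           dimnames = list(c("a", "b"), NULL)))
  expect_equal(unname(bray_curtis(disj)["a", "b"]), 1)
  skip_if_not_installed("vegan")
  tab <- toy_table(8, 15, seed = 15)
  rel <- relative_abundance(tab)
  expect_equal(unclass(bray_curtis(tab))[,],
               as.matrix(vegan::vegdist(rel, "bray"))[,],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCoA double-centering matches the linear-algebra oracle", {
  set.seed(16)
  x <- matrix(rnorm(10 * 4), 10)
  d <- as.matrix(dist(x))
  ord <- pcoa_ordination(d)
  # oracle: independent double-centering
  n <- nrow(d)
  g_oracle <- matrix(0, n, n)
  d2 <- d^2
  rm_ <- rowMeans(d2); cm <- colMeans(d2); gm <- mean(d2)
  for (i in 1:n) for (j in 1:n)
    g_oracle[i, j] <- -0.5 * (d2[i, j] - rm_[i] - cm[j] + gm)
  expect_lt(max(abs(ord$gram - g_oracle)), 1e-8)
  # reconstruction: gram = P P' when distances are Euclidean
  expect_lt(max(abs(ord$points %*% t(ord$points) - g_oracle)), 1e-8)
  # base-R oracle for the coordinates (up to sign)
  cs <- cmdscale(d, k = 4)
  for (k in 1:4)
    expect_equal(abs(ord$points[, k]), abs(cs[, k]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  expect_error(pcoa_ordination(d[1:2, 1:2]), "at least 3")
})

test_that("PERMANOVA agrees with vegan and with full enumeration at n = 6", {
  set.seed(17)
  x <- matrix(rnorm(6 * 3), 6)
  x[4:6, ] <- x[4:6, ] + 1
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 3)
  perms <- all_label_permutations(6)
  res <- permanova(d, g, permutations = perms)
  # brute-force oracle: recompute F for every permutation from scratch
  f_of <- function(lab) {
    n <- 6
    ss_t <- sum(d^2) / (2 * n)
    ss_w <- 0
    for (lv in unique(lab)) {
      idx <- which(lab == lv)
      ss_w <- ss_w + sum(d[idx, idx]^2) / (2 * length(idx))
    }
    ((ss_t - ss_w) / 1) / (ss_w / 4)
  }
  f_obs <- f_of(g)
  f_all <- apply(perms, 1, function(pm) f_of(g[pm]))
  expect_equal(res$pseudo_f, f_obs, tolerance = 1e-12)
  expect_equal(res$p_value, mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)

  skip_if_not_installed("vegan")
  set.seed(18)
  x2 <- matrix(rnorm(15 * 5), 15)
  d2 <- as.matrix(dist(x2))
  g2 <- factor(rep(c("a", "b", "c"), each = 5))
  mine <- permanova(d2, g2, n_perm = 49, seed = 1)
  ado <- vegan::adonis2(as.dist(d2) ~ g2, permutations = 49)
  expect_equal(mine$pseudo_f, ado$F[1], tolerance = 1e-10)
  expect_equal(mine$r2, ado$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA hits the permutation floor on separated clusters and guards groups", {
  set.seed(19)
  x <- rbind(matrix(rnorm(10 * 2), 10), matrix(rnorm(10 * 2) + 50, 10))
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 10)
  res <- permanova(d, g, n_perm = 99, seed = 2)
  expect_equal(res$p_value, 1 / 100)
  expect_error(permanova(d, c(rep("a", 19), "b")), "size 1")
  # R2 is invariant to a consistent relabelling of the matrix
  pm <- sample(20)
  res2 <- permanova(d[pm, pm], g[pm], n_perm = 19, seed = 3)
  expect_equal(res2$r2, res$r2, tolerance = 1e-12)
})

test_that("Mantel matches identity, enumeration, and size contract", {
  set.seed(20)
  x <- matrix(rnorm(5 * 3), 5)
  da <- as.matrix(dist(x))
  expect_equal(mantel_test(da, da, n_perm = 19, seed = 1)$r, 1)
  db <- as.matrix(dist(matrix(rnorm(5 * 3), 5)))
  perms <- all_label_permutations(5)
  res <- mantel_test(da, db, permutations = perms)
  ut <- upper.tri(da)
  r_obs <- cor(da[ut], db[ut])
  r_all <- apply(perms, 1, function(pm) cor(da[ut], db[pm, pm][ut]))
  expect_equal(res$r, r_obs)
  expect_equal(res$p_value, mean(r_all >= r_obs - 1e-12))
  expect_error(mantel_test(da, db[1:4, 1:4]), "differ in size")
})

test_that("pairwise Wilcoxon utility applies Holm ordering", {
  set.seed(21)
  v <- c(rnorm(20), rnorm(20, 2), rnorm(20, 4))
  g <- rep(c("a", "b", "c"), each = 20)
  res <- pairwise_wilcox_holm(v, g)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_holm >= res$p_value))
  expect_equal(res$p_holm, p.adjust(res$p_value, "holm"))
})
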