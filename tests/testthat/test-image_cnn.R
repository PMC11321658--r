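test_that("select_top_otus keeps everything when n is large and sorts ties", {
  tab <- toy_table(4, 10, seed = 1)
  expect_setequal(select_top_otus(tab)$otu_ids, tab$otu_ids)
  # ties at the cutoff broken lexicographically
  m <- matrix(c(5, 5, 5, 9), 1, dimnames = list("s", c("b", "a", "c", "z")))
  sel <- select_top_otus(otu_table(m), n = 2)
  expect_identical(sel$otu_ids, c("z", "a"))
  # full-sort oracle
  set.seed(2)
  m2 <- matrix(rpois(5 * 40, 10), 5, dimnames = list(NULL, sprintf("o%02d", 1:40)))
  sel2 <- select_top_otus(otu_table(m2), n = 15)
  tot <- colSums(m2)
  oracle <- names(sort(tot, decreasing = TRUE))[1:15]  # stable for distinct
  expect_setequal(sel2$otu_ids, colnames(m2)[order(-tot, colnames(m2))][1:15])
})

test_that("abundance-to-pixel transform hits its endpoints and is monotone", {
  expect_equal(abundance_to_pixel(0), 0L)
  expect_equal(abundance_to_pixel(1), 255L)
  expect_equal(abundance_to_pixel(1e-6), 0L)   # at the log floor
  grid <- seq(0, 1, length.out = 2000)
  px <- abundance_to_pixel(grid)
  expect_true(all(diff(px) >= 0))
  expect_true(all(px >= 0 & px <= 255))
  expect_error(abundance_to_pixel(1.2), "outside")
})

test_that("layout ordering follows abundance with partner insertion", {
  # no correlations above threshold -> pure descending abundance
  set.seed(3)
  n <- 40
  g <- matrix(runif(n * 4), n, dimnames = list(NULL, c("w", "x", "y", "z")))
  g <- sweep(g, 2, c(4, 3, 2, 1), "*")
  counts <- round(g * 1000)
  gt <- otu_table(counts, sample_ids = paste0("s", 1:n))
  ot <- gt  # one OTU per genus for simplicity
  tax <- taxonomy_map(colnames(counts),
                      paste0("k__B; g__", colnames(counts)))
  lay <- build_genus_layout(gt, ot, tax, L = 8)
  ord_abund <- colnames(counts)[order(-colMeans(relative_abundance(gt)),
                                      colnames(counts))]
  expect_identical(lay$blocks$genus, ord_abund)

  # two perfectly correlated mid-abundance genera become adjacent
  base <- runif(n)
  g2 <- cbind(big = 5 + runif(n), mid = base, partner = base * 0.5,
              small = runif(n) * 0.2)
  counts2 <- round(g2 * 1000) + 1
  gt2 <- otu_table(counts2, sample_ids = paste0("s", 1:n))
  tax2 <- taxonomy_map(colnames(counts2),
                       paste0("k__B; g__", colnames(counts2)))
  lay2 <- build_genus_layout(gt2, gt2, tax2, L = 8)
  pos <- match(c("mid", "partner"), lay2$blocks$genus)
  expect_equal(pos[2], pos[1] + 1)

  # determinism: identical input -> identical hash
  lay2b <- build_genus_layout(gt2, gt2, tax2, L = 8)
  expect_identical(lay2$hash, lay2b$hash)
  # distinct layouts -> distinct hashes
  expect_false(identical(lay$hash, lay2$hash))
})

test_that("constant genera are tolerated with a warning and no edges", {
  # constant relative abundance: fixed depth with a fixed count
  n <- 30
  set.seed(7)
  a <- rpois(n, 40) + 10L
  counts <- cbind(flat = rep(10L, n), vara = a, varb = 90L - a)
  gt <- otu_table(counts, sample_ids = paste0("s", 1:n))
  tax <- taxonomy_map(colnames(counts), paste0("k__B; g__", colnames(counts)))
  expect_warning(lay <- build_genus_layout(gt, gt, tax, L = 8), "constant")
  expect_equal(lay$blocks$corr_weight[lay$blocks$genus == "flat"], 0)
  # the two varying genera are perfectly anticorrelated -> edge weight 1
  expect_equal(lay$blocks$corr_weight[lay$blocks$genus == "vara"], 1)
})

test_that("encoding fills blocks per channel semantics, byte-identically", {
  co <- simulate_counts(cohort_spec(n_samples = 25, seed = 9))
  top <- select_top_otus(co$table, n = 32^2)
  gen <- collapse_to_genus(co$table, co$taxonomy)
  lay <- build_genus_layout(gen, top, co$taxonomy, L = 32)
  rel <- relative_abundance(top)
  img <- encode_image(rel[1, ], lay, L = 32)
  img2 <- encode_image(rel[1, ], lay, L = 32)
  expect_identical(img, img2)
  expect_equal(dim(img), c(32, 32, 3))
  expect_true(all(img >= 0 & img <= 255))
  # channel 1 zero where abundance is zero
  a <- rel[1, lay$otu_ids]
  rows <- (seq_along(a) - 1) %/% 32 + 1
  cols <- (seq_along(a) - 1) %% 32 + 1
  ch1 <- img[cbind(rows, cols, 1)]
  expect_true(all(ch1[a == 0] == 0))
  expect_equal(ch1, abundance_to_pixel(unname(a)))
  # channel 2 constant within a genus block
  b <- lay$blocks[lay$blocks$length > 1, ][1, ]
  idx <- b$start + seq_len(b$length) - 1
  ch2 <- img[cbind((idx - 1) %/% 32 + 1, (idx - 1) %% 32 + 1, 2)]
  expect_equal(length(unique(ch2)), 1L)
  expect_equal(unique(ch2), abundance_to_pixel(min(sum(a[idx]), 1)))
  # unused pixels zero
  used <- length(lay$otu_ids)
  if (used < 32^2) {
    p <- (used + 1):(32^2)
    expect_true(all(img[cbind((p - 1) %/% 32 + 1, (p - 1) %% 32 + 1, 1)] == 0))
  }
  bad <- rel[1, ]
  bad[lay$otu_ids[1]] <- 1.5
  expect_error(encode_image(bad, lay, L = 32), "outside")
})

test_that("channel-1 brightness grows with evenness at fixed richness", {
  # constructed case: 4 OTUs, increasingly even compositions
  counts <- rbind(c(970, 10, 10, 10), c(700, 100, 100, 100),
                  c(250, 250, 250, 250))
  tabs <- otu_table(counts, sample_ids = c("skewed", "mid", "even"),
                    otu_ids = paste0("o", 1:4))
  tax <- taxonomy_map(paste0("o", 1:4), rep("k__B; g__G", 4))
  gen <- collapse_to_genus(tabs, tax)
  # a single genus is constant in relative abundance; warning expected
  lay <- suppressWarnings(build_genus_layout(gen, tabs, tax, L = 4))
  rel <- relative_abundance(tabs)
  bright <- vapply(1:3, function(i)
    sum(encode_image(rel[i, ], lay, L = 4)[, , 1]), 0)
  expect_true(all(diff(bright) > 0))
})

test_that("age bins enumerate the declared spans and assign correctly", {
  bins <- build_age_bins()
  # independent enumeration oracle of the printed spans
  oracle <- c(seq(0, 1, 1 / 12), seq(1, 2, 1 / 6), seq(2, 4, 1 / 4),
              seq(4, 10, 1), seq(10, 22, 2), seq(22, 40, 3),
              seq(40, 70, 5), seq(70, 102, 8))
  oracle <- sort(unique(oracle))
  expect_equal(nrow(bins), length(oracle) - 1)
  expect_equal(bins$lower, head(oracle, -1))
  # age 0.04 -> first monthly bin; age 21 -> [20, 22)
  expect_equal(assign_age_bin(0.04, bins), 1L)
  i21 <- assign_age_bin(21, bins)
  expect_equal(bins$lower[i21], 20)
  expect_equal(bins$upper[i21], 22)
  expect_error(build_age_bins(ages = 150), "outside")
})

test_that("underfilled bins merge until min_count is met", {
  set.seed(4)
  ages <- runif(300, 0, 12)
  bins <- build_age_bins(ages, scheme = seq(0, 12, by = 1), min_count = 40)
  expect_true(all(bins$n >= 40))
  expect_equal(bins$lower[1], 0)
  expect_equal(bins$upper[nrow(bins)], 12)
  # contiguity
  expect_equal(bins$lower[-1], bins$upper[-nrow(bins)])
})

test_that("the CNN learns a separable toy and is seed-deterministic", {
  set.seed(5)
  L <- 16
  make_img <- function(cls) {
    im <- array(0L, c(L, L, 3))
    base <- matrix(rpois(L * L, 20), L)
    if (cls == 2) base[1:8, ] <- base[1:8, ] + 120
    im[, , 1] <- pmin(base, 255)
    im[, , 2] <- pmin(base %/% 2, 255)
    im
  }
  labs <- rep(1:2, each = 50)
  imgs <- lapply(labs, make_img)
  bins <- build_age_bins(scheme = c(0, 5, 10))
  cfg <- cnn_config(epochs = 10, conv1 = 4, conv2 = 8, batch_size = 16)
  mod <- train_cnn_age(imgs, labs, bins, cfg, seed = 1)
  acc <- mean(vapply(seq_along(imgs), function(i)
    predict_age_cnn(mod, imgs[[i]])$top3[1], 0L) == labs)
  expect_gte(acc, 0.95)
  mod2 <- train_cnn_age(imgs, labs, bins, cfg, seed = 1)
  expect_equal(mod$loss[length(mod$loss)], mod2$loss[length(mod2$loss)],
               tolerance = 1e-12)
  expect_error(train_cnn_age(imgs, rep(1L, length(imgs)), bins, cfg),
               "absent")
})

test_that("prediction takes the median of the top-3 bin midpoints", {
  set.seed(6)
  L <- 16
  imgs <- lapply(1:20, function(i) array(sample(0:255, L * L * 3, TRUE),
                                         c(L, L, 3)))
  bins <- build_age_bins(scheme = c(0, 2, 4, 16, 20))
  mod <- train_cnn_age(imgs, rep(1:4, each = 5), bins,
                       cnn_config(epochs = 2, conv1 = 2, conv2 = 4), seed = 1)
  pr <- predict_age_cnn(mod, imgs[[1]])
  expect_equal(pr$microbiota_age,
               median(bins$midpoint[order(-pr$probs)[1:3]]))
  expect_equal(pr$top3_midpoints, bins$midpoint[pr$top3])
  expect_error(predict_age_cnn(mod, array(0, c(8, 8, 3))), "shape")
})
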