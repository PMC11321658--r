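test_that("taxa selection finds a single planted age tracker", {
  set.seed(1)
  n <- 150
  ages <- runif(n, 0, 15)
  x <- matrix(runif(n * 21, 0, 0.05), n, 21)
  colnames(x) <- paste0("g", 1:21)
  x[, 1] <- plogis(ages - 5) * 0.2 + rnorm(n, 0, 0.01)
  rk <- select_age_discriminatory_taxa(x, ages, k = 5, n_iter = 10,
                                       ntree = 50, seed = 2)
  expect_equal(rk$genus[1], "g1")
  rk2 <- select_age_discriminatory_taxa(x, ages, k = 5, n_iter = 10,
                                        ntree = 50, seed = 2)
  expect_identical(rk, rk2)
  expect_error(select_age_discriminatory_taxa(x, ages, k = 50), "exceeds")
})

test_that("planted trajectory genera are recovered into the top ranks", {
  # a world with exactly 5 trajectory genera among 25 background ones
  panel <- c(
    lapply(1:5, function(i) trajectory_spec(
      paste0("Traj", i), "age_discriminatory",
      baseline_log = -0.5, midpoint = 1.5 * i, slope = 3)),
    lapply(1:25, function(i) trajectory_spec(
      paste0("Bg", i), "background", baseline_log = -1.5 + 0.05 * i)))
  co <- simulate_counts(cohort_spec(n_samples = 300, panel = panel,
                                    seed = 5))
  healthy <- co$metadata$group == "control"
  rel <- relative_abundance(co$genus_table)[healthy, ]
  ages <- co$metadata$age[healthy]
  rk <- select_age_discriminatory_taxa(rel, ages, k = 10, n_iter = 20,
                                       ntree = 100, seed = 1)
  expect_true(all(paste0("Traj", 1:5) %in% rk$genus[1:10]))
})

test_that("taxa ranking is stable across seed sets", {
  co <- simulate_counts(cohort_spec(n_samples = 500, seed = 6))
  healthy <- co$metadata$group == "control"
  rel <- relative_abundance(co$genus_table)[healthy, ]
  ages <- co$metadata$age[healthy]
  r1 <- select_age_discriminatory_taxa(rel, ages, k = 10, n_iter = 15,
                                       ntree = 80, seed = 100)
  r2 <- select_age_discriminatory_taxa(rel, ages, k = 10, n_iter = 15,
                                       ntree = 80, seed = 900)
  rho <- cor(r1$mean_rank[match(colnames(rel), r1$genus)],
             r2$mean_rank[match(colnames(rel), r2$genus)],
             method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("age model training enforces its contracts", {
  x <- matrix(runif(100 * 5), 100, dimnames = list(NULL, paste0("g", 1:5)))
  expect_error(train_age_model(x, rep(3, 100)), "constant")
  ages <- runif(100, 0, 2.9)  # only the first stratum occupied
  expect_error(train_age_model(x, ages, stratify = TRUE), "empty age stratum")
})

test_that("stratified models score each sample with its stratum's model", {
  co <- simulate_counts(cohort_spec(n_samples = 400, seed = 7,
                                    age_range = c(0, 25)))
  healthy <- co$metadata$group == "control"
  rel <- relative_abundance(co$genus_table)[healthy, ]
  ages <- co$metadata$age[healthy]
  ms <- train_age_model(rel, ages, stratify = TRUE, ntree = 100,
                        min_stratum_n = 10, seed = 1)
  expect_s3_class(ms, "age_model_set")
  pred <- predict_microbiota_age(ms, rel, ages)
  expect_length(pred, nrow(rel))
  # strata are routed: predictions equal the per-stratum model outputs
  s1 <- ages < 3
  direct <- predict(ms$models[["<3"]]$forest, rel[s1, , drop = FALSE])
  expect_equal(pred[s1], unname(direct))
  expect_error(predict_microbiota_age(ms, rel, ages - 100), "outside")
  expect_error(predict_microbiota_age(ms, rel), "need chronological")
})

test_that("training replica predictions track training ages", {
  co <- simulate_counts(cohort_spec(n_samples = 300, seed = 8))
  healthy <- co$metadata$group == "control"
  rel <- relative_abundance(co$genus_table)[healthy, ]
  ages <- co$metadata$age[healthy]
  m <- train_age_model(rel, ages, ntree = 300, seed = 1)
  expect_gt(m$oob_r2, 0.6)   # synthetic monotone benchmark
  pred <- predict_microbiota_age(m, rel)
  expect_gte(cor(pred, ages), 0.9)
  # degenerate all-zero profile predicts inside the training range
  zero <- matrix(0, 1, ncol(rel), dimnames = list(NULL, colnames(rel)))
  pz <- predict_microbiota_age(m, zero)
  expect_true(pz >= min(ages) && pz <= max(ages))
})

test_that("MAZ follows its formula and centers the reference", {
  ref <- build_healthy_reference(c(1, 2, 3, 10, 11, 12, 14),
                                 c(1, 1.5, 2, 5, 6, 7, 8))
  med1 <- median(c(1, 2, 3))
  sd1 <- sd(c(1, 2, 3))
  r1 <- compute_maz(med1, 2, ref)
  expect_equal(r1$maz, 0)
  r2 <- compute_maz(med1 + sd1, 2, ref)
  expect_equal(r2$maz, 1)
  # reference population has per-stratum median MAZ 0 by construction
  maz_ref <- compute_maz(c(1, 2, 3, 10, 11, 12, 14),
                         c(1, 1.5, 2, 5, 6, 7, 8), ref)
  expect_true(all(abs(tapply(maz_ref$maz, maz_ref$age < 3, median)) < 1e-12))
  expect_error(compute_maz(5, 50, ref), "does not cover")
  expect_error(build_healthy_reference(c(2, 2, 2), c(1, 1.2, 2)),
               "zero/undefined")
})
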