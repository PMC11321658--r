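#' Rank age-discriminatory genera
#'
#' Trains `n_iter` regression forests of chronological age on genus
#' relative abundances under different seeds and ranks genera by their
#' mean importance rank across iterations (rank 1 = most important in an
#' iteration). The top `k` genera (default 30) form the
#' age-discriminatory panel.
#'
#' @param genus_table genus-level relative-abundance matrix
#'   (samples x genera) or an `otu_table` collapsed to genus.
#' @param ages numeric chronological ages (years), must vary.
#' @param k number of genera to select (default 30).
#' @param n_iter forest repetitions (default 100).
#' @param ntree trees per iteration (default 100; the ranking is a mean
#'   over iterations so small forests suffice).
#' @param seed base seed; iteration i uses `seed + i - 1`.
#' @return data.frame ordered by `mean_rank` with attribute `selected`
#'   containing the top-k genus names.
#' @export
select_age_discriminatory_taxa <- function(genus_table, ages, k = 30,
                                           n_iter = 100, ntree = 100,
                                           seed = 1) {
  x <- if (inherits(genus_table, "otu_table"))
    relative_abundance(genus_table) else as.matrix(genus_table)
  if (ncol(x) < 2) stop("need at least 2 genera")
  if (stats::var(ages) == 0) stop("ages must vary")
  if (k > ncol(x)) stop("k (", k, ") exceeds genus count (", ncol(x), ")")
  ranks <- matrix(NA_real_, n_iter, ncol(x))
  imps <- matrix(NA_real_, n_iter, ncol(x))
  for (i in seq_len(n_iter)) {
    fit <- gm_random_forest(x, ages, ntree = ntree, seed = seed + i - 1)
    imps[i, ] <- fit$importance
    ranks[i, ] <- rank(-fit$importance, ties.method = "average")
  }
  res <- data.frame(genus = colnames(x),
                    mean_rank = colMeans(ranks),
                    mean_importance = colMeans(imps))
  res <- res[order(res$mean_rank, res$genus), ]
  rownames(res) <- NULL
  attr(res, "selected") <- res$genus[seq_len(k)]
  res
}

age_strata_breaks <- c(0, 3, 10, 19, Inf)
age_strata_labels <- c("<3", "3-9", "10-18", ">18")

assign_stratum <- function(ages, breaks = age_strata_breaks) {
  s <- findInterval(ages, breaks, rightmost.closed = FALSE)
  s[ages < breaks[1]] <- NA
  s
}

#' Train microbiota-age regression model(s)
#'
#' Regression forest (500 trees, default mtry = p/3) of chronological age
#' on genus relative abundances. With `stratify = TRUE` one model is
#' trained per chronological-age stratum (<3, 3-9, 10-18, >18 years;
#' left-closed, last open-ended) and each needs at least
#' `min_stratum_n` training samples.
#'
#' @param genus_table genus relative-abundance matrix or genus-level
#'   `otu_table`.
#' @param ages chronological ages (years).
#' @param stratify train per-stratum models (default FALSE).
#' @param ntree trees (default 500).
#' @param min_stratum_n minimum samples per stratum (default 20).
#' @param seed optional seed.
#' @return `age_model` (single forest) or `age_model_set` (one per
#'   stratum); both expose out-of-bag R-squared.
#' @export
train_age_model <- function(genus_table, ages, stratify = FALSE,
                            ntree = 500, min_stratum_n = 20, seed = NULL) {
  x <- if (inherits(genus_table, "otu_table"))
    relative_abundance(genus_table) else as.matrix(genus_table)
  if (length(ages) != nrow(x)) stop("ages length must match samples")
  if (stats::var(ages) == 0) stop("ages must vary (constant-age training set)")
  if (!stratify) {
    fit <- gm_random_forest(x, ages, ntree = ntree, seed = seed)
    return(structure(list(forest = fit, genera = colnames(x),
                          age_range = range(ages), oob_r2 = fit$oob_r2),
                     class = "age_model"))
  }
  strata <- assign_stratum(ages)
  models <- vector("list", length(age_strata_labels))
  names(models) <- age_strata_labels
  for (s in seq_along(age_strata_labels)) {
    idx <- which(strata == s)
    if (length(idx) == 0)
      stop("empty age stratum: ", age_strata_labels[s])
    if (length(idx) < min_stratum_n)
      stop("stratum ", age_strata_labels[s], " has only ", length(idx),
           " samples (need >= ", min_stratum_n, ")")
    if (stats::var(ages[idx]) == 0)
      stop("ages constant within stratum ", age_strata_labels[s])
    fit <- gm_random_forest(x[idx, , drop = FALSE], ages[idx],
                            ntree = ntree, seed = seed)
    models[[s]] <- structure(list(forest = fit, genera = colnames(x),
                                  age_range = range(ages[idx]),
                                  oob_r2 = fit$oob_r2),
                             class = "age_model")
  }
  structure(list(models = models, breaks = age_strata_breaks,
                 labels = age_strata_labels),
            class = "age_model_set")
}

#' @export
print.age_model <- function(x, ...) {
  cat("Microbiota-age model:", length(x$genera), "genera, ages",
      round(x$age_range[1], 2), "-", round(x$age_range[2], 2),
      "| OOB R2:", round(x$oob_r2, 3), "\n")
  invisible(x)
}

#' @export
print.age_model_set <- function(x, ...) {
  cat("Stratified microbiota-age models:\n")
  for (nm in names(x$models)) {
    cat("  ", nm, ": OOB R2 ", round(x$models[[nm]]$oob_r2, 3), "\n",
        sep = "")
  }
  invisible(x)
}

#' Predict microbiota age
#'
#' Scores each sample with the regression forest; with a stratified model
#' set the model of the sample's chronological-age stratum is used, so
#' `ages` is then required. Missing genera are imputed as zero with a
#' warning; an all-zero abundance vector yields the forest's mean
#' response.
#'
#' @param model `age_model` or `age_model_set`.
#' @param genus_table genus relative-abundance matrix aligned by genus
#'   name.
#' @param ages chronological ages (needed for `age_model_set`).
#' @return numeric vector of microbiota ages (years).
#' @export
predict_microbiota_age <- function(model, genus_table, ages = NULL) {
  x <- if (inherits(genus_table, "otu_table"))
    relative_abundance(genus_table) else as.matrix(genus_table)
  if (inherits(model, "age_model"))
    return(unname(predict(model$forest, x)))
  stopifnot(inherits(model, "age_model_set"))
  if (is.null(ages))
    stop("stratified models need chronological ages")
  strata <- assign_stratum(ages, model$breaks)
  if (any(is.na(strata)))
    stop("age(s) outside all strata: ",
         paste(ages[is.na(strata)], collapse = ", "))
  out <- numeric(nrow(x))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    out[idx] <- predict(model$models[[s]]$forest, x[idx, , drop = FALSE])
  }
  out
}

#' Healthy reference for the microbiota-for-age Z score
#'
#' Per chronological-age stratum, the median and standard deviation of
#' microbiota age among healthy reference samples. By construction the
#' median MAZ of the reference population is 0 in every stratum.
#'
#' @param microbiota_ages predicted microbiota ages of healthy samples.
#' @param ages their chronological ages.
#' @param breaks stratum breakpoints (default the four bands <3, 3-9,
#'   10-18, >18 years).
#' @return data.frame of class `healthy_reference` with one row per
#'   stratum (`stratum`, `lower`, `upper`, `n`, `median_ma`, `sd_ma`).
#' @export
build_healthy_reference <- function(microbiota_ages, ages,
                                    breaks = age_strata_breaks) {
  stopifnot(length(microbiota_ages) == length(ages))
  s <- assign_stratum(ages, breaks)
  used <- sort(unique(s))
  ref <- data.frame(
    stratum = used,
    lower = breaks[used],
    upper = breaks[used + 1],
    n = as.integer(tabulate(s, nbins = length(breaks) - 1)[used]),
    median_ma = vapply(used, function(k) stats::median(
      microbiota_ages[s == k]), 0),
    sd_ma = vapply(used, function(k) stats::sd(
      microbiota_ages[s == k]), 0))
  bad <- ref$n < 2 | !is.finite(ref$sd_ma) | ref$sd_ma <= 0
  if (any(bad))
    stop("reference stratum with zero/undefined s.d.: ",
         paste(ref$stratum[bad], collapse = ", "))
  structure(ref, class = c("healthy_reference", "data.frame"),
            breaks = breaks)
}

#' Microbiota-for-age Z score
#'
#' MAZ = (microbiota age - median microbiota age of healthy reference of
#' the same chronological-age stratum) / (s.d. of microbiota age in that
#' stratum).
#'
#' @param microbiota_ages predicted microbiota ages.
#' @param chronological_ages chronological ages (years).
#' @param reference a `healthy_reference`.
#' @param sample_ids optional identifiers.
#' @return data.frame with `sample_id`, `age`, `microbiota_age`, `maz`.
#' @export
compute_maz <- function(microbiota_ages, chronological_ages, reference,
                        sample_ids = NULL) {
  stopifnot(inherits(reference, "healthy_reference"),
            length(microbiota_ages) == length(chronological_ages))
  breaks <- attr(reference, "breaks")
  s <- assign_stratum(chronological_ages, breaks)
  idx <- match(s, reference$stratum)
  if (any(is.na(idx)))
    stop("reference does not cover age(s): ",
         paste(unique(chronological_ages[is.na(idx)]), collapse = ", "))
  maz <- (microbiota_ages - reference$median_ma[idx]) / reference$sd_ma[idx]
  if (is.null(sample_ids)) sample_ids <- seq_along(maz)
  data.frame(sample_id = sample_ids, age = chronological_ages,
             microbiota_age = microbiota_ages, maz = maz)
}
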