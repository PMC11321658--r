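#' Covariate-adjusted per-feature association
#'
#' Per feature: a linear model of transformed relative abundance on the
#' group label plus fixed-effect covariates (age, BMI, sex, district, or
#' whatever is supplied), with Benjamini-Hochberg correction across
#' features. The default abundance transform is arcsine-square-root;
#' `"logtss"` (log10 of relative abundance with a pseudocount) is also
#' available. This is a covariate-adjusted stand-in for a full
#' multivariable association framework.
#'
#' @param feature_table relative-abundance matrix (samples x features) or
#'   an `otu_table`.
#' @param group binary or categorical grouping variable.
#' @param covariates data.frame of covariates (complete cases required).
#' @param transform `"arcsinsqrt"` (default) or `"logtss"`.
#' @return data.frame of class `association_result` with `feature`,
#'   `coefficient` (first non-reference group level), `se`, `p_value`,
#'   `q_value`, ordered by q.
#' @export
associate_features <- function(feature_table, group, covariates = NULL,
                               transform = c("arcsinsqrt", "logtss")) {
  transform <- match.arg(transform)
  x <- if (inherits(feature_table, "otu_table"))
    relative_abundance(feature_table) else as.matrix(feature_table)
  if (is.null(colnames(x))) colnames(x) <- paste0("feature", seq_len(ncol(x)))
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("group must have at least two levels")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (anyNA(covariates)) stop("covariates contain missing values")
    mm <- stats::model.matrix(~ ., data = covariates)
    qr_mm <- qr(cbind(stats::model.matrix(~ group), mm[, -1, drop = FALSE]))
    if (qr_mm$rank < ncol(qr_mm$qr)) {
      aliased <- colnames(qr_mm$qr)[setdiff(seq_len(ncol(qr_mm$qr)),
                                            qr_mm$pivot[seq_len(qr_mm$rank)])]
      stop("collinear covariate(s): ", paste(aliased, collapse = ", "))
    }
    dat0 <- data.frame(group = group, covariates)
  } else {
    dat0 <- data.frame(group = group)
  }
  y_all <- switch(transform,
                  arcsinsqrt = asin(sqrt(pmin(pmax(x, 0), 1))),
                  logtss = log10(x + 1e-6))
  res <- lapply(seq_len(ncol(x)), function(j) {
    dat <- dat0
    dat$y <- y_all[, j]
    if (stats::var(dat$y) == 0) {
      # constant feature: no association by definition
      return(data.frame(feature = colnames(x)[j], coefficient = 0,
                        se = 0, p_value = 1))
    }
    fit <- stats::lm(y ~ ., data = dat)
    co <- summary(fit)$coefficients
    grow <- grep("^group", rownames(co))[1]
    full <- stats::anova(fit)
    p_group <- full["group", "Pr(>F)"]
    data.frame(feature = colnames(x)[j],
               coefficient = co[grow, "Estimate"],
               se = co[grow, "Std. Error"],
               p_value = p_group)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$q_value, out$p_value, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("association_result", "data.frame")
  out
}

#' Spearman co-occurrence network
#'
#' All genus pairs within the selected samples: Spearman rho with
#' asymptotic p, Benjamini-Hochberg across pairs, then edges retained at
#' q < `fdr` and |rho| > `rho_min` (defaults 0.05 and 0.1). Constant
#' genera are skipped with a warning. Edge counts are reported by sign.
#'
#' @param genus_table genus abundance matrix or genus-level `otu_table`.
#' @param group_mask optional logical/index vector selecting the samples
#'   (e.g. one clinical group); needs >= 10 samples.
#' @param fdr FDR threshold (default 0.05).
#' @param rho_min absolute-correlation threshold (default 0.1).
#' @return list of class `correlation_network`: `edges` (data.frame with
#'   genus_a, genus_b, rho, p_value, q_value, sign), `n_positive`,
#'   `n_negative`, `nodes`, `n_samples`.
#' @export
spearman_network <- function(genus_table, group_mask = NULL, fdr = 0.05,
                             rho_min = 0.1) {
  x <- if (inherits(genus_table, "otu_table"))
    relative_abundance(genus_table) else as.matrix(genus_table)
  if (!is.null(group_mask)) x <- x[group_mask, , drop = FALSE]
  if (nrow(x) < 10) stop("need at least 10 samples in the group")
  keep <- apply(x, 2, function(v) stats::var(v) > 0)
  if (any(!keep))
    warning("constant genus skipped: ",
            paste(colnames(x)[!keep], collapse = ", "))
  x <- x[, keep, drop = FALSE]
  g <- colnames(x)
  pairs <- utils::combn(seq_along(g), 2)
  rho <- numeric(ncol(pairs))
  pv <- numeric(ncol(pairs))
  rx <- apply(x, 2, rank)
  n <- nrow(x)
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]
    j <- pairs[2, m]
    r <- stats::cor(rx[, i], rx[, j])
    rho[m] <- r
    # t approximation, as used for rank correlations at n >= 10
    tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
    pv[m] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  qv <- bh_adjust(pv)
  sel <- qv < fdr & abs(rho) > rho_min
  edges <- data.frame(genus_a = g[pairs[1, sel]],
                      genus_b = g[pairs[2, sel]],
                      rho = rho[sel], p_value = pv[sel],
                      q_value = qv[sel],
                      sign = ifelse(rho[sel] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges,
                 n_positive = sum(edges$sign == "positive"),
                 n_negative = sum(edges$sign == "negative"),
                 nodes = g, n_samples = n,
                 fdr = fdr, rho_min = rho_min),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("Co-occurrence network:", length(x$nodes), "genera,",
      x$n_positive, "positive and", x$n_negative, "negative edges",
      sprintf("(FDR < %g, |rho| > %g, n = %d)\n",
              x$fdr, x$rho_min, x$n_samples))
  invisible(x)
}

#' Write a network edge list
#' @param network a `correlation_network`.
#' @param path output TSV path.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

stratified_folds <- function(labels, n_folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Cross-validated random-forest classification AUC
#'
#' Stratified k-fold cross-validation (default tenfold) of a
#' classification forest (default 1000 trees); reports per-fold and mean
#' out-of-fold AUC. Deterministic under `seed` (which fixes both the
#' fold assignment and each fold's forest).
#'
#' @param feature_table feature matrix (samples x features) or
#'   `otu_table` (relative abundances are used).
#' @param labels binary labels (two-level factor / 0-1).
#' @param n_folds folds (default 10).
#' @param n_trees trees per forest (default 1000).
#' @param seed integer seed.
#' @return list of class `classifier_eval`: `fold_auc`, `mean_auc`,
#'   `folds` (assignment), `n_trees`.
#' @export
rf_classify_auc <- function(feature_table, labels, n_folds = 10,
                            n_trees = 1000, seed = 1) {
  x <- if (inherits(feature_table, "otu_table"))
    relative_abundance(feature_table) else as.matrix(feature_table)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("single-class input; need both classes")
  labels <- droplevels(labels)
  fold <- stratified_folds(labels, n_folds, seed = seed)
  pos <- levels(labels)[2]
  fold_auc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    te <- !tr
    if (length(unique(labels[tr])) < 2 || sum(te) == 0)
      stop("fold ", f, " lost a class; reduce n_folds")
    fit <- gm_random_forest(x[tr, , drop = FALSE], labels[tr],
                            ntree = n_trees, seed = seed + f)
    pr <- predict(fit, x[te, , drop = FALSE], type = "prob")[, pos]
    fold_auc[f] <- if (length(unique(labels[te])) < 2) NA_real_
    else auc_score(pr, labels[te] == pos)
  }
  structure(list(fold_auc = fold_auc,
                 mean_auc = mean(fold_auc, na.rm = TRUE),
                 folds = fold, n_trees = n_trees, n_folds = n_folds),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat("RF classification:", x$n_folds, "folds,", x$n_trees,
      "trees | mean AUC", round(x$mean_auc, 4), "\n")
  invisible(x)
}
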