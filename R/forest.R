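#' Random forest (built-in CART implementation)
#'
#' Bagged CART trees with random feature subsets at each split, impurity
#' importance and out-of-bag predictions. Regression trees split on
#' variance reduction; classification trees on Gini. The implementation is
#' self-contained (compiled) and seeded through R's RNG, so fits are
#' reproducible with `set.seed()` or the `seed` argument.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y response: numeric for regression, factor for classification.
#' @param ntree number of trees (default 500).
#' @param mtry features tried per split; defaults to `p/3` (regression) or
#'   `sqrt(p)` (classification), at least 1.
#' @param min_node minimum samples in a leaf (default 5 regression,
#'   1 classification).
#' @param max_depth maximum tree depth (default 25).
#' @param seed optional integer seed.
#' @return object of class `gm_rf` with elements `trees`, `importance`
#'   (mean impurity decrease per feature), `oob` (out-of-bag predictions:
#'   numeric vector or class-probability matrix), `oob_r2` (regression) or
#'   `oob_error` (classification), `type`, `levels`, `features`.
#' @export
gm_random_forest <- function(x, y, ntree = 500, mtry = NULL,
                             min_node = NULL, max_depth = 25, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (!is.null(seed)) set.seed(seed)
  classify <- is.factor(y) || is.character(y) || is.logical(y)
  if (classify) {
    y <- as.factor(y)
    lev <- levels(droplevels(y))
    y <- factor(y, levels = lev)
    yv <- as.numeric(y) - 1
    nclass <- length(lev)
    if (nclass < 2) stop("classification needs at least 2 classes")
    if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
    if (is.null(min_node)) min_node <- 1L
  } else {
    if (stats::var(y) == 0) stop("response is constant; it must vary")
    yv <- as.numeric(y)
    lev <- NULL
    nclass <- 0L
    if (is.null(mtry)) mtry <- max(1L, floor(ncol(x) / 3))
    if (is.null(min_node)) min_node <- 5L
  }
  mtry <- min(as.integer(mtry), ncol(x))
  fit <- rf_fit_cpp(x, yv, as.integer(ntree), mtry, as.integer(min_node),
                    as.integer(max_depth), classify, as.integer(nclass))
  out <- list(trees = fit$trees, importance = stats::setNames(
    fit$importance, colnames(x)), type = if (classify) "classification"
    else "regression", levels = lev, features = colnames(x),
    ntree = ntree, mtry = mtry)
  seen <- fit$oob_n > 0
  if (classify) {
    votes <- fit$oob_votes
    probs <- votes / pmax(fit$oob_n, 1)
    probs[!seen, ] <- NA
    colnames(probs) <- lev
    out$oob <- probs
    pred <- lev[max.col(probs, ties.method = "first")]
    out$oob_error <- mean(pred[seen] != as.character(y)[seen])
  } else {
    pred <- fit$oob_sum / pmax(fit$oob_n, 1)
    pred[!seen] <- NA
    out$oob <- pred
    out$oob_r2 <- 1 - mean((pred[seen] - yv[seen])^2) / stats::var(yv)
  }
  class(out) <- "gm_rf"
  out
}

#' @export
print.gm_rf <- function(x, ...) {
  cat("Random forest (", x$type, "): ", x$ntree, " trees, mtry ", x$mtry,
      "\n", sep = "")
  if (x$type == "regression") cat("OOB R2:", round(x$oob_r2, 4), "\n")
  else cat("OOB error:", round(x$oob_error, 4), "\n")
  invisible(x)
}

#' Predict from a `gm_rf` forest
#'
#' @param object a `gm_rf` fit.
#' @param newdata feature matrix; columns are matched to the training
#'   features by name when available, and genera absent from `newdata`
#'   are imputed as zero with a warning.
#' @param type `"response"` (default) or `"prob"` (classification only).
#' @param ... unused.
#' @return numeric vector, class vector, or probability matrix.
#' @export
predict.gm_rf <- function(object, newdata,
                          type = c("response", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata))) {
    missing <- setdiff(object$features, colnames(newdata))
    if (length(missing)) {
      warning("feature(s) absent from newdata imputed as 0: ",
              paste(missing, collapse = ", "))
      add <- matrix(0, nrow(newdata), length(missing),
                    dimnames = list(rownames(newdata), missing))
      newdata <- cbind(newdata, add)
    }
    newdata <- newdata[, object$features, drop = FALSE]
  }
  storage.mode(newdata) <- "double"
  classify <- object$type == "classification"
  res <- rf_predict_cpp(object$trees, newdata, classify,
                        as.integer(length(object$levels)))
  if (!classify) return(drop(res))
  colnames(res) <- object$levels
  if (type == "prob") return(res)
  object$levels[max.col(res, ties.method = "first")]
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUC with midrank tie handling.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels binary labels (logical, 0/1, or two-level factor whose
#'   second level is positive).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
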