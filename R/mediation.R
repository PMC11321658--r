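#' Logistic mediator score from a genus panel
#'
#' Collapses a genus panel into one per-sample mediator score: the fitted
#' probability from a logistic regression of the treatment label on the
#' panel's relative abundances. Perfect separation is caught and the
#' model refit with a small ridge penalty (with a warning), so scores
#' stay strictly inside (0, 1). The classifier's AUC is reported
#' alongside.
#'
#' @param genus_table genus relative-abundance matrix or genus-level
#'   `otu_table`.
#' @param treatment_labels binary treatment (0/1, logical, or two-level
#'   factor whose second level is treated).
#' @param panel character vector of genus names to combine.
#' @return list of class `mediator_score`: `score` (fitted
#'   probabilities), `auc`, `coefficients`, `ridged` (logical).
#' @export
build_mediator_score <- function(genus_table, treatment_labels, panel) {
  x <- if (inherits(genus_table, "otu_table"))
    relative_abundance(genus_table) else as.matrix(genus_table)
  missing <- setdiff(panel, colnames(x))
  if (length(missing))
    stop("panel genera absent from table: ",
         paste(missing, collapse = ", "))
  if (is.factor(treatment_labels))
    treatment_labels <- as.integer(treatment_labels) - 1L
  tr <- as.numeric(treatment_labels)
  if (!all(tr %in% c(0, 1))) stop("treatment must be binary 0/1")
  if (length(unique(tr)) < 2) stop("both treatment classes must be present")
  xm <- x[, panel, drop = FALSE]
  fit <- suppressWarnings(stats::glm(tr ~ xm, family = stats::binomial()))
  sep <- !fit$converged || any(fit$fitted.values > 1 - 1e-8) ||
    any(fit$fitted.values < 1e-8)
  ridged <- FALSE
  if (sep) {
    warning("perfect or quasi-perfect separation; refitting with a ",
            "ridge penalty")
    rf <- ridge_logistic(cbind(1, xm), tr, lambda = 1)
    score <- rf$fitted
    coefs <- rf$beta
    ridged <- TRUE
  } else {
    score <- fit$fitted.values
    coefs <- stats::coef(fit)
  }
  structure(list(score = unname(score), auc = auc_score(score, tr),
                 coefficients = coefs, ridged = ridged, panel = panel),
            class = "mediator_score")
}

# L2-penalized logistic regression by IRLS (intercept unpenalized)
ridge_logistic <- function(x, y, lambda = 1, max_iter = 100, tol = 1e-8) {
  p <- ncol(x)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(x * w)
    beta_new <- solve(xtw %*% x + pen, xtw %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  list(beta = drop(beta), fitted = stats::plogis(drop(x %*% beta)))
}

#' Mediation model specification
#'
#' @param treatment name of the binary treatment column (0/1 coded).
#' @param mediator name of the mediator column (or a `mediator_score`
#'   is passed to [fit_mediation()] separately).
#' @param outcome name of the outcome column; binary 0/1 or continuous.
#' @param covariates character vector of covariate columns (e.g. age,
#'   BMI, sex, UCCS use, district).
#' @param n_boot bootstrap resamples (default 5000).
#' @param seed integer seed.
#' @return list of class `mediation_spec`.
#' @export
mediation_spec <- function(treatment, mediator, outcome,
                           covariates = character(0), n_boot = 5000,
                           seed = 1) {
  stopifnot(n_boot >= 1)
  structure(list(treatment = treatment, mediator = mediator,
                 outcome = outcome, covariates = covariates,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "mediation_spec")
}

mediation_paths <- function(tr, m, y, covs) {
  xa <- cbind(1, tr, covs)
  a <- .lm.fit(xa, m)$coefficients[2]
  xb <- cbind(1, m, tr, covs)
  cf <- .lm.fit(xb, y)$coefficients
  b <- cf[2]
  c_prime <- cf[3]
  c(a = a, b = b, c_prime = c_prime, indirect = a * b,
    total = c_prime + a * b)
}

#' Fit the mediation model
#'
#' Standardized product-of-coefficients mediation with covariate
#' adjustment and a percentile bootstrap. The treatment, mediator,
#' outcome and continuous covariates are z-scored; path `a` is the
#' treatment coefficient in the mediator regression, paths `b` and `c'`
#' come from the outcome regression on mediator + treatment +
#' covariates. The outcome model is linear (linear-probability coding
#' when the outcome is binary) so the decomposition
#' `total = c' + a*b` holds exactly; a logistic-outcome option reports
#' `b` and `c'` on the log-odds scale instead (no exact decomposition).
#' The two-sided bootstrap p for the indirect effect is the fraction of
#' resampled estimates crossing zero (doubled, capped at 1).
#'
#' @param spec a `mediation_spec`.
#' @param data data.frame holding the spec's columns (n >= 50).
#' @param outcome_model `"linear"` (default) or `"logistic"`.
#' @return list of class `mediation_result`: standardized `a`, `b`,
#'   `c_prime`, `indirect` (= a*b), `total`, percentile `ci` (2.5/97.5)
#'   for each path, `p_indirect`, `n_boot`, `redraws`.
#' @export
fit_mediation <- function(spec, data, outcome_model = c("linear",
                                                        "logistic")) {
  stopifnot(inherits(spec, "mediation_spec"))
  outcome_model <- match.arg(outcome_model)
  if (nrow(data) < 50) stop("mediation needs n >= 50")
  tr_raw <- data[[spec$treatment]]
  if (is.factor(tr_raw)) tr_raw <- as.integer(tr_raw) - 1L
  if (!all(tr_raw %in% c(0, 1))) stop("treatment must be 0/1 coded")
  m_raw <- data[[spec$mediator]]
  if (stats::var(m_raw) == 0) stop("mediator is constant")
  y_raw <- data[[spec$outcome]]
  binary_y <- all(y_raw %in% c(0, 1))
  covs_raw <- if (length(spec$covariates))
    data.matrix(data[spec$covariates]) else NULL

  standardize <- function(v) {
    s <- stats::sd(v)
    if (s == 0) v - mean(v) else (v - mean(v)) / s
  }
  prep <- function(idx) {
    tr <- standardize(tr_raw[idx])
    m <- standardize(m_raw[idx])
    y <- standardize(y_raw[idx])
    covs <- if (is.null(covs_raw)) NULL
    else apply(covs_raw[idx, , drop = FALSE], 2, standardize)
    list(tr = tr, m = m, y = y, covs = covs)
  }

  n <- nrow(data)
  d <- prep(seq_len(n))
  if (outcome_model == "logistic") {
    if (!binary_y) stop("logistic outcome model needs a binary outcome")
    xa <- cbind(1, d$tr, d$covs)
    a <- .lm.fit(xa, d$m)$coefficients[2]
    gf <- stats::glm(y_raw ~ d$m + d$tr + d$covs,
                     family = stats::binomial())
    b <- stats::coef(gf)[2]
    c_prime <- stats::coef(gf)[3]
    est <- c(a = a, b = unname(b), c_prime = unname(c_prime),
             indirect = a * unname(b), total = NA_real_)
  } else {
    est <- mediation_paths(d$tr, d$m, d$y, d$covs)
  }

  set.seed(spec$seed)
  boot <- matrix(NA_real_, spec$n_boot, 5,
                 dimnames = list(NULL, names(est)))
  redraws <- 0L
  max_redraw <- 100L * spec$n_boot
  i <- 1L
  while (i <= spec$n_boot) {
    idx <- sample.int(n, replace = TRUE)
    if (length(unique(tr_raw[idx])) < 2 ||
        stats::var(m_raw[idx]) == 0) {
      redraws <- redraws + 1L
      if (redraws > max_redraw)
        stop("too many degenerate bootstrap resamples")
      next
    }
    db <- prep(idx)
    boot[i, ] <- if (outcome_model == "logistic") {
      ab <- .lm.fit(cbind(1, db$tr, db$covs), db$m)$coefficients[2]
      gb <- suppressWarnings(stats::glm(
        y_raw[idx] ~ db$m + db$tr + db$covs,
        family = stats::binomial()))
      bb <- stats::coef(gb)[2]
      c(ab, bb, stats::coef(gb)[3], ab * bb, NA_real_)
    } else {
      mediation_paths(db$tr, db$m, db$y, db$covs)
    }
    i <- i + 1L
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  ind <- boot[, "indirect"]
  p_ind <- 2 * min(mean(ind <= 0), mean(ind >= 0))
  p_ind <- min(max(p_ind, 1 / spec$n_boot), 1)
  structure(list(a = unname(est["a"]), b = unname(est["b"]),
                 c_prime = unname(est["c_prime"]),
                 indirect = unname(est["indirect"]),
                 total = unname(est["total"]),
                 ci = ci, p_indirect = p_ind, n_boot = spec$n_boot,
                 redraws = redraws, outcome_model = outcome_model),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation (", x$outcome_model, " outcome, ", x$n_boot,
      " bootstraps):\n", sep = "")
  cat(sprintf("  a = %.3f, b = %.3f, c' = %.3f\n", x$a, x$b, x$c_prime))
  cat(sprintf("  indirect a*b = %.3f [%.3f, %.3f], p = %.4g\n",
              x$indirect, x$ci["2.5%", "indirect"],
              x$ci["97.5%", "indirect"], x$p_indirect))
  invisible(x)
}
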