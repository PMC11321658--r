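#' Genus trajectory specification
#'
#' Describes how one genus' expected relative abundance moves with age
#' and disease. Classes:
#' \describe{
#'   \item{age_discriminatory}{logistic rise with age; disease rescales
#'     the level by `disease_multiplier` (depletion when < 1).}
#'   \item{stunted_colonization}{same logistic rise, but disease delays
#'     the maturation midpoint by `disease_delay` years.}
#'   \item{disrupted_colonization}{non-monotone Gaussian bump centred at
#'     `midpoint` with width `width`; disease rescales by the multiplier.}
#'   \item{persistent_overgrowth}{flat in health, elevated by
#'     `disease_multiplier` (> 1) at all ages in disease.}
#'   \item{background}{constant.}
#' }
#'
#' @param genus genus name.
#' @param class one of the five classes above.
#' @param baseline_log baseline log-weight (natural log scale).
#' @param midpoint maturation midpoint or bump centre (years).
#' @param slope logistic steepness / bump amplitude on the log scale.
#' @param disease_multiplier multiplicative disease effect on the weight
#'   (> 0; default 1).
#' @param disease_delay midpoint delay (years) in disease, used by the
#'   stunted class (default 0).
#' @param width bump width (years) for the disrupted class (default 2).
#' @return list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(genus, class = c("age_discriminatory",
                                             "stunted_colonization",
                                             "disrupted_colonization",
                                             "persistent_overgrowth",
                                             "background"),
                            baseline_log = 0, midpoint = 4, slope = 2,
                            disease_multiplier = 1, disease_delay = 0,
                            width = 2) {
  class <- match.arg(class)
  stopifnot(is.finite(slope), disease_multiplier > 0, width > 0)
  structure(list(genus = genus, class = class,
                 baseline_log = baseline_log, midpoint = midpoint,
                 slope = slope, disease_multiplier = disease_multiplier,
                 disease_delay = disease_delay, width = width),
            class = "trajectory_spec")
}

# log-weight of one genus for vectors of ages / disease flags
trajectory_log_weight <- function(ts, age, disease) {
  b <- ts$baseline_log
  switch(ts$class,
    age_discriminatory =
      b + ts$slope * stats::plogis(age - ts$midpoint) +
        disease * log(ts$disease_multiplier),
    stunted_colonization =
      b + ts$slope *
        stats::plogis(age - ts$midpoint - disease * ts$disease_delay) +
        disease * log(ts$disease_multiplier),
    disrupted_colonization =
      b + ts$slope * exp(-(age - ts$midpoint)^2 / (2 * ts$width^2)) +
        disease * log(ts$disease_multiplier),
    persistent_overgrowth =
      b + disease * log(ts$disease_multiplier),
    background = rep(b, length(age)))
}

#' Expected relative-abundance trajectories
#'
#' @param panel list of `trajectory_spec`s.
#' @param age numeric ages.
#' @param disease 0/1 disease flags.
#' @return matrix (samples x genera) of expected relative abundances;
#'   rows sum to 1.
#' @export
trajectory_means <- function(panel, age, disease) {
  lw <- vapply(panel, trajectory_log_weight, numeric(length(age)),
               age = age, disease = disease)
  if (length(age) == 1) lw <- matrix(lw, nrow = 1)
  w <- exp(lw)
  colnames(w) <- vapply(panel, `[[`, "", "genus")
  sweep(w, 1, rowSums(w), "/")
}

#' Default genus panel
#'
#' Forty genera emulating a pediatric gut cohort: eight
#' age-discriminatory maturation risers depleted in disease, six genera
#' whose colonization is stunted (midpoint delayed 6 years) in disease,
#' four transient colonizers disrupted in disease, four persistent
#' overgrowers (8-fold elevated in disease, mirroring
#' oral-pathogen expansion), and eighteen background genera.
#'
#' @param disease_delay midpoint delay applied to the stunted class
#'   (default 6 years).
#' @return list of `trajectory_spec`s.
#' @export
default_genus_panel <- function(disease_delay = 6) {
  risers <- c("Faecalibacterium", "Bacteroides", "Ruminococcus",
              "Akkermansia", "Roseburia", "Blautia", "Prevotella",
              "Alistipes")
  stunted <- c("Coprococcus", "Dorea", "Eubacterium", "Oscillibacter",
               "Anaerostipes", "Dialister")
  disrupted <- c("Bifidobacterium", "Clostridium", "Collinsella",
                 "Lachnospira")
  overgrow <- c("Veillonella", "Enterococcus", "Streptococcus",
                "Lactobacillus")
  background <- c("Parabacteroides", "Sutterella",
                  "Phascolarctobacterium", "Odoribacter", "Butyricimonas",
                  "Desulfovibrio", "Bilophila", "Fusobacterium",
                  "Megamonas", "Acidaminococcus", "Holdemanella",
                  "Catenibacterium", "Slackia", "Eggerthella",
                  "Gordonibacter", "Adlercreutzia", "Christensenella",
                  "Subdoligranulum")
  panel <- list()
  for (i in seq_along(risers))
    panel[[length(panel) + 1]] <- trajectory_spec(
      risers[i], "age_discriminatory",
      baseline_log = -1 + 0.25 * (i - 1), midpoint = 1 + (i - 1),
      slope = 3, disease_multiplier = 0.4)
  for (i in seq_along(stunted))
    panel[[length(panel) + 1]] <- trajectory_spec(
      stunted[i], "stunted_colonization",
      baseline_log = -1.5 + 0.3 * (i - 1), midpoint = 2 + 0.8 * (i - 1),
      slope = 3, disease_delay = disease_delay)
  for (i in seq_along(disrupted))
    panel[[length(panel) + 1]] <- trajectory_spec(
      disrupted[i], "disrupted_colonization",
      baseline_log = -0.5 + 0.2 * (i - 1), midpoint = 2.5 + 1.2 * (i - 1),
      slope = 2, disease_multiplier = 0.3, width = 2)
  for (i in seq_along(overgrow))
    panel[[length(panel) + 1]] <- trajectory_spec(
      overgrow[i], "persistent_overgrowth",
      baseline_log = -1 + 0.3 * (i - 1), disease_multiplier = 8)
  for (i in seq_along(background))
    panel[[length(panel) + 1]] <- trajectory_spec(
      background[i], "background",
      baseline_log = -2.5 + 0.15 * (i - 1))
  panel
}

#' Cohort specification
#'
#' @param n_samples cohort size (>= 2; default 200).
#' @param age_range uniform age range in years (default 0-20, matching a
#'   pediatric skew).
#' @param prevalence disease prevalence in (0, 1) (default 0.3).
#' @param panel list of `trajectory_spec`s (default
#'   [default_genus_panel()]).
#' @param otus_per_genus OTUs per genus (default 10), with abundance
#'   split by a fixed geometric series.
#' @param theta Dirichlet concentration (default 50; lower = more
#'   compositional overdispersion).
#' @param depth_range sequencing depth drawn uniformly from this range
#'   (default 5000-20000; minimum allowed 100).
#' @param mediation list with standardized paths `a`, `b`, `c_prime`
#'   (defaults 0.5, 0.4, 0.2).
#' @param covariate_effects named effects of standardized covariates on
#'   the mediator (default 0.1 each for age and bmi).
#' @param seed default seed for [simulate_counts()].
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 200, age_range = c(0, 20),
                        prevalence = 0.3, panel = default_genus_panel(),
                        otus_per_genus = 10, theta = 50,
                        depth_range = c(5000, 20000),
                        mediation = list(a = 0.5, b = 0.4, c_prime = 0.2),
                        covariate_effects = c(age = 0.1, bmi = 0.1),
                        seed = 1) {
  if (length(panel) == 0) stop("genus panel is empty")
  stopifnot(n_samples >= 2, prevalence > 0, prevalence < 1,
            otus_per_genus >= 1, theta > 0, min(depth_range) >= 100)
  structure(list(n_samples = as.integer(n_samples), age_range = age_range,
                 prevalence = prevalence, panel = panel,
                 otus_per_genus = as.integer(otus_per_genus),
                 theta = theta, depth_range = depth_range,
                 mediation = mediation,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate Dirichlet-multinomial counts for a cohort
#'
#' Draws ages, disease status and covariates, evaluates each genus'
#' trajectory mean, and samples genus counts from a
#' Dirichlet-multinomial with concentration `theta` at a per-sample
#' depth drawn uniformly from `depth_range`. Genus counts are then split
#' over `otus_per_genus` OTUs by a fixed geometric series (ratio 0.6),
#' so both OTU- and genus-level stages have structure. Every sample's
#' row sum equals its drawn depth exactly.
#'
#' @param spec a `cohort_spec`.
#' @param seed integer seed (default `spec$seed`).
#' @return list of class `generated_cohort`: `table` (`otu_table`),
#'   `genus_table` (genus-level `otu_table`), `taxonomy`
#'   (`taxonomy_map`), `metadata` (`sample_metadata`), `ground_truth`
#'   (trajectory means, class map, depths).
#' @export
simulate_counts <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_samples
  ages <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  disease <- stats::rbinom(n, 1, spec$prevalence)
  sex <- stats::rbinom(n, 1, 0.5)
  bmi <- 15 + 0.25 * ages + stats::rnorm(n, 0, 2)
  district <- sample.int(5, n, replace = TRUE)
  uccs <- stats::rbinom(n, 1, ifelse(disease == 1, 0.9, 0.05))
  depths <- floor(stats::runif(n, spec$depth_range[1],
                               spec$depth_range[2] + 1))

  mu <- trajectory_means(spec$panel, ages, disease)
  genera <- colnames(mu)
  g <- length(genera)

  # Dirichlet-multinomial: p ~ Dir(theta * mu), counts ~ Mult(depth, p)
  genus_counts <- matrix(0L, n, g, dimnames = list(NULL, genera))
  for (i in seq_len(n)) {
    gam <- stats::rgamma(g, shape = spec$theta * mu[i, ])
    p <- gam / sum(gam)
    genus_counts[i, ] <- stats::rmultinom(1, depths[i], p)
  }

  k <- spec$otus_per_genus
  split_probs <- 0.6^(seq_len(k) - 1)
  split_probs <- split_probs / sum(split_probs)
  otu_counts <- matrix(0L, n, g * k)
  otu_ids <- character(g * k)
  lineages <- character(g * k)
  for (j in seq_len(g)) {
    cols <- (j - 1) * k + seq_len(k)
    otu_ids[cols] <- sprintf("OTU_%s_%02d", genera[j], seq_len(k))
    lineages[cols] <- paste0("k__Bacteria; p__Unspecified; c__; o__; f__; g__",
                             genera[j], "; s__")
    nz <- which(genus_counts[, j] > 0)
    if (length(nz))
      otu_counts[nz, cols] <- t(vapply(nz, function(i)
        stats::rmultinom(1, genus_counts[i, j], split_probs)[, 1],
        integer(k)))
  }
  sample_ids <- sprintf("S%04d", seq_len(n))
  colnames(otu_counts) <- otu_ids
  rownames(otu_counts) <- sample_ids
  rownames(genus_counts) <- sample_ids

  meta <- sample_metadata(data.frame(
    sample_id = sample_ids, age = ages,
    group = ifelse(disease == 1, "disease", "control"),
    sex = sex, bmi = bmi, district = district, uccs = uccs,
    stringsAsFactors = FALSE))
  classes <- vapply(spec$panel, `[[`, "", "class")
  names(classes) <- genera
  structure(list(
    table = otu_table(otu_counts),
    genus_table = otu_table(genus_counts),
    taxonomy = taxonomy_map(otu_ids, lineages),
    metadata = meta,
    ground_truth = list(trajectory_mean = mu, classes = classes,
                        depths = depths, disease = disease, seed = seed)),
    class = "generated_cohort")
}

#' Simulate mediation outcomes for a cohort
#'
#' Builds the treatment -> mediator -> outcome chain with known
#' standardized paths. With the treatment indicator standardized, the
#' mediator is `M = a*T + covariate terms + noise` with unit variance;
#' the continuous comorbidity score is `Y = b*M + c'*T + covariate terms
#' + noise`, also standardized, so a standardized linear estimator
#' recovers `a`, `b`, `c'` consistently. A binary comorbidity flag is
#' additionally drawn from a logistic link with linear predictor
#' `b*M + c'*T + covariates` and an intercept set for the target
#' prevalence. The true indirect effect `a*b` is recorded in the ground
#' truth.
#'
#' @param cohort a `generated_cohort`.
#' @param a,b,c_prime standardized path coefficients (|a|, |b| <= 5).
#' @param seed integer seed.
#' @param outcome_prevalence target prevalence of the binary flag
#'   (default 0.3).
#' @return the cohort with `metadata` gaining `mediator`,
#'   `comorbidity_score`, `comorbidity_flag` columns and `ground_truth`
#'   gaining the true paths.
#' @export
simulate_mediation_outcomes <- function(cohort, a = 0.5, b = 0.4,
                                        c_prime = 0.2, seed = 1,
                                        outcome_prevalence = 0.3) {
  stopifnot(inherits(cohort, "generated_cohort"))
  if (abs(a) > 5 || abs(b) > 5)
    stop("implausibly large path coefficient (|a|, |b| must be <= 5)")
  set.seed(seed)
  md <- cohort$metadata
  n <- nrow(md)
  tr <- as.numeric(md$group == "disease")
  tstd <- as.numeric(scale(tr))
  covs <- cbind(age = as.numeric(scale(md$age)),
                bmi = as.numeric(scale(md$bmi)))
  gamma <- c(0.1, 0.1)
  sd_m <- sqrt(max(1 - a^2 - sum(gamma^2), 0.05))
  m <- a * tstd + drop(covs %*% gamma) + stats::rnorm(n, 0, sd_m)

  delta <- c(0.1, 0.1)
  # Var(Y) = b^2 + c'^2 + |delta|^2 + 2abc' + 2b*gamma.delta + sd_y^2,
  # so subtract the covariance terms too to land Var(Y) = 1
  sd_y <- sqrt(max(1 - b^2 - c_prime^2 - sum(delta^2) -
                     2 * a * b * c_prime - 2 * b * sum(gamma * delta),
                   0.05))
  y_score <- b * m + c_prime * tstd + drop(covs %*% delta) +
    stats::rnorm(n, 0, sd_y)

  lp <- b * m + c_prime * tstd + drop(covs %*% delta)
  intercept <- stats::qlogis(outcome_prevalence)
  y_flag <- stats::rbinom(n, 1, stats::plogis(intercept + lp))

  md$mediator <- m
  md$comorbidity_score <- y_score
  md$comorbidity_flag <- y_flag
  cohort$metadata <- sample_metadata(md)
  cohort$ground_truth$paths <- list(a = a, b = b, c_prime = c_prime,
                                    indirect = a * b)
  cohort
}

#' Generate a full synthetic cohort
#'
#' Composes [simulate_counts()] and [simulate_mediation_outcomes()]
#' (using `spec$mediation`) and optionally writes all artifacts to disk
#' in the package's plain-text formats: OTU TSV, taxonomy TSV, metadata
#' CSV and ground-truth JSON.
#'
#' @param spec a `cohort_spec`.
#' @param dir optional output directory (created if missing).
#' @param seed integer seed (default `spec$seed`).
#' @return a `generated_cohort`.
#' @export
generate_cohort <- function(spec, dir = NULL, seed = spec$seed) {
  cohort <- simulate_counts(spec, seed = seed)
  med <- spec$mediation
  cohort <- simulate_mediation_outcomes(cohort, a = med$a, b = med$b,
                                        c_prime = med$c_prime,
                                        seed = seed + 1)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_otu_table(cohort$table, file.path(dir, "otu_table.tsv"))
    write_taxonomy(cohort$taxonomy, file.path(dir, "taxonomy.tsv"))
    write_sample_metadata(cohort$metadata, file.path(dir, "metadata.csv"))
    gt <- cohort$ground_truth
    jsonlite::write_json(
      list(classes = as.list(gt$classes), depths = gt$depths,
           disease = gt$disease, paths = gt$paths, seed = gt$seed,
           trajectory_mean = gt$trajectory_mean),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  cohort
}

#' @export
print.generated_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$metadata), "samples,",
      length(unique(x$taxonomy$genus)), "genera,",
      length(x$table$otu_ids), "OTUs\n")
  cat("disease prevalence:",
      round(mean(x$metadata$group == "disease"), 3), "\n")
  invisible(x)
}
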