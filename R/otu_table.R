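#' OTU count table
#'
#' The pipeline's universal input: a non-negative integer count matrix with
#' samples as rows and OTUs as columns, plus ordered sample and OTU
#' identifiers. Duplicated identifiers and negative or non-integer counts are
#' rejected at construction, so every downstream stage can assume a valid
#' table.
#'
#' @param counts numeric matrix (samples x OTUs) of non-negative integers.
#' @param sample_ids,otu_ids optional identifier vectors; default to the
#'   matrix dimnames.
#' @return an object of class `otu_table` wrapping the validated matrix.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (length(sample_ids) != nrow(counts))
    stop("sample_ids length (", length(sample_ids),
         ") does not match row count (", nrow(counts), ")")
  if (length(otu_ids) != ncol(counts))
    stop("otu_ids length (", length(otu_ids),
         ") does not match column count (", ncol(counts), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU identifiers: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (!is.numeric(counts))
    stop("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-finite count at sample '", sample_ids[bad[1, 1]],
         "', OTU '", otu_ids[bad[1, 2]], "'")
  bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-integer count at sample '", sample_ids[bad[1, 1]],
         "', OTU '", otu_ids[bad[1, 2]], "'")
  counts <- round(counts)
  dimnames(counts) <- list(sample_ids, otu_ids)
  structure(list(counts = counts, sample_ids = sample_ids,
                 otu_ids = otu_ids),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", length(x$sample_ids), "samples x",
      length(x$otu_ids), "OTUs\n")
  d <- sample_depths(x)
  cat("depth range:", min(d), "-", max(d), "\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Per-sample sequencing depth
#' @param table an `otu_table`.
#' @return named integer vector of row sums.
#' @export
sample_depths <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  rowSums(table$counts)
}

#' Subset an OTU table
#' @param x an `otu_table`.
#' @param samples,otus index or name vectors; missing means keep all.
#' @param ... unused.
#' @export
subset_otu_table <- function(x, samples = NULL, otus = NULL, ...) {
  stopifnot(inherits(x, "otu_table"))
  m <- x$counts
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  if (!is.null(otus)) m <- m[, otus, drop = FALSE]
  otu_table(m)
}

#' Read an OTU table from TSV or dense BIOM-JSON
#'
#' TSV files are expected to carry a header row and identifiers in the first
#' column. The default orientation is samples-as-rows; files whose header
#' starts with `#OTU ID` follow the QIIME convention (OTUs as rows) and are
#' transposed automatically, overriding `orientation`. The BIOM reader
#' accepts the dense-matrix JSON subset (`matrix_type: "dense"`), where rows
#' are observations (OTUs) and columns are samples.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param orientation for TSV: `"samples"` (rows are samples, default) or
#'   `"otus"` (rows are OTUs).
#' @return an `otu_table`.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom"),
                           orientation = c("samples", "otus")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    b <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(b$matrix_type) || b$matrix_type != "dense")
      stop("only dense BIOM-JSON is supported (matrix_type = 'dense')")
    m <- b$data
    if (is.list(m)) m <- do.call(rbind, m)
    m <- as.matrix(m)
    otus <- if (is.data.frame(b$rows)) b$rows$id else
      vapply(b$rows, function(r) r$id, "")
    samples <- if (is.data.frame(b$columns)) b$columns$id else
      vapply(b$columns, function(r) r$id, "")
    return(otu_table(t(m), sample_ids = samples, otu_ids = otus))
  }
  header <- readLines(path, n = 1L)
  fields <- strsplit(header, "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric count in column '", colnames(m)[bad[1, 2]],
         "', row '", ids[bad[1, 1]], "'")
  }
  rownames(m) <- ids
  qiime <- identical(fields[1], "#OTU ID")
  if (qiime || orientation == "otus") m <- t(m)
  otu_table(m)
}

#' Write an OTU table
#'
#' @param table an `otu_table`.
#' @param path output path.
#' @param format `"tsv"` (samples as rows) or `"biom"` (dense BIOM-JSON,
#'   OTUs as rows per the BIOM convention).
#' @export
write_otu_table <- function(table, path, format = c("tsv", "biom")) {
  stopifnot(inherits(table, "otu_table"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(sample_id = table$sample_ids,
                     table$counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    obj <- list(
      id = "gutmaz", format = "1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table", matrix_type = "dense",
      matrix_element_type = "int",
      shape = c(length(table$otu_ids), length(table$sample_ids)),
      rows = data.frame(id = table$otu_ids),
      columns = data.frame(id = table$sample_ids),
      data = unname(t(table$counts)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a taxonomy map
#'
#' Two-column TSV: OTU identifier and a semicolon-separated lineage using
#' the usual rank prefixes (`k__`, `p__`, `c__`, `o__`, `f__`, `g__`,
#' `s__`). Ranks below genus may be missing; OTUs with an empty or missing
#' genus field are treated as unassigned at genus level.
#'
#' @param path file path.
#' @return data.frame with columns `otu_id`, `lineage`, `genus` (NA when
#'   unassigned), of class `taxonomy_map`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  names(df)[1:2] <- c("otu_id", "lineage")
  taxonomy_map(df$otu_id, df$lineage)
}

#' Construct a taxonomy map
#' @param otu_id character vector of OTU identifiers.
#' @param lineage character vector of semicolon-separated lineages.
#' @return `taxonomy_map` data.frame.
#' @export
taxonomy_map <- function(otu_id, lineage) {
  stopifnot(length(otu_id) == length(lineage))
  if (anyDuplicated(otu_id))
    stop("duplicate OTU identifiers in taxonomy: ",
         paste(unique(otu_id[duplicated(otu_id)]), collapse = ", "))
  genus <- vapply(strsplit(lineage, ";"), function(parts) {
    parts <- trimws(parts)
    g <- parts[startsWith(parts, "g__")]
    if (length(g) == 0) return(NA_character_)
    g <- sub("^g__", "", g[1])
    if (!nzchar(g)) NA_character_ else g
  }, "")
  structure(data.frame(otu_id = as.character(otu_id),
                       lineage = as.character(lineage),
                       genus = genus, stringsAsFactors = FALSE),
            class = c("taxonomy_map", "data.frame"))
}

#' Write a taxonomy map
#' @param tax a `taxonomy_map`.
#' @param path output path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax[, c("otu_id", "lineage")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse an OTU table to genus level
#'
#' Genus counts are the exact sums of their member OTU counts, so total
#' counts per sample are conserved. OTUs without a genus assignment are
#' pooled into a declared `unassigned` column rather than dropped, keeping
#' count conservation testable.
#'
#' @param table an `otu_table`.
#' @param tax a `taxonomy_map` covering at least one OTU of the table.
#' @param unassigned_label column name for the pooled unassigned OTUs.
#' @return genus-level `otu_table`.
#' @export
collapse_to_genus <- function(table, tax, unassigned_label = "unassigned") {
  stopifnot(inherits(table, "otu_table"))
  genus <- tax$genus[match(table$otu_ids, tax$otu_id)]
  if (all(is.na(match(table$otu_ids, tax$otu_id))))
    stop("taxonomy covers none of the table's OTUs")
  genus[is.na(genus)] <- unassigned_label
  agg <- t(rowsum(t(table$counts), group = genus))
  # deterministic column order: descending total, ties by name
  ord <- order(-colSums(agg), colnames(agg))
  agg <- agg[, ord, drop = FALSE]
  otu_table(agg, sample_ids = table$sample_ids)
}

#' Relative abundance transform
#'
#' @param table an `otu_table` or a non-negative numeric matrix
#'   (samples x features).
#' @return matrix of row-normalized proportions; each row sums to 1.
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  d <- rowSums(m)
  zero <- d <= 0
  if (any(zero))
    stop("zero-depth sample(s): ",
         paste(rownames(m)[zero], collapse = ", "))
  sweep(m, 1, d, "/")
}

#' Read sample metadata
#'
#' CSV with one row per sample. Required columns: `sample_id`, `age`
#' (years, fractional allowed), `group`. Optional: `sex`, `bmi`,
#' `district`, `uccs` and any number of 0/1 comorbidity flag columns.
#'
#' @param path file path.
#' @return validated data.frame of class `sample_metadata`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Validate sample metadata
#' @param df data.frame with at least `sample_id`, `age`, `group`.
#' @return the validated data.frame, classed `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "age", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (any(!is.finite(df$age)) || any(df$age < 0))
    stop("age must be finite and >= 0")
  flags <- grep("^comorbidity(?!.*_score$)", names(df), value = TRUE,
                perl = TRUE)
  for (fl in c(flags, intersect("uccs", names(df)))) {
    v <- df[[fl]]
    if (!all(v %in% c(0, 1)))
      stop("column '", fl, "' must be 0/1 coded")
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Write sample metadata
#' @param meta `sample_metadata` data.frame.
#' @param path output path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of every stage in one serializable
#' object with documented defaults.
#'
#' @param seed integer random seed.
#' @param rarefaction_fraction fraction of the minimum depth used as the
#'   rarefaction target (default 0.9).
#' @param n_resamples rarefaction resample count (default 100).
#' @param rare_otu_fraction prevalence filter threshold as a fraction of
#'   total sequences (default 1e-5, i.e. 0.001 percent).
#' @param n_trees_regression,n_trees_classification forest sizes
#'   (defaults 500 and 1000).
#' @param n_taxa_iterations iterations for taxa ranking (default 100).
#' @param k_taxa number of age-discriminatory genera retained (default 30).
#' @param image_side image side length L (default 256).
#' @param corr_threshold genus-correlation threshold for the layout
#'   (default 0.75).
#' @param n_boot mediation bootstrap count (default 5000).
#' @param extra named list of additional stage parameters.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, rarefaction_fraction = 0.9,
                            n_resamples = 100L, rare_otu_fraction = 1e-5,
                            n_trees_regression = 500L,
                            n_trees_classification = 1000L,
                            n_taxa_iterations = 100L, k_taxa = 30L,
                            image_side = 256L, corr_threshold = 0.75,
                            n_boot = 5000L, extra = list()) {
  stopifnot(rarefaction_fraction > 0, rarefaction_fraction <= 1,
            n_resamples >= 1, rare_otu_fraction >= 0,
            rare_otu_fraction < 1, corr_threshold >= 0, corr_threshold <= 1,
            image_side >= 8, n_boot >= 1)
  structure(list(seed = as.integer(seed),
                 rarefaction_fraction = rarefaction_fraction,
                 n_resamples = as.integer(n_resamples),
                 rare_otu_fraction = rare_otu_fraction,
                 n_trees_regression = as.integer(n_trees_regression),
                 n_trees_classification = as.integer(n_trees_classification),
                 n_taxa_iterations = as.integer(n_taxa_iterations),
                 k_taxa = as.integer(k_taxa),
                 image_side = as.integer(image_side),
                 corr_threshold = corr_threshold,
                 n_boot = as.integer(n_boot), extra = extra),
            class = "pipeline_config")
}

#' Read/write pipeline configuration as JSON
#' @param path file path.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
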