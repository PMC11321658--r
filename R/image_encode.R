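#' Select the most abundant OTUs
#'
#' Keeps the `n` OTUs with the highest grand-total abundance (all of them
#' if fewer exist), with ties at the cutoff broken by OTU identifier in
#' lexicographic order. `n` defaults to the number of pixels of the
#' default image side (256^2 = 65536).
#'
#' @param table an `otu_table`.
#' @param n number of OTUs to retain (default 65536).
#' @return `otu_table` subset, columns ordered by descending abundance
#'   (ties by id).
#' @export
select_top_otus <- function(table, n = 65536) {
  stopifnot(inherits(table, "otu_table"))
  tot <- colSums(table$counts)
  ord <- order(-tot, table$otu_ids)
  keep <- ord[seq_len(min(n, length(ord)))]
  subset_otu_table(table, otus = keep)
}

# 32-bit FNV-1a over a string, with the multiply done in 16-bit halves so
# doubles never lose precision
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  prime <- 16777619
  two16 <- 65536
  two32 <- 4294967296
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% two16), b) + (h %/% two16) * two16
    lo <- h %% two16
    hi <- h %/% two16
    h <- (lo * prime + ((hi * prime) %% two16) * two16) %% two32
  }
  sprintf("%04x%04x", h %/% two16, h %% two16)
}

#' Build the genus pixel layout
#'
#' Orders genera for the image encoder: compute pairwise Spearman
#' correlations of genus relative abundances, retain edges with absolute
#' correlation strictly above `corr_threshold` (default 0.75), then place
#' genera by descending mean abundance -- and whenever a genus is placed,
#' its retained partners that are not yet placed are placed immediately
#' after it (by descending abundance among the partners, depth-first).
#' Each genus receives a contiguous row-major pixel block sized to its
#' retained OTU count; member OTUs are ordered inside the block by
#' descending grand-total abundance (ties by id).
#'
#' @param genus_table genus-level `otu_table` or abundance matrix
#'   (samples x genera).
#' @param table OTU-level `otu_table` (already passed through
#'   [select_top_otus()]).
#' @param tax a `taxonomy_map` linking OTUs to genera.
#' @param corr_threshold correlation threshold (default 0.75, strict).
#' @param L image side; the blocks must tile at most L^2 pixels.
#' @return object of class `genus_layout`: `blocks` (data.frame with
#'   genus, start, length, corr_weight), `otu_ids` (pixel order),
#'   `corr_threshold`, `hash`.
#' @export
build_genus_layout <- function(genus_table, table, tax,
                               corr_threshold = 0.75, L = 256) {
  gm <- if (inherits(genus_table, "otu_table"))
    relative_abundance(genus_table) else as.matrix(genus_table)
  if (ncol(gm) < 1) stop("need at least one genus")
  genera <- colnames(gm)

  const <- apply(gm, 2, function(v) stats::var(v) == 0 || !is.finite(stats::var(v)))
  if (any(const))
    warning("constant genus abundance; no correlation edges for: ",
            paste(genera[const], collapse = ", "))
  rho <- suppressWarnings(stats::cor(gm, method = "spearman"))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 0
  adj <- abs(rho) > corr_threshold

  mean_ab <- colMeans(gm)
  placed <- character(0)
  remaining <- genera[order(-mean_ab, genera)]
  place <- function(g) {
    if (g %in% placed) return(invisible(NULL))
    placed <<- c(placed, g)
    partners <- genera[adj[g, ]]
    partners <- setdiff(partners, placed)
    for (p in partners[order(-mean_ab[partners], partners)]) place(p)
    invisible(NULL)
  }
  for (g in remaining) place(g)

  # member OTUs per genus, ordered by descending grand total then id
  genus_of <- tax$genus[match(table$otu_ids, tax$otu_id)]
  tot <- colSums(table$counts)
  blocks <- data.frame(genus = placed, start = NA_integer_,
                       length = NA_integer_, corr_weight = NA_real_,
                       stringsAsFactors = FALSE)
  otu_order <- character(0)
  pos <- 1L
  for (i in seq_along(placed)) {
    g <- placed[i]
    members <- table$otu_ids[!is.na(genus_of) & genus_of == g]
    members <- members[order(-tot[members], members)]
    blocks$start[i] <- pos
    blocks$length[i] <- length(members)
    w <- abs(rho[g, ])[adj[g, ]]
    blocks$corr_weight[i] <- if (length(w)) max(w) else 0
    otu_order <- c(otu_order, members)
    pos <- pos + length(members)
  }
  if (length(otu_order) > L^2)
    stop("layout needs ", length(otu_order), " pixels but the image has ",
         L^2, "; raise L or pre-filter with select_top_otus()")
  hash <- fnv1a32(paste(blocks$genus, blocks$start, blocks$length,
                        round(blocks$corr_weight, 6), collapse = "|"))
  structure(list(blocks = blocks, otu_ids = otu_order,
                 corr_threshold = corr_threshold, L = L, hash = hash),
            class = "genus_layout")
}

#' @export
print.genus_layout <- function(x, ...) {
  cat("Genus layout:", nrow(x$blocks), "genera,", length(x$otu_ids),
      "pixels, threshold >", x$corr_threshold, ", hash", x$hash, "\n")
  invisible(x)
}

#' Log transform of relative abundance to pixel intensity
#'
#' `t = clamp(2 * (log10(a) - log10(eps)) / (0 - log10(eps)) - 1, -1, 1)`
#' with floor `eps = 1e-6`; `a = 0` is pinned to `t = -1`. The pixel is
#' `round((t + 1) / 2 * 255)`, so 0 maps to pixel 0 and 1 maps to 255,
#' monotonically.
#'
#' @param a relative abundances in [0, 1].
#' @param eps log floor (default 1e-6).
#' @return integer pixel values 0-255.
#' @export
abundance_to_pixel <- function(a, eps = 1e-6) {
  if (any(a < 0 | a > 1))
    stop("abundance outside [0, 1]")
  t <- rep(-1, length(a))
  pos <- a > 0
  t[pos] <- 2 * (log10(a[pos]) - log10(eps)) / (0 - log10(eps)) - 1
  t <- pmin(pmax(t, -1), 1)
  as.integer(round((t + 1) / 2 * 255))
}

#' Encode one sample as a microbiota image
#'
#' Three channels on an L x L grid filled row-major along the layout:
#' (1) OTU-level abundance intensity per pixel, (2) the genus-level
#' summed abundance broadcast over the genus block, (3) the genus'
#' maximum retained correlation weight (|rho| scaled to 0-255) broadcast
#' over the block. Unused pixels are 0, and a zero-abundance OTU gives a
#' zero pixel in channel 1.
#'
#' @param sample_abundances named numeric vector of OTU relative
#'   abundances for one sample (names matched to the layout's OTUs;
#'   OTUs absent from the vector count as 0).
#' @param layout a `genus_layout`.
#' @param L image side (default the layout's L).
#' @return integer array `c(L, L, 3)` of class `microbiota_image`.
#' @export
encode_image <- function(sample_abundances, layout, L = layout$L) {
  stopifnot(inherits(layout, "genus_layout"))
  if (length(layout$otu_ids) > L^2)
    stop("layout does not fit an image of side ", L)
  a <- sample_abundances[layout$otu_ids]
  a[is.na(a)] <- 0
  if (any(a < 0 | a > 1)) stop("abundance outside [0, 1]")

  npix <- L^2
  ch1 <- integer(npix)
  ch2 <- integer(npix)
  ch3 <- integer(npix)
  used <- length(a)
  if (used > 0) ch1[seq_len(used)] <- abundance_to_pixel(unname(a))
  for (i in seq_len(nrow(layout$blocks))) {
    len <- layout$blocks$length[i]
    if (len == 0) next
    idx <- layout$blocks$start[i] + seq_len(len) - 1L
    gsum <- min(sum(a[idx]), 1)
    ch2[idx] <- abundance_to_pixel(gsum)
    ch3[idx] <- as.integer(round(layout$blocks$corr_weight[i] * 255))
  }
  # row-major fill: pixel p -> row (p-1) %/% L + 1, col (p-1) %% L + 1
  img <- array(0L, dim = c(L, L, 3))
  p <- seq_len(npix)
  rows <- (p - 1L) %/% L + 1L
  cols <- (p - 1L) %% L + 1L
  img[cbind(rows, cols, 1L)] <- ch1
  img[cbind(rows, cols, 2L)] <- ch2
  img[cbind(rows, cols, 3L)] <- ch3
  structure(img, class = "microbiota_image", layout_hash = layout$hash)
}

#' Encode a whole table of samples
#'
#' @param table OTU-level `otu_table` (post [select_top_otus()]).
#' @param layout a `genus_layout`.
#' @param L image side.
#' @return list of `microbiota_image`s, one per sample.
#' @export
encode_images <- function(table, layout, L = layout$L) {
  rel <- relative_abundance(table)
  lapply(seq_len(nrow(rel)), function(i) encode_image(rel[i, ], layout, L))
}

#' Write a microbiota image as plain-text matrix dumps
#'
#' One TSV per channel (`<prefix>_ch1.tsv` etc.).
#'
#' @param image a `microbiota_image`.
#' @param prefix output path prefix.
#' @export
write_image_text <- function(image, prefix) {
  for (ch in 1:3) {
    utils::write.table(image[, , ch],
                       paste0(prefix, "_ch", ch, ".tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(prefix)
}
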