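# Small in-code fixtures shared across test files.

# deterministic toy table: n samples x p OTUs of Poisson counts
toy_table <- function(n = 6, p = 8, lambda = 20, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("otu", seq_len(p))))
  otu_table(m)
}

# taxonomy assigning OTUs round-robin to `g` genera
toy_taxonomy <- function(otu_ids, g = 3) {
  genus <- paste0("Genus", ((seq_along(otu_ids) - 1) %% g) + 1)
  taxonomy_map(otu_ids, paste0("k__Bacteria; p__P; g__", genus, "; s__"))
}

# FASTQ writer for planted-read tests
write_fastq <- function(path, seqs, quals) {
  stopifnot(length(seqs) == length(quals))
  out <- character(4 * length(seqs))
  out[seq(1, length(out), 4)] <- paste0("@read", seq_along(seqs))
  out[seq(2, length(out), 4)] <- seqs
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- quals
  writeLines(out, path)
  path
}

phred_string <- function(q, len) {
  strrep(rawToChar(as.raw(q + 33)), len)
}

# all distinct assignments of `sizes` group labels to n items (used for
# exhaustive permutation oracles at tiny n)
all_label_permutations <- function(n) {
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  perms(seq_len(n))
}

# delayed-maturation panel: every maturation ramp's midpoint shifted by
# `delay` years in disease (the stunted-colonization world)
delayed_panel <- function(delay = 8) {
  panel <- default_genus_panel()
  lapply(panel, function(ts) {
    if (ts$class == "age_discriminatory") {
      ts$class <- "stunted_colonization"
      ts$disease_multiplier <- 1
    }
    if (ts$class == "stunted_colonization") ts$disease_delay <- delay
    ts
  })
}

# brute-force BH step-up used as oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o[i:m]] * m / (i:m)))
  }
  # classic step-up: q_(i) = min_{j >= i} p_(j) * m / j
  qs <- p[o] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) qs[i] <- min(qs[i], qs[i + 1])
  q[o] <- pmin(qs, 1)
  q
}
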