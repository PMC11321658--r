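#' Read-level quality filter for FASTQ
#'
#' Applies the amplicon QC rules: discard reads shorter than `min_length`
#' (150 bp), with mean Phred below `min_quality` (20), containing any
#' ambiguous base (anything other than A/C/G/T), or containing a
#' mononucleotide run longer than `max_homopolymer` (8 bp). Survivors are
#' written to `fastq_out` when given. Qualities are Sanger Phred+33.
#'
#' @param fastq_in input FASTQ path (uncompressed).
#' @param fastq_out optional output path for surviving reads.
#' @param min_length minimum read length (default 150).
#' @param min_quality minimum mean Phred score (default 20).
#' @param max_homopolymer longest allowed mononucleotide run (default 8).
#' @return list with `n_total`, `n_kept`, `n_discarded` and per-criterion
#'   tallies (`fail_length`, `fail_quality`, `fail_ambiguous`,
#'   `fail_homopolymer`; a read can fail several criteria).
#' @export
qc_filter_reads <- function(fastq_in, fastq_out = NULL, min_length = 150,
                            min_quality = 20, max_homopolymer = 8) {
  if (!file.exists(fastq_in)) stop("file not found: ", fastq_in)
  lines <- readLines(fastq_in)
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ: ", length(lines),
         " lines is not a multiple of 4 (record ",
         length(lines) %/% 4 + 1, ")")
  n <- length(lines) %/% 4
  heads <- lines[seq(1, length(lines), by = 4)]
  seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  plus <- lines[seq(3, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  bad_rec <- which(!startsWith(heads, "@") | !startsWith(plus, "+") |
                     nchar(seqs) != nchar(quals))
  if (length(bad_rec))
    stop("malformed FASTQ record at index ", bad_rec[1])

  fail_len <- nchar(seqs) < min_length
  mean_q <- vapply(quals, function(q) {
    mean(as.integer(charToRaw(q))) - 33
  }, 0, USE.NAMES = FALSE)
  fail_q <- mean_q < min_quality
  fail_amb <- grepl("[^ACGT]", seqs)
  homopat <- paste0("([ACGT])\\1{", max_homopolymer, ",}")
  fail_homo <- grepl(homopat, seqs)

  keep <- !(fail_len | fail_q | fail_amb | fail_homo)
  if (!is.null(fastq_out)) {
    idx <- which(keep)
    out <- character(4 * length(idx))
    out[seq(1, length(out), by = 4)] <- heads[idx]
    out[seq(2, length(out), by = 4)] <- seqs[idx]
    out[seq(3, length(out), by = 4)] <- plus[idx]
    out[seq(4, length(out), by = 4)] <- quals[idx]
    writeLines(out, fastq_out)
  }
  list(n_total = n, n_kept = sum(keep), n_discarded = sum(!keep),
       fail_length = sum(fail_len), fail_quality = sum(fail_q),
       fail_ambiguous = sum(fail_amb), fail_homopolymer = sum(fail_homo))
}
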