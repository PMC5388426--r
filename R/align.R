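#' K-mer uniqueness audit of a genome
#'
#' Counts every k-mer instance over both strands (k-mers containing N are
#' excluded) and reports the fraction of instances whose sequence occurs
#' exactly once in the pooled two-strand collection. The audit justifies the
#' aligner seed length: a seed is only informative if most genomic k-mers of
#' that length are unique.
#'
#' @param genome named character vector of contig sequences.
#' @param k k-mer length; must not exceed the longest contig.
#' @return one-row tibble: k, total_kmers, distinct, unique_fraction.
#' @export
kmer_uniqueness <- function(genome, k) {
  lens <- nchar(genome)
  if (k < 1 || k > max(lens)) stop("k must be between 1 and the longest contig")
  kmers <- character(0)
  for (s in c(genome, revcomp(genome))) {
    L <- nchar(s)
    if (L < k) next
    kmers <- c(kmers, substring(s, 1:(L - k + 1L), k:L))
  }
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  total <- length(kmers)
  if (total == 0) {
    return(tibble::tibble(k = k, total_kmers = 0L, distinct = 0L,
                          unique_fraction = NA_real_))
  }
  u <- unique(kmers)
  counts <- tabulate(match(kmers, u), nbins = length(u))
  tibble::tibble(k = as.integer(k), total_kmers = total,
                 distinct = length(u),
                 unique_fraction = sum(counts[match(kmers, u)] == 1L) / total)
}

#' Unique seed-anchored ungapped alignment
#'
#' Aligns transcript-space reads to both strands of the genome. The seed is
#' the `seed_len` bases at the read's 3' end (its suffix — the end carrying
#' any misincorporation); candidate placements are all genomic locations
#' where the seed matches with at most `seed_mismatches` substitutions, each
#' extended ungapped over the full read with no cap on mismatches outside the
#' seed. Placements are ranked by total mismatch count; with
#' `unique_only = TRUE` any tie in the best stratum rejects the read as
#' multimapped, the conservative reading of reporting only unique alignments.
#' Any base pair involving N counts as a mismatch.
#'
#' @param reads read tibble (read_id, sequence, and optionally qualities).
#' @param genome named character vector of contig sequences.
#' @param seed_len seed length at the 3' end (default 14).
#' @param seed_mismatches maximum substitutions tolerated inside the seed
#'   (default 2).
#' @param unique_only reject reads whose best stratum holds more than one
#'   placement?
#' @param circular may seeds and extensions wrap around contig ends?
#' @return alignment tibble: read_id, status (aligned / multimapped /
#'   unaligned / too_short), contig, start (0-based leftmost genomic), strand,
#'   read_length, n_mismatch, mismatch_offsets (list column of offsets from
#'   the 3' end, <= 0).
#' @export
align_reads <- function(reads, genome, seed_len = 14, seed_mismatches = 2,
                        unique_only = TRUE, circular = FALSE) {
  stopifnot(seed_len >= 1, seed_mismatches >= 0)
  res <- cpp_align_reads(unname(genome), reads$sequence,
                         as.integer(seed_len), as.integer(seed_mismatches),
                         unique_only, circular,
                         max(nchar(reads$sequence), seed_len))
  status <- c("aligned", "multimapped", "unaligned", "too_short")[res$status + 1L]
  tibble::tibble(
    read_id = reads$read_id,
    status = status,
    contig = names(genome)[res$contig],
    start = res$start,
    strand = res$strand,
    read_length = nchar(reads$sequence),
    n_mismatch = res$n_mismatch,
    mismatch_offsets = lapply(res$offsets, function(o) o %||% integer(0)))
}

#' Summarise alignment outcomes
#'
#' @param alignments alignment tibble.
#' @return one-row tibble of counts per status.
#' @export
alignment_summary <- function(alignments) {
  tibble::tibble(
    input = nrow(alignments),
    aligned = sum(alignments$status == "aligned"),
    multimapped = sum(alignments$status == "multimapped"),
    unaligned = sum(alignments$status == "unaligned"),
    too_short = sum(alignments$status == "too_short"))
}

#' Write alignments as SAM
#'
#' Minimal SAM dialect: @HD/@SQ header, one record per accepted alignment,
#' FLAG 16 for minus strand, 1-based POS, CIGAR `<len>M`, NM tag with the
#' mismatch count. SEQ/QUAL are reference-forward (reverse-complemented /
#' reversed for minus-strand reads), per the SAM convention.
#'
#' @param alignments alignment tibble.
#' @param reads read tibble supplying sequences and qualities.
#' @param genome named character vector (for @SQ lines).
#' @param path output file.
#' @export
write_sam <- function(alignments, reads, genome, path) {
  acc <- alignments[alignments$status == "aligned", , drop = FALSE]
  acc <- dplyr::left_join(acc, reads, by = "read_id")
  minus <- acc$strand == "-"
  seq_out <- acc$sequence
  qual_out <- acc[["qualities"]] %||% strrep("I", acc$read_length)
  if (any(minus)) {
    seq_out[minus] <- revcomp(seq_out[minus])
    qual_out[minus] <- vapply(qual_out[minus],
                              function(q) intToUtf8(rev(utf8ToInt(q))),
                              character(1))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)), con)
  if (nrow(acc)) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                       acc$read_id, ifelse(minus, 16L, 0L), acc$contig,
                       acc$start + 1L, acc$read_length, seq_out, qual_out,
                       acc$n_mismatch), con)
  }
  invisible(path)
}

#' Read alignments back from SAM
#'
#' Converts via BAM (Rsamtools) and reconstructs the package's alignment
#' tibble; reads are returned in transcript space (reverse-complemented back
#' for minus-strand records) and mismatch offsets are recomputed against the
#' genome.
#'
#' @param path SAM file.
#' @param genome named character vector of contig sequences.
#' @return list with `alignments` and `reads` tibbles.
#' @export
read_sam <- function(path, genome) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "seq", "qual"),
    tag = "NM")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  minus <- bitwAnd(b$flag, 16L) > 0L
  seqs <- as.character(b$seq)
  quals <- as.character(b$qual)
  seqs[minus] <- revcomp(seqs[minus])
  quals[minus] <- vapply(quals[minus], function(q) intToUtf8(rev(utf8ToInt(q))),
                         character(1))
  reads <- tibble::tibble(read_id = b$qname, sequence = seqs, qualities = quals)
  aln <- tibble::tibble(
    read_id = b$qname, status = "aligned",
    contig = as.character(b$rname), start = b$pos - 1L,
    strand = ifelse(minus, "-", "+"),
    read_length = nchar(seqs),
    n_mismatch = as.integer(b$tag$NM))
  aln$mismatch_offsets <- mismatch_offsets_for(aln, reads, genome)
  list(alignments = aln, reads = reads)
}

# recompute per-read mismatch offsets (from the 3' end) against the genome
mismatch_offsets_for <- function(alignments, reads, genome) {
  seqs <- reads$sequence[match(alignments$read_id, reads$read_id)]
  refs <- reference_slices(alignments, genome)
  mapply(function(rd, rf) {
    a <- strsplit(rd, "")[[1]]
    b <- strsplit(rf, "")[[1]]
    which(a != b | a == "N" | b == "N") - length(a)
  }, seqs, refs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# transcript-space reference sequence under each accepted alignment
reference_slices <- function(alignments, genome) {
  g <- genome[alignments$contig]
  out <- substring(g, alignments$start + 1L,
                   alignments$start + alignments$read_length)
  minus <- alignments$strand == "-"
  if (any(minus)) out[minus] <- revcomp(out[minus])
  unname(out)
}
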