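#' Pileup of aligned read bases
#'
#' Tallies, for every covered (contig, position, strand), the read bases in
#' transcript space (minus-strand reads report the transcribed base, i.e. the
#' complement of the forward genome). N bases are counted in their own column
#' and excluded from the calling depth.
#'
#' @param alignments alignment tibble ([align_reads()]); only accepted
#'   alignments contribute.
#' @param reads read tibble supplying the sequences.
#' @param genome named character vector (reference bases for each column).
#' @return tibble: contig, pos (0-based), strand, ref (forward-strand
#'   reference base), A, C, G, T, n_N, depth (= A+C+G+T).
#' @export
pileup <- function(alignments, reads, genome) {
  acc <- alignments[alignments$status == "aligned", , drop = FALSE]
  if (nrow(acc) == 0) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          strand = character(), ref = character(),
                          A = integer(), C = integer(), G = integer(),
                          T = integer(), n_N = integer(), depth = integer()))
  }
  seqs <- reads$sequence[match(acc$read_id, reads$read_id)]
  len <- acc$read_length
  if (any(acc$start + len > nchar(genome[acc$contig])) || any(acc$start < 0)) {
    stop("alignment outside contig bounds")
  }
  fi <- flat_index(len)
  r <- fi$read
  base <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  gpos <- ifelse(acc$strand[r] == "+",
                 acc$start[r] + fi$pos - 1L,
                 acc$start[r] + len[r] - fi$pos)
  long <- dplyr::count(
    tibble::tibble(contig = acc$contig[r], pos = as.integer(gpos),
                   strand = acc$strand[r], base = base),
    .data$contig, .data$pos, .data$strand, .data$base)
  wide <- tidyr::pivot_wider(long, names_from = "base", values_from = "n",
                             values_fill = 0L)
  for (b in c(BASES, "N")) if (is.null(wide[[b]])) wide[[b]] <- 0L
  wide <- dplyr::rename(wide, n_N = "N")
  wide$depth <- wide$A + wide$C + wide$G + wide$T
  wide$ref <- substring(genome[wide$contig], wide$pos + 1L, wide$pos + 1L)
  dplyr::arrange(
    dplyr::select(wide, "contig", "pos", "strand", "ref",
                  dplyr::all_of(BASES), "n_N", "depth"),
    .data$contig, .data$pos, .data$strand)
}

#' Call strain-vs-reference variants from a pileup
#'
#' A genomic mutation affects reads from both strands, so strand-resolved
#' transcript-space counts are complemented onto the forward strand and
#' pooled per genomic position. A position is a variant iff pooled depth >=
#' `min_depth` and the most frequent non-reference base reaches
#' `min_alt_fraction` of the depth — a threshold caller suited to homozygous
#' strain differences, which sit near fraction 1 while misincorporation noise
#' stays far below the threshold.
#'
#' @param columns pileup tibble from [pileup()].
#' @param min_depth minimum pooled depth (default 10).
#' @param min_alt_fraction minimum alt fraction (default 0.8).
#' @return variant tibble: contig, pos (0-based), ref, alt, alt_fraction,
#'   depth.
#' @export
call_variants <- function(columns, min_depth = 10, min_alt_fraction = 0.8) {
  if (nrow(columns) == 0) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          alt_fraction = double(), depth = integer()))
  }
  fwd <- columns
  minus <- fwd$strand == "-"
  if (any(minus)) {  # complement counts back onto the forward strand
    tmp <- fwd[minus, ]
    fwd[minus, c("A", "C", "G", "T")] <- tmp[, c("T", "G", "C", "A")]
  }
  pooled <- dplyr::summarise(
    dplyr::group_by(fwd, .data$contig, .data$pos, .data$ref),
    dplyr::across(dplyr::all_of(BASES), sum), .groups = "drop")
  cnt <- as.matrix(pooled[, BASES])
  depth <- rowSums(cnt)
  cnt[cbind(seq_len(nrow(cnt)), match(pooled$ref, BASES))] <- -1L  # mask ref
  top <- max.col(cnt, ties.method = "first")
  alt_n <- cnt[cbind(seq_len(nrow(cnt)), top)]
  out <- tibble::tibble(contig = pooled$contig, pos = pooled$pos,
                        ref = pooled$ref, alt = BASES[top],
                        alt_fraction = ifelse(depth > 0, alt_n / depth, 0),
                        depth = as.integer(depth))
  dplyr::arrange(
    dplyr::filter(out, .data$depth >= min_depth,
                  .data$alt_fraction >= min_alt_fraction,
                  .data$alt != .data$ref, alt_n > 0),
    .data$contig, .data$pos)
}

#' Remove mismatch events at variant positions
#'
#' A mismatch at a genuine strain-vs-reference mutation is not a
#' misincorporation; every event whose genomic position carries a called
#' variant is excluded from all downstream statistics.
#'
#' @param events mismatch-event tibble (with contig and genomic_position).
#' @param variants variant tibble ([call_variants()] or planted truth).
#' @return the events tibble with masked rows removed; the number removed is
#'   reported via a message and the `n_masked` attribute.
#' @export
mask_events <- function(events, variants) {
  if (is.null(variants) || nrow(variants) == 0 || nrow(events) == 0) {
    attr(events, "n_masked") <- 0L
    return(events)
  }
  bad <- paste(events$contig, events$genomic_position) %in%
    paste(variants$contig, variants$pos)
  out <- events[!bad, , drop = FALSE]
  attr(out, "n_masked") <- sum(bad)
  if (sum(bad) > 0) {
    message(sum(bad), " mismatch event(s) removed at variant positions")
  }
  out
}
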