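#' Trim a 3' sequencing adapter
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter, provided the match is at least `min_overlap` bases; reads without
#' such a suffix are returned unchanged, qualities are trimmed in step.
#'
#' @param reads read tibble (read_id, sequence, qualities).
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum suffix/prefix match length.
#' @return read tibble with trimmed sequences and qualities.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3) {
  if (is.null(adapter) || !nzchar(adapter)) stop("adapter must be non-empty")
  len <- nchar(reads$sequence)
  kmax <- pmin(len, nchar(adapter))
  trim <- integer(nrow(reads))
  if (min_overlap > nchar(adapter)) return(reads)
  # longest first, so each read keeps the first (longest) matching overlap
  for (k in rev(seq.int(min_overlap, nchar(adapter)))) {
    if (k > max(kmax, 0)) next
    open <- trim == 0L & kmax >= k
    if (!any(open)) next
    suffix <- substring(reads$sequence[open], len[open] - k + 1L, len[open])
    hit <- suffix == substring(adapter, 1L, k)
    trim[open][hit] <- k
  }
  keep <- len - trim
  dplyr::mutate(reads,
                sequence = substring(.data$sequence, 1L, keep),
                qualities = substring(.data$qualities, 1L, keep))
}

#' Filter reads before alignment
#'
#' Applies the pre-alignment exclusions: drops reads shorter than
#' `min_length`, and (optionally) reads whose base at the 3'-adjacent
#' position — the position immediately upstream (-1) of the 3' terminal base,
#' i.e. the penultimate character of the transcript-space read — is N, a
#' signature of a systematic sequencing artefact at that cycle. Contaminant
#' (blacklist) removal operates on alignments, see [apply_blacklist()].
#'
#' @param reads read tibble.
#' @param min_length minimum surviving read length (nt).
#' @param drop_n_at_3prime_adjacent drop reads with N at offset -1?
#' @return list with `reads` (survivors) and `report` (a `filter_report`
#'   tibble of category counts; input = surviving + sum(dropped)).
#' @export
filter_reads <- function(reads, min_length = 16, drop_n_at_3prime_adjacent = TRUE) {
  n_in <- nrow(reads)
  len <- nchar(reads$sequence)
  short <- len < min_length
  nadj <- rep(FALSE, n_in)
  if (drop_n_at_3prime_adjacent) {
    penult <- substring(reads$sequence, len - 1L, len - 1L)
    nadj <- !short & len >= 2L & penult == "N"
  }
  keep <- !short & !nadj
  report <- tibble::tibble(
    input = n_in,
    dropped_too_short = sum(short),
    dropped_n_3prime_adjacent = sum(nadj),
    dropped_blacklist = 0L,
    surviving = sum(keep))
  class(report) <- c("filter_report", class(report))
  list(reads = reads[keep, , drop = FALSE], report = report)
}

#' Drop alignments falling in blacklist intervals
#'
#' Contaminant loci (rRNA/tRNA/snoRNA analogues) are removed after alignment:
#' any accepted alignment whose genomic footprint overlaps a blacklist
#' interval is discarded.
#'
#' @param alignments alignment tibble from [align_reads()].
#' @param blacklist interval tibble (contig, start, end; 0-based half-open),
#'   e.g. from [read_bed()]. `NULL` is a no-op.
#' @return list with `alignments` and `n_dropped`.
#' @export
apply_blacklist <- function(alignments, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0) {
    return(list(alignments = alignments, n_dropped = 0L))
  }
  acc <- alignments$status == "aligned"
  gr <- GenomicRanges::GRanges(
    alignments$contig[acc],
    IRanges::IRanges(start = alignments$start[acc] + 1L,
                     width = alignments$read_length[acc]))
  bl <- GenomicRanges::GRanges(
    blacklist$contig,
    IRanges::IRanges(start = blacklist$start + 1L, end = blacklist$end))
  hit <- IRanges::overlapsAny(gr, bl)
  drop_idx <- which(acc)[hit]
  list(alignments = if (length(drop_idx)) alignments[-drop_idx, , drop = FALSE]
                    else alignments,
       n_dropped = length(drop_idx))
}
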