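#' Extract quality-passing mismatch events near nascent 3' ends
#'
#' Walks every accepted alignment over the offsets 0, -1, ..., -(window-1)
#' from the 3' terminus (shorter reads contribute fewer offsets). At each
#' offset the denominator counts every read whose base there is not N; a
#' mismatch event is emitted when the transcript-space read base differs from
#' the reference, neither base is N, the base call reaches `phred_min`
#' (mismatches below the threshold are discarded as likely miscalls, but the
#' read still counts in the denominator), and the genomic position carries no
#' known variant. Set `quality_filtered_denominator = TRUE` to additionally
#' drop sub-threshold bases from denominators.
#'
#' @param alignments alignment tibble ([align_reads()]).
#' @param reads read tibble with sequences and qualities.
#' @param genome named character vector of contig sequences.
#' @param variants variant tibble to mask, or NULL.
#' @param phred_min Phred threshold for calling a mismatch (default 30,
#'   i.e. 99.9% base-call accuracy).
#' @param window number of 3'-anchored offsets analysed (default 11:
#'   offsets 0 to -10, roughly the RNA/DNA hybrid length in the elongation
#'   complex).
#' @param quality_filtered_denominator also exclude low-quality matched bases
#'   from denominators (default FALSE).
#' @return list with `events` (tibble: read_id, contig, genomic_position,
#'   strand, offset, template_base, read_base, quality, substitution) and
#'   `denominators` (tibble: offset, denominator_reads).
#' @export
extract_mismatch_events <- function(alignments, reads, genome, variants = NULL,
                                    phred_min = 30, window = 11,
                                    quality_filtered_denominator = FALSE) {
  if (phred_min < 0) stop("phred_min must be non-negative")
  if (window < 1) stop("window must be at least 1")
  acc <- alignments[alignments$status == "aligned", , drop = FALSE]
  offsets_all <- 0L:(-(as.integer(window) - 1L))
  empty_events <- tibble::tibble(
    read_id = character(), contig = character(), genomic_position = integer(),
    strand = character(), offset = integer(), template_base = character(),
    read_base = character(), quality = integer(), substitution = character())
  if (nrow(acc) == 0) {
    return(list(events = empty_events,
                denominators = tibble::tibble(offset = offsets_all,
                                              denominator_reads = 0L)))
  }
  idx <- match(acc$read_id, reads$read_id)
  seqs <- reads$sequence[idx]
  quals <- reads$qualities[idx]
  len <- acc$read_length

  # long view: one row per (read, offset), offsets limited by read length
  w <- pmin(len, as.integer(window))
  r <- rep.int(seq_len(nrow(acc)), w)
  offset <- -(sequence(w) - 1L)
  rpos <- len[r] + offset  # 1-based position within the read string
  read_base <- substring(seqs[r], rpos, rpos)
  qchar <- substring(quals[r], rpos, rpos)
  quality <- utf8ToInt(paste(qchar, collapse = ""))[seq_along(qchar)] - 33L
  gpos <- ifelse(acc$strand[r] == "+", acc$start[r] + len[r] - 1L + offset,
                 acc$start[r] - offset)
  tmpl <- substring(genome[acc$contig[r]], gpos + 1L, gpos + 1L)
  minus <- acc$strand[r] == "-"
  tmpl[minus] <- complement_chr(tmpl[minus])

  denom_keep <- read_base != "N"
  if (quality_filtered_denominator) denom_keep <- denom_keep & quality >= phred_min
  denominators <- dplyr::left_join(
    tibble::tibble(offset = offsets_all),
    dplyr::count(tibble::tibble(offset = offset[denom_keep]), .data$offset,
                 name = "denominator_reads"),
    by = "offset")
  denominators$denominator_reads[is.na(denominators$denominator_reads)] <- 0L

  is_event <- read_base != tmpl & read_base != "N" & tmpl != "N" &
    quality >= phred_min
  keep <- which(is_event)
  tmpl_keep <- tmpl[keep]
  base_keep <- read_base[keep]
  events <- tibble::tibble(
    read_id = acc$read_id[r[keep]],
    contig = acc$contig[r[keep]],
    genomic_position = as.integer(gpos[keep]),
    strand = acc$strand[r[keep]],
    offset = offset[keep],
    template_base = tmpl_keep,
    read_base = base_keep,
    quality = as.integer(quality[keep]),
    substitution = paste0(tmpl_keep, ">", base_keep))
  if (!is.null(variants)) events <- mask_events(events, variants)
  list(events = events, denominators = denominators)
}

#' Per-position total and specific error rates
#'
#' The core readout: for each offset from the nascent 3' end, the percentage
#' of reads carrying a (quality-passing) mismatch there, plus the same
#' percentage split over the 12 template>read substitution classes. Offset 0
#' is the 3' terminus, where a mismatch marks a misincorporated elongation
#' complex.
#'
#' @param events,denominators from [extract_mismatch_events()].
#' @return a `positional_error_table`: list with `total` (offset,
#'   denominator_reads, mismatch_reads, total_rate_percent) and `specific`
#'   (offset, substitution, count, rate_percent). Offsets with zero
#'   denominator report NA rates.
#' @export
positional_error_table <- function(events, denominators) {
  per_read <- dplyr::distinct(events, .data$read_id, .data$offset)
  total <- dplyr::left_join(
    denominators,
    dplyr::count(per_read, .data$offset, name = "mismatch_reads"),
    by = "offset")
  total$mismatch_reads[is.na(total$mismatch_reads)] <- 0L
  total$total_rate_percent <- ifelse(
    total$denominator_reads > 0,
    100 * total$mismatch_reads / total$denominator_reads, NA_real_)

  grid <- tidyr::expand_grid(offset = denominators$offset,
                             substitution = SUBSTITUTIONS)
  specific <- dplyr::left_join(
    grid,
    dplyr::count(events, .data$offset, .data$substitution, name = "count"),
    by = c("offset", "substitution"))
  specific$count[is.na(specific$count)] <- 0L
  specific <- dplyr::left_join(specific, denominators, by = "offset")
  specific$rate_percent <- ifelse(
    specific$denominator_reads > 0,
    100 * specific$count / specific$denominator_reads, NA_real_)
  specific$denominator_reads <- NULL

  structure(list(total = dplyr::arrange(total, dplyr::desc(.data$offset)),
                 specific = dplyr::arrange(specific, dplyr::desc(.data$offset),
                                           .data$substitution)),
            class = "positional_error_table")
}

#' @export
print.positional_error_table <- function(x, ...) {
  cat("Positional error table (offsets from the nascent 3' end)\n")
  print(x$total, ...)
  top <- dplyr::slice_max(dplyr::filter(x$specific, .data$offset == 0),
                          .data$count, n = 3, with_ties = FALSE)
  cat("Top offset-0 substitutions:",
      paste(sprintf("%s (%d)", top$substitution, top$count), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname positional_error_table
#' @param x a `positional_error_table`.
#' @param ... unused.
#' @export
tidy.positional_error_table <- function(x, ...) {
  dplyr::left_join(x$specific,
                   dplyr::select(x$total, "offset", "denominator_reads"),
                   by = "offset")
}

#' @rdname positional_error_table
#' @export
glance.positional_error_table <- function(x, ...) {
  t0 <- x$total[x$total$offset == 0, ]
  interior <- x$total[x$total$offset < 0, ]
  tibble::tibble(
    misincorporated_ec_percent = t0$total_rate_percent,
    interior_mean_rate_percent = mean(interior$total_rate_percent, na.rm = TRUE),
    modal_substitution_3prime = {
      s0 <- x$specific[x$specific$offset == 0, ]
      if (sum(s0$count) > 0) s0$substitution[which.max(s0$count)] else NA_character_
    },
    n_offsets = nrow(x$total))
}

#' Proportion of misincorporated elongation complexes
#'
#' Each read is one elongation complex and its final base is the nascent 3'
#' terminus, so the total mismatch rate at offset 0 *is* the percentage of
#' ECs that have just misincorporated.
#'
#' @param table a [positional_error_table()].
#' @return percentage (0-100).
#' @export
misincorporated_ec_fraction <- function(table) {
  row <- table$total[table$total$offset == 0, ]
  if (nrow(row) == 0 || row$denominator_reads == 0) {
    stop("offset 0 is missing or has a zero denominator")
  }
  row$total_rate_percent
}

#' Sweep a per-position misincorporation-count threshold
#'
#' Groups offset-0 events by genomic location (contig, position, strand) and,
#' for each threshold t, reports how many locations carry strictly more than
#' t events and how many elongation complexes sit at those locations. Both
#' series are non-increasing in t; the gap between them shows how much of the
#' signal is concentrated in hotspots versus scattered single events.
#'
#' @param events mismatch-event tibble (offset-0 rows are used).
#' @param thresholds integer thresholds (default 0, 1, 2, 5, 10, 20, 50, 100).
#' @return tibble: threshold, n_positions, n_ecs.
#' @export
threshold_sweep <- function(events, thresholds = c(0L, 1L, 2L, 5L, 10L, 20L,
                                                   50L, 100L)) {
  e0 <- events[events$offset == 0, , drop = FALSE]
  counts <- dplyr::count(e0, .data$contig, .data$genomic_position,
                         .data$strand, name = "n")$n
  tibble::tibble(
    threshold = as.integer(thresholds),
    n_positions = vapply(thresholds, function(t) sum(counts > t), integer(1)),
    n_ecs = vapply(thresholds, function(t) sum(counts[counts > t]), integer(1)))
}
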