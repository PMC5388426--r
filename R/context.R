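#' Call misincorporation hotspots
#'
#' Groups offset-0 mismatch events by genomic location and substitution class
#' and reports groups with strictly more than `min_count` events — the
#' ">50 misincorporations" definition at the default. `substitution = "all"`
#' pools substitution classes per location; a specific label (e.g. `"G>A"`)
#' restricts to that class.
#'
#' @param events mismatch-event tibble (offset-0 rows are used).
#' @param substitution `"all"` or one of the 12 template>read labels.
#' @param min_count hotspot threshold (strict; default 50).
#' @return tibble: contig, position (0-based), strand, substitution,
#'   event_count.
#' @export
call_hotspots <- function(events, substitution = "G>A", min_count = 50) {
  e0 <- events[events$offset == 0, , drop = FALSE]
  if (substitution == "all") {
    grp <- dplyr::count(e0, .data$contig, .data$genomic_position, .data$strand,
                        name = "event_count")
    grp$substitution <- "all"
  } else {
    if (!substitution %in% SUBSTITUTIONS) stop("unknown substitution label")
    e0 <- e0[e0$substitution == substitution, , drop = FALSE]
    grp <- dplyr::count(e0, .data$contig, .data$genomic_position, .data$strand,
                        .data$substitution, name = "event_count")
  }
  out <- dplyr::filter(grp, .data$event_count > min_count)
  out <- dplyr::rename(out, position = "genomic_position")
  dplyr::arrange(
    dplyr::select(out, "contig", "position", "strand", "substitution",
                  "event_count"),
    dplyr::desc(.data$event_count))
}

#' Extract transcript-space sequence context around a position
#'
#' Returns the window of `2 * halfwidth + 1` bases centred on the given
#' genomic position, oriented in transcript space: index 0 is the
#' misincorporated position, negative offsets are upstream RNA bases (-1 is
#' the base preceding the 3' terminus) and +1/+2... are template positions
#' not yet transcribed, read from the non-template strand. Minus-strand
#' windows are reverse-complemented. On a linear contig a window running off
#' the end is truncated with `N` placeholders; circular contigs wrap.
#'
#' @param genome named character vector of contig sequences.
#' @param contig,position,strand vectors describing the positions (0-based).
#' @param halfwidth bases on each side (default 5).
#' @param circular wrap around contig ends?
#' @return character vector of context sequences.
#' @export
extract_context <- function(genome, contig, position, strand, halfwidth = 5,
                            circular = FALSE) {
  L <- nchar(genome[contig])
  w <- 2L * as.integer(halfwidth) + 1L
  if (circular) {
    idx <- outer(position - halfwidth, 0:(w - 1L), `+`) %% L
    chars <- substring(genome[rep(contig, w)], as.vector(idx) + 1L,
                       as.vector(idx) + 1L)
    fwd <- apply(matrix(chars, ncol = w), 1, paste, collapse = "")
  } else {
    lo <- pmax(position - halfwidth, 0L)
    hi <- pmin(position + halfwidth, L - 1L)
    core <- substring(genome[contig], lo + 1L, hi + 1L)
    fwd <- paste0(strrep("N", lo - (position - halfwidth)), core,
                  strrep("N", (position + halfwidth) - hi))
  }
  minus <- strand == "-"
  if (any(minus)) fwd[minus] <- revcomp(fwd[minus])
  unname(fwd)
}

#' Attach context windows to hotspots
#'
#' @param hotspots hotspot tibble from [call_hotspots()].
#' @inheritParams extract_context
#' @return the hotspot tibble with a `context` column.
#' @export
hotspot_contexts <- function(hotspots, genome, halfwidth = 5, circular = FALSE) {
  hotspots$context <- extract_context(genome, hotspots$contig,
                                      hotspots$position, hotspots$strand,
                                      halfwidth, circular)
  hotspots
}

#' Position frequency matrix of aligned context windows
#'
#' Per-column base frequencies of equal-length contexts, the numeric core of
#' a sequence logo. N entries are dropped from that column's denominator;
#' all-N columns are NA and flagged.
#'
#' @param contexts character vector of equal-length context windows (odd
#'   length; the centre is the misincorporated position).
#' @return a `position_frequency_matrix`: 4 x width matrix (rows A/C/G/T)
#'   with column names as offsets, attribute `n_sequences`.
#' @export
position_frequency_matrix <- function(contexts) {
  if (length(contexts) == 0) stop("at least one context is required")
  w <- unique(nchar(contexts))
  if (length(w) != 1) stop("contexts must have equal lengths")
  chars <- matrix(strsplit(paste(contexts, collapse = ""), "",
                           fixed = TRUE)[[1]],
                  ncol = w, byrow = TRUE)
  half <- (w - 1L) %/% 2L
  m <- vapply(seq_len(w), function(j) {
    col <- chars[, j]
    col <- col[col %in% BASES]
    if (length(col) == 0) return(rep(NA_real_, 4))
    tabulate(match(col, BASES), nbins = 4) / length(col)
  }, numeric(4))
  dimnames(m) <- list(BASES, as.character(seq_len(w) - half - 1L))
  structure(m, n_sequences = length(contexts),
            class = c("position_frequency_matrix", "matrix"))
}

#' @export
print.position_frequency_matrix <- function(x, ...) {
  cat("Position frequency matrix over", attr(x, "n_sequences"),
      "contexts (columns = offsets from the misincorporated position)\n")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' @rdname position_frequency_matrix
#' @param x a `position_frequency_matrix`.
#' @param ... unused.
#' @export
tidy.position_frequency_matrix <- function(x, ...) {
  tibble::tibble(
    offset = rep(as.integer(colnames(x)), each = 4),
    base = rep(rownames(x), ncol(x)),
    frequency = as.vector(unclass(x)))
}

#' Write hotspots as BED (and TSV)
#'
#' @param hotspots hotspot tibble (optionally with contexts).
#' @param path BED path; a TSV with all columns is written alongside with a
#'   `.tsv` suffix.
#' @export
write_hotspots <- function(hotspots, path) {
  write_bed(tibble::tibble(contig = hotspots$contig, start = hotspots$position,
                           end = hotspots$position + 1L,
                           name = sprintf("%s_%d", hotspots$substitution,
                                          hotspots$event_count),
                           strand = hotspots$strand), path)
  write_tsv_plain(hotspots, paste0(path, ".tsv"))
  invisible(path)
}
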