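#' Load a region annotation from GFF3 and BED files
#'
#' CDS intervals are taken from the GFF3 (1-based inclusive, converted to the
#' internal 0-based half-open convention); UTR intervals from a BED file;
#' introns (yeast mode only) from a second BED file. In `mode = "yeast"`
#' introns join the transcribed-untranslated class; in `mode = "bacteria"`
#' intron intervals are ignored.
#'
#' @param gff3 path to a GFF3 file with CDS features and `##sequence-region`
#'   headers.
#' @param utr_bed path to a BED file of UTR intervals (0-based half-open), or
#'   NULL for none.
#' @param intron_bed optional BED of introns.
#' @param mode `"bacteria"` or `"yeast"`.
#' @return an `annotation_set`: tibble (contig, strand, start, end, class)
#'   with `contig_lengths` and `mode` attributes. class is `translated`
#'   (CDS) or `transcribed_untranslated` (UTR/intron).
#' @export
load_annotation <- function(gff3, utr_bed = NULL, intron_bed = NULL,
                            mode = c("bacteria", "yeast")) {
  mode <- match.arg(mode)
  gr <- rtracklayer::import(gff3, format = "gff3")
  cl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(cl))) {
    # fall back to the ##sequence-region pragmas when the importer drops them
    pragma <- grep("^##sequence-region", readLines(gff3), value = TRUE)
    if (length(pragma)) {
      parts <- strsplit(trimws(pragma), "\\s+")
      cl2 <- setNames(vapply(parts, function(p) as.integer(p[4]), integer(1)),
                      vapply(parts, function(p) p[2], character(1)))
      hit <- names(cl) %in% names(cl2)
      cl[hit] <- cl2[names(cl)[hit]]
    }
  }
  if (any(is.na(cl))) stop("GFF3 must declare contig lengths (##sequence-region)")
  cds <- gr[gr$type == "CDS"]
  cds_tbl <- tibble::tibble(contig = as.character(GenomicRanges::seqnames(cds)),
                            strand = as.character(GenomicRanges::strand(cds)),
                            start = GenomicRanges::start(cds) - 1L,
                            end = GenomicRanges::end(cds),
                            class = "translated")
  utr_tbl <- if (!is.null(utr_bed)) {
    b <- read_bed(utr_bed)
    tibble::tibble(contig = b$contig, strand = b$strand, start = b$start,
                   end = b$end, class = "transcribed_untranslated")
  } else NULL
  intron_tbl <- if (!is.null(intron_bed) && mode == "yeast") {
    b <- read_bed(intron_bed)
    tibble::tibble(contig = b$contig, strand = b$strand, start = b$start,
                   end = b$end, class = "transcribed_untranslated")
  } else NULL
  build_annotation_set(dplyr::bind_rows(cds_tbl, utr_tbl, intron_tbl),
                       cl, mode)
}

#' Build an annotation set from an in-memory annotation tibble
#'
#' Converts a generator annotation ([generate_genome()]) or any tibble with
#' contig/strand/start/end plus either a `class` or a `type` column
#' (CDS -> translated, *UTR / intron -> transcribed_untranslated).
#'
#' @param annotation annotation tibble.
#' @param mode `"bacteria"` or `"yeast"`.
#' @param contig_lengths named integer vector; defaults to the tibble's
#'   `contig_lengths` attribute.
#' @return an `annotation_set`.
#' @export
as_annotation_set <- function(annotation, mode = "bacteria",
                              contig_lengths = attr(annotation, "contig_lengths")) {
  if (is.null(annotation[["class"]])) {
    annotation$class <- dplyr::case_when(
      annotation$type == "CDS" ~ "translated",
      grepl("UTR|intron", annotation$type) ~ "transcribed_untranslated",
      TRUE ~ NA_character_)
    annotation <- annotation[!is.na(annotation$class), , drop = FALSE]
  }
  build_annotation_set(
    dplyr::select(annotation, "contig", "strand", "start", "end", "class"),
    contig_lengths, mode)
}

build_annotation_set <- function(tbl, contig_lengths, mode) {
  if (is.null(contig_lengths)) stop("contig lengths are required")
  if (nrow(tbl)) {
    if (any(tbl$start < 0) || any(tbl$end > contig_lengths[tbl$contig]) ||
        any(tbl$end < tbl$start)) {
      stop("annotation intervals outside contig bounds")
    }
    gr <- annotation_granges(tbl)
    ov <- GenomicRanges::findOverlaps(gr[tbl$class == "translated"],
                                      gr[tbl$class != "translated"])
    if (length(ov) > 0) {
      stop("CDS and UTR/intron intervals overlap on the same strand")
    }
  }
  structure(dplyr::arrange(tibble::as_tibble(tbl), .data$contig, .data$start),
            contig_lengths = contig_lengths, mode = mode,
            class = c("annotation_set", class(tibble::tibble())))
}

annotation_granges <- function(tbl) {
  GenomicRanges::GRanges(tbl$contig,
                         IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
                         strand = tbl$strand)
}

#' Classify genomic locations by region
#'
#' A location is `translated` when it lies in a CDS on the matching strand,
#' `transcribed_untranslated` when in a UTR (or intron, yeast mode) on the
#' matching strand, and `other` otherwise; translated takes precedence.
#'
#' @param contig,position,strand vectors describing the locations (0-based).
#' @param annotation an `annotation_set`.
#' @return character vector of classes.
#' @export
classify_position <- function(contig, position, strand, annotation) {
  n <- max(length(contig), length(position), length(strand))
  if (length(position) == 0) n <- 0
  out <- rep("other", n)
  if (nrow(annotation) == 0 || n == 0) return(out)
  q <- GenomicRanges::GRanges(contig,
                              IRanges::IRanges(start = position + 1L, width = 1L),
                              strand = strand)
  for (cls in c("transcribed_untranslated", "translated")) {
    sub <- annotation[annotation$class == cls, , drop = FALSE]
    if (nrow(sub) == 0) next
    hit <- IRanges::overlapsAny(q, annotation_granges(sub))
    out[hit] <- cls
  }
  out
}

#' Region-stratified misincorporation rates
#'
#' Counts distinct misincorporated locations and elongation complexes per
#' region class and normalises to events per 100 kb of class length. Class
#' lengths are merged intervals counted per strand and summed (a region
#' annotated on both strands contributes twice, matching the strand-resolved
#' locations); `other` is the remaining two-strand genome footprint.
#'
#' @param events mismatch-event tibble (offset-0 rows are used).
#' @param hotspots hotspot tibble ([call_hotspots()]), or NULL.
#' @param annotation an `annotation_set`.
#' @return tibble: class, n_locations, n_ecs, region_length,
#'   locations_per_100kb, n_hotspots, hotspots_per_100kb.
#' @export
region_rate_table <- function(events, hotspots, annotation) {
  cl <- attr(annotation, "contig_lengths")
  classes <- c("translated", "transcribed_untranslated", "other")

  merged_len <- vapply(classes[1:2], function(cls) {
    sub <- annotation[annotation$class == cls, , drop = FALSE]
    if (nrow(sub) == 0) return(0)
    sum(GenomicRanges::width(GenomicRanges::reduce(annotation_granges(sub))))
  }, numeric(1))
  lens <- c(merged_len, other = 2 * sum(as.numeric(cl)) - sum(merged_len))
  names(lens) <- classes

  e0 <- events[events$offset == 0, , drop = FALSE]
  locs <- dplyr::count(e0, .data$contig, .data$genomic_position, .data$strand,
                       name = "n_ecs")
  locs$class <- classify_position(locs$contig, locs$genomic_position,
                                  locs$strand, annotation)
  per_class <- dplyr::summarise(dplyr::group_by(locs, .data$class),
                                n_locations = dplyr::n(),
                                n_ecs = sum(.data$n_ecs), .groups = "drop")
  hs <- if (!is.null(hotspots) && nrow(hotspots)) {
    h <- hotspots
    h$class <- classify_position(h$contig, h$position, h$strand, annotation)
    dplyr::count(h, .data$class, name = "n_hotspots")
  } else tibble::tibble(class = character(), n_hotspots = integer())

  out <- tibble::tibble(class = classes, region_length = as.numeric(lens))
  out <- dplyr::left_join(out, per_class, by = "class")
  out <- dplyr::left_join(out, hs, by = "class")
  out$n_locations[is.na(out$n_locations)] <- 0L
  out$n_ecs[is.na(out$n_ecs)] <- 0L
  out$n_hotspots[is.na(out$n_hotspots)] <- 0L
  out$locations_per_100kb <- ifelse(out$region_length > 0,
                                    1e5 * out$n_locations / out$region_length,
                                    NA_real_)
  out$hotspots_per_100kb <- ifelse(out$region_length > 0,
                                   1e5 * out$n_hotspots / out$region_length,
                                   NA_real_)
  dplyr::select(out, "class", "n_locations", "n_ecs", "region_length",
                "locations_per_100kb", "n_hotspots", "hotspots_per_100kb")
}
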