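#' Read and write genome FASTA
#'
#' Thin wrappers around Biostrings keeping the package's internal genome
#' representation (a named character vector of contig sequences, uppercase).
#'
#' @param path file path.
#' @return `read_genome_fasta`: named character vector.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_genome_fasta
#' @param genome named character vector of contig sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read and write FASTQ reads
#'
#' Reads are tibbles with `read_id`, `sequence` (A/C/G/T/N, 5' to 3' in
#' transcript space so the last base is the nascent 3' terminus) and
#' `qualities` (Sanger Phred+33 string).
#'
#' @param path file path.
#' @return tibble of reads.
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                 sequence = unname(as.character(x)),
                 qualities = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' @rdname read_reads_fastq
#' @param reads tibble of reads.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qualities))
  invisible(path)
}

#' Write a GFF3 annotation file
#'
#' Emits `##sequence-region` headers and one feature line per annotation row
#' (1-based inclusive coordinates, per the GFF3 convention; the package works
#' in 0-based half-open internally).
#'
#' @param annotation annotation tibble with a `contig_lengths` attribute.
#' @param path file path.
#' @export
write_gff3 <- function(annotation, path) {
  cl <- attr(annotation, "contig_lengths")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ctg in names(cl)) {
    writeLines(sprintf("##sequence-region %s 1 %d", ctg, cl[[ctg]]), con)
  }
  if (nrow(annotation)) {
    lines <- sprintf("%s\tnetfidelity\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                     annotation$contig, annotation$type,
                     annotation$start + 1L, annotation$end, annotation$strand,
                     paste0(annotation$gene_id, "_", annotation$type),
                     annotation$gene_id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write intervals as BED
#'
#' BED is 0-based half-open, matching the internal convention directly.
#'
#' @param intervals tibble with contig, start, end and optionally strand and
#'   name columns.
#' @param path file path.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  nm <- intervals[["name"]] %||% intervals[["gene_id"]] %||%
    rep(".", nrow(intervals))
  st <- intervals[["strand"]] %||% rep(".", nrow(intervals))
  write.table(data.frame(intervals$contig, intervals$start, intervals$end,
                         nm, 0L, st),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' @param path file path.
#' @return tibble: contig, start, end, name, strand (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(contig = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr),
                 name = if (!is.null(gr$name)) gr$name else NA_character_,
                 strand = as.character(GenomicRanges::strand(gr)))
}

#' Write and read the simulation truth table
#'
#' The event table is a TSV with columns read_id, contig, strand, pos3
#' (0-based genomic 3' position), offset (from the 3' end, <= 0), tmpl, obs,
#' layer; one row per injected event. A companion `<path>` with suffix
#' `.reads.tsv` records every read's EC and misincorporation flag.
#'
#' @param truth truth list from [synthesize_reads()].
#' @param path path for the event TSV.
#' @export
write_truth_table <- function(truth, path) {
  ev <- truth$events
  write.table(data.frame(read_id = ev$read_id, contig = ev$contig,
                         strand = ev$strand, pos3 = ev$pos3,
                         offset = ev$offset, tmpl = ev$template_base,
                         obs = ev$read_base, layer = ev$layer),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(truth$reads), paste0(path, ".reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  ev <- tibble::as_tibble(read.delim(path, colClasses = c(
    read_id = "character", contig = "character", strand = "character",
    tmpl = "character", obs = "character", layer = "character")))
  names(ev)[names(ev) == "tmpl"] <- "template_base"
  names(ev)[names(ev) == "obs"] <- "read_base"
  rd <- tibble::as_tibble(read.delim(paste0(path, ".reads.tsv"),
                                     colClasses = c(read_id = "character",
                                                    contig = "character",
                                                    strand = "character")))
  list(reads = rd, events = ev)
}

#' Write variants as a minimal VCF
#'
#' CHROM/POS (1-based)/ID/REF/ALT/QUAL/FILTER/INFO with DP and AF in INFO.
#'
#' @param variants tibble from [call_variants()] (contig, pos 0-based, ref,
#'   alt, and optionally depth, alt_fraction).
#' @param path file path.
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt fraction\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    dp <- variants$depth %||% rep(NA_integer_, nrow(variants))
    af <- variants$alt_fraction %||% rep(NA_real_, nrow(variants))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%s;AF=%s",
                       variants$contig, variants$pos + 1L, variants$ref,
                       variants$alt, dp, signif(af, 4)), con)
  }
  invisible(path)
}

write_tsv_plain <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
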