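#' Default template>read substitution spectrum
#'
#' A G>A-dominant spectrum: misincorporation of AMP where GMP was templated is
#' by far the most frequent class observed for bacterial and eukaryotic RNA
#' polymerases, so G>A carries most of the mass and the remaining 11 classes
#' share the rest equally.
#'
#' @param ga_mass probability mass on the G>A class.
#' @return named numeric vector over the 12 template>read classes, summing to 1.
#' @export
default_substitution_spectrum <- function(ga_mass = 0.55) {
  s <- setNames(rep((1 - ga_mass) / 11, 12), SUBSTITUTIONS)
  s["G>A"] <- ga_mass
  s
}

#' Configuration for the synthetic NET-seq generator
#'
#' Defines a synthetic genome, a population of elongation complexes (ECs),
#' the misincorporation process at nascent 3' ends, and the experimental
#' error layers (reverse transcription, PCR, sequencing with Phred
#' qualities). All rates are per base unless stated.
#'
#' @param genome_length contig length in bases.
#' @param gc_fraction GC content of the random genome, in `[0, 1]`.
#' @param n_genes number of non-overlapping genes (5'UTR + CDS + 3'UTR).
#' @param utr5_len,utr3_len UTR lengths in bases.
#' @param cds_len_range range of CDS lengths (rounded to codon multiples).
#' @param n_ecs number of elongation complexes to sample (one read each).
#' @param misinc_fraction probability that a sampled EC carries a 3'-terminal
#'   misincorporation.
#' @param substitution_spectrum named probabilities over the 12 template>read
#'   substitution classes (transcript space, U written as T); must sum to 1.
#' @param hotspot_motif_boost multiplicative weight on the per-EC
#'   misincorporation probability when the template context is C at -1 and G
#'   at the 3' position (capped at probability 1). The default of 1 leaves
#'   misincorporation uniform over eligible positions.
#' @param readthrough_rate probability of a U>C read-through error at each of
#'   offsets -1 and -2 when the template base there is T.
#' @param read_length_min,read_length_max read length bounds (nt); lengths are
#'   uniform on the range. The minimum must not fall below the aligner seed.
#' @param variant_positions number of homozygous strain-vs-reference
#'   substitutions to plant inside transcribed regions.
#' @param rt_error_rate reverse-transcription errors per base.
#' @param pcr_error_rate PCR errors per base per cycle.
#' @param pcr_cycles number of PCR cycles.
#' @param seq_error_rate sequencing miscalls per base.
#' @param quality_model list with `correct_mean`, `correct_sd`,
#'   `miscall_mean`, `miscall_sd`, `qmin`, `qmax`: Phred scores are drawn
#'   from truncated normals, high for correctly sequenced bases and lower for
#'   sequencing miscalls, so a Q30 filter removes most miscalls while keeping
#'   genuine misincorporations.
#' @param seed integer RNG seed; every generator stage derives its own
#'   substream from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 200000,
                       gc_fraction = 0.5,
                       n_genes = 40,
                       utr5_len = 50,
                       utr3_len = 100,
                       cds_len_range = c(300, 900),
                       n_ecs = 200000,
                       misinc_fraction = 0.03,
                       substitution_spectrum = default_substitution_spectrum(),
                       hotspot_motif_boost = 1,
                       readthrough_rate = 0.002,
                       read_length_min = 16,
                       read_length_max = 30,
                       variant_positions = 0,
                       rt_error_rate = 1e-4,
                       pcr_error_rate = 4e-7,
                       pcr_cycles = 15,
                       seq_error_rate = 1e-3,
                       quality_model = list(correct_mean = 38, correct_sd = 2,
                                            miscall_mean = 22, miscall_sd = 6,
                                            qmin = 2, qmax = 40),
                       seed = 1L) {
  if (!setequal(names(substitution_spectrum), SUBSTITUTIONS)) {
    stop("substitution_spectrum must be named by the 12 template>read classes")
  }
  substitution_spectrum <- substitution_spectrum[SUBSTITUTIONS]
  if (abs(sum(substitution_spectrum) - 1) > 1e-9) {
    stop("substitution_spectrum must sum to 1 (within 1e-9)")
  }
  stopifnot_prob(c(gc_fraction, misinc_fraction, readthrough_rate,
                   rt_error_rate, pcr_error_rate, seq_error_rate),
                 "sim_config rates")
  if (read_length_min < 14) {
    stop("read_length_min must be at least the aligner seed length (14)")
  }
  if (read_length_max < read_length_min) stop("read_length_max < read_length_min")
  if (hotspot_motif_boost < 0) stop("hotspot_motif_boost must be >= 0")
  structure(list(
    genome_length = as.integer(genome_length), gc_fraction = gc_fraction,
    n_genes = as.integer(n_genes), utr5_len = as.integer(utr5_len),
    utr3_len = as.integer(utr3_len), cds_len_range = as.integer(cds_len_range),
    n_ecs = as.integer(n_ecs), misinc_fraction = misinc_fraction,
    substitution_spectrum = substitution_spectrum,
    hotspot_motif_boost = hotspot_motif_boost,
    readthrough_rate = readthrough_rate,
    read_length_min = as.integer(read_length_min),
    read_length_max = as.integer(read_length_max),
    variant_positions = as.integer(variant_positions),
    rt_error_rate = rt_error_rate, pcr_error_rate = pcr_error_rate,
    pcr_cycles = as.integer(pcr_cycles), seq_error_rate = seq_error_rate,
    quality_model = quality_model, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a random annotated genome
#'
#' Places `n_genes` non-overlapping genes on a random contig, each gene a
#' 5'UTR + CDS (codon-multiple length) + 3'UTR block on a random strand, with
#' random intergenic gaps. Coordinates are 0-based half-open internally.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector of contig sequences)
#'   and `annotation` (tibble: contig, gene_id, strand, type, start, end,
#'   with a `contig_lengths` attribute).
#' @export
generate_genome <- function(config) {
  set.seed(derive_seed(config$seed, "genome"))
  gc <- config$gc_fraction
  L <- config$genome_length
  seq <- paste(sample(BASES, L, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
               collapse = "")
  genome <- c(chr1 = seq)

  n <- config$n_genes
  if (n == 0) {
    ann <- tibble::tibble(contig = character(), gene_id = character(),
                          strand = character(), type = character(),
                          start = integer(), end = integer())
    attr(ann, "contig_lengths") <- c(chr1 = L)
    return(list(genome = genome, annotation = ann))
  }

  lo <- ceiling(config$cds_len_range[1] / 3)
  hi <- floor(config$cds_len_range[2] / 3)
  cds_len <- 3L * sample(lo:hi, n, replace = TRUE)
  footprint <- config$utr5_len + cds_len + config$utr3_len
  slack <- L - sum(footprint)
  if (slack < 0) stop("genome_length too small to place genes without overlap")
  # random gaps before each gene and after the last
  cuts <- sort(sample.int(slack + 1, n, replace = TRUE) - 1L)
  gaps <- diff(c(0L, cuts))
  gene_start <- cumsum(gaps) + cumsum(c(0L, footprint[-n]))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("gene%03d", seq_len(n))

  one_gene <- function(i) {
    s <- gene_start[i]
    if (strand[i] == "+") {
      widths <- c(config$utr5_len, cds_len[i], config$utr3_len)
      types <- c("five_prime_UTR", "CDS", "three_prime_UTR")
    } else {
      widths <- c(config$utr3_len, cds_len[i], config$utr5_len)
      types <- c("three_prime_UTR", "CDS", "five_prime_UTR")
    }
    ends <- s + cumsum(widths)
    tibble::tibble(contig = "chr1", gene_id = gene_id[i], strand = strand[i],
                   type = types, start = c(s, ends[-3]), end = ends)
  }
  ann <- dplyr::bind_rows(lapply(seq_len(n), one_gene))
  ann <- dplyr::filter(ann, .data$end > .data$start)
  attr(ann, "contig_lengths") <- c(chr1 = L)
  list(genome = genome, annotation = ann)
}

# transcribed span of each gene (5'UTR..3'UTR), 0-based half-open
transcript_spans <- function(annotation) {
  dplyr::summarise(dplyr::group_by(annotation, .data$contig, .data$gene_id,
                                   .data$strand),
                   start = min(.data$start), end = max(.data$end),
                   .groups = "drop")
}

#' Sample elongation-complex 3' positions
#'
#' Draws `n_ecs` nascent-RNA 3'-end positions across genes with per-gene
#' abundance weights (log-normal by default), uniform within each gene's
#' eligible span. A 3' position is eligible when the full longest read fits
#' inside the transcript upstream of it, i.e. it lies at least
#' `read_length_max - 1` bases downstream of the transcript start.
#'
#' @param genome named character vector of contig sequences.
#' @param annotation annotation tibble from [generate_genome()].
#' @param config a [sim_config()].
#' @param weights optional named per-gene abundance weights; zero removes a
#'   gene. Defaults to log-normal draws under the config seed.
#' @return tibble: contig, strand, pos3 (0-based genomic 3' position), gene_id.
#' @export
sample_elongation_complexes <- function(genome, annotation, config,
                                        weights = NULL) {
  if (nrow(annotation) == 0) stop("annotation is empty")
  set.seed(derive_seed(config$seed, "ecs"))
  tx <- transcript_spans(annotation)
  rmax <- config$read_length_max
  tx$eligible <- tx$end - tx$start - rmax + 1L
  if (is.null(weights)) {
    weights <- setNames(stats::rlnorm(nrow(tx)), tx$gene_id)
  }
  tx$w <- as.numeric(weights[tx$gene_id])
  tx$w[is.na(tx$w)] <- 0
  tx$w[tx$eligible <= 0] <- 0
  if (all(tx$w == 0)) stop("no transcript is long enough to carry a full read")

  gi <- sample.int(nrow(tx), config$n_ecs, replace = TRUE, prob = tx$w)
  u <- floor(runif(config$n_ecs) * tx$eligible[gi])
  # eligible 3' positions: plus strand [start + rmax - 1, end - 1],
  # minus strand [start, end - rmax]
  pos3 <- ifelse(tx$strand[gi] == "+",
                 tx$start[gi] + rmax - 1L + u,
                 tx$end[gi] - rmax - u)
  tibble::tibble(contig = tx$contig[gi], strand = tx$strand[gi],
                 pos3 = as.integer(pos3), gene_id = tx$gene_id[gi])
}

#' Plant homozygous strain variants into a genome
#'
#' Substitutes `n` reference bases at distinct random positions inside
#' transcribed spans, producing the "experimental strain" genome that reads
#' are synthesised from while alignment and rate calculation use the
#' unmodified reference.
#'
#' @param genome named character vector (reference).
#' @param annotation annotation tibble (variants land in transcribed spans so
#'   they are covered by reads).
#' @param n number of variants.
#' @param seed RNG seed.
#' @return list with `genome` (mutated copy) and `variants` tibble
#'   (contig, pos 0-based, ref, alt).
#' @export
plant_variants <- function(genome, annotation, n, seed = 1L) {
  if (n == 0) {
    return(list(genome = genome,
                variants = tibble::tibble(contig = character(), pos = integer(),
                                          ref = character(), alt = character())))
  }
  set.seed(derive_seed(seed, "variants"))
  tx <- transcript_spans(annotation)
  all_pos <- unlist(mapply(seq.int, tx$start, tx$end - 1L, SIMPLIFY = FALSE))
  all_ctg <- rep(tx$contig, tx$end - tx$start)
  keep <- !duplicated(paste(all_ctg, all_pos))
  all_pos <- all_pos[keep]; all_ctg <- all_ctg[keep]
  pick <- sample.int(length(all_pos), min(n, length(all_pos)))
  ctg <- all_ctg[pick]; pos <- as.integer(all_pos[pick])
  ref <- substring(genome[ctg], pos + 1L, pos + 1L)
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1))
  mutated <- genome
  for (i in seq_along(pos)) {
    substr(mutated[ctg[i]], pos[i] + 1L, pos[i] + 1L) <- alt[i]
  }
  ord <- order(ctg, pos)
  list(genome = mutated,
       variants = tibble::tibble(contig = ctg[ord], pos = pos[ord],
                                 ref = unname(ref[ord]), alt = unname(alt[ord])))
}

#' Synthesise NET-seq reads with a recorded ground truth
#'
#' Each elongation complex yields one read: the transcript-space sequence
#' (5' to 3', so the *last* base of the read string is the nascent-RNA 3'
#' terminus) ending at the EC's genomic 3' position, reverse-complemented
#' from the genome for minus-strand transcripts. Error layers are applied in
#' biological order: 3'-terminal misincorporation (per the configured
#' spectrum, boosted at C(-1)G(0) motifs), U>C read-through at offsets -1/-2,
#' then per-base reverse-transcription, PCR (`pcr_cycles * pcr_error_rate`)
#' and sequencing errors. Phred strings are drawn from the quality model,
#' with sequencing miscalls receiving the low-quality distribution.
#'
#' @param ecs tibble from [sample_elongation_complexes()].
#' @param genome named character vector (the strain genome reads derive from).
#' @param config a [sim_config()].
#' @return list with `reads` (tibble: read_id, sequence, qualities) and
#'   `truth` (list of `reads` and `events` tibbles; see [write_truth_table()]).
#' @export
synthesize_reads <- function(ecs, genome, config) {
  n <- nrow(ecs)
  if (n == 0) stop("empty elongation-complex list")
  set.seed(derive_seed(config$seed, "reads"))

  len <- sample(config$read_length_min:config$read_length_max, n, replace = TRUE)
  plus <- ecs$strand == "+"
  seqs <- character(n)
  g <- genome[ecs$contig]
  seqs[plus] <- substring(g[plus], ecs$pos3[plus] - len[plus] + 2L,
                          ecs$pos3[plus] + 1L)
  seqs[!plus] <- revcomp(substring(g[!plus], ecs$pos3[!plus] + 1L,
                                   ecs$pos3[!plus] + len[!plus]))

  fi <- flat_index(len)
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  tmpl <- chars  # template bases, frozen before any error layer
  end_flat <- fi$starts + len - 1L  # flat index of each read's 3' base

  ev <- list()
  add_events <- function(read_idx, flatpos, obs, layer) {
    if (length(read_idx) == 0) return(invisible(NULL))
    ev[[length(ev) + 1]] <<- tibble::tibble(
      read = read_idx,
      offset = as.integer(flatpos - end_flat[read_idx]),
      template_base = tmpl[flatpos], read_base = obs, layer = layer)
    invisible(NULL)
  }

  # --- misincorporation at the 3' terminus -------------------------------
  t0 <- chars[end_flat]
  tm1 <- chars[end_flat - 1L]
  boost <- ifelse(tm1 == "C" & t0 == "G", config$hotspot_motif_boost, 1)
  p <- pmin(1, config$misinc_fraction * boost)
  is_misinc <- runif(n) < p
  spec <- config$substitution_spectrum
  mis_obs <- rep(NA_character_, n)
  for (b in BASES) {
    sel <- which(is_misinc & t0 == b)
    if (length(sel) == 0) next
    row <- spec[paste0(b, ">", setdiff(BASES, b))]
    if (sum(row) <= 0) next  # spectrum carries no mass for this template base
    mis_obs[sel] <- sample(setdiff(BASES, b), length(sel), replace = TRUE,
                           prob = row / sum(row))
  }
  inj <- which(!is.na(mis_obs))
  chars[end_flat[inj]] <- mis_obs[inj]
  add_events(inj, end_flat[inj], mis_obs[inj], "misincorporation")

  # --- U>C read-through at offsets -1 and -2 -----------------------------
  for (off in c(-1L, -2L)) {
    fp <- end_flat + off
    hit <- which(tmpl[fp] == "T" & runif(n) < config$readthrough_rate)
    if (length(hit)) {
      chars[fp[hit]] <- "C"
      add_events(hit, fp[hit], rep("C", length(hit)), "readthrough")
    }
  }

  # --- experimental layers ------------------------------------------------
  N <- length(chars)
  seq_hit <- integer(0)
  layers <- list(rt = config$rt_error_rate,
                 pcr = config$pcr_cycles * config$pcr_error_rate,
                 sequencing = config$seq_error_rate)
  alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                nrow = 3, dimnames = list(NULL, BASES))
  for (lname in names(layers)) {
    rate <- layers[[lname]]
    if (rate <= 0) next
    hit <- which(runif(N) < rate)
    if (length(hit) == 0) next
    cur <- chars[hit]
    ok <- cur %in% BASES
    hit <- hit[ok]; cur <- cur[ok]
    newb <- alt[cbind(sample.int(3, length(hit), replace = TRUE),
                      match(cur, BASES))]
    chars[hit] <- newb
    add_events(fi$read[hit], hit, newb, lname)
    if (lname == "sequencing") seq_hit <- hit
  }

  # --- qualities ----------------------------------------------------------
  qm <- config$quality_model
  q <- round(rnorm(N, qm$correct_mean, qm$correct_sd))
  if (length(seq_hit)) {
    q[seq_hit] <- round(rnorm(length(seq_hit), qm$miscall_mean, qm$miscall_sd))
  }
  q <- pmin(pmax(q, qm$qmin), qm$qmax)

  big_seq <- paste(chars, collapse = "")
  big_qual <- intToUtf8(q + 33L)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  read_id <- sprintf("read%07d", seq_len(n))

  reads <- tibble::tibble(read_id = read_id,
                          sequence = substring(big_seq, starts, ends),
                          qualities = substring(big_qual, starts, ends))
  events <- if (length(ev)) dplyr::bind_rows(ev) else
    tibble::tibble(read = integer(), offset = integer(),
                   template_base = character(), read_base = character(),
                   layer = character())
  events <- dplyr::arrange(
    tibble::tibble(read_id = read_id[events$read],
                   contig = ecs$contig[events$read],
                   strand = ecs$strand[events$read],
                   pos3 = ecs$pos3[events$read],
                   offset = events$offset,
                   template_base = events$template_base,
                   read_base = events$read_base,
                   layer = events$layer),
    .data$read_id, .data$offset)
  truth_reads <- tibble::tibble(read_id = read_id, contig = ecs$contig,
                                strand = ecs$strand, pos3 = ecs$pos3,
                                is_misincorporated_ec = is_misinc)
  list(reads = reads, truth = list(reads = truth_reads, events = events))
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: genome + annotation, planted strain variants, EC
#' sampling, and read synthesis (from the variant-carrying strain genome).
#'
#' @param config a [sim_config()].
#' @param weights optional per-gene abundance weights.
#' @return list: `reference` (genome the analysis aligns to), `strain_genome`,
#'   `annotation`, `variants`, `ecs`, `reads`, `truth`.
#' @export
simulate_netseq <- function(config = sim_config(), weights = NULL) {
  ref <- generate_genome(config)
  pv <- plant_variants(ref$genome, ref$annotation, config$variant_positions,
                       seed = config$seed)
  ecs <- sample_elongation_complexes(ref$genome, ref$annotation, config, weights)
  syn <- synthesize_reads(ecs, pv$genome, config)
  list(reference = ref$genome, strain_genome = pv$genome,
       annotation = ref$annotation, variants = pv$variants,
       ecs = ecs, reads = syn$reads, truth = syn$truth)
}
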