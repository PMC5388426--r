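#' Pipeline configuration
#'
#' One object wiring every stage: synthetic-data generation (or persisted
#' inputs), read QC, alignment, variant masking, spectrum, hotspot/context,
#' region rates and the accuracy model. A single run seed drives per-stage
#' substreams, so reruns with the same config are byte-identical.
#'
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param preprocess list: min_length, adapter (NULL = no trimming),
#'   min_overlap, drop_n_3prime_adjacent, blacklist (interval tibble or BED
#'   path or NULL).
#' @param align list: seed_len, seed_mismatches, unique_only, circular.
#' @param varmask list: min_depth, min_alt_fraction.
#' @param spectrum list: phred_min, window.
#' @param context list: min_count, halfwidth, substitution.
#' @param regions list: mode.
#' @param accuracy an [error_budget()].
#' @param seed run seed.
#' @param outdir output directory for persisted artifacts (NULL = in-memory
#'   only).
#' @param stages named logical toggles: simulate, varmask, context, regions,
#'   accuracy, truth. With `simulate = FALSE` the simulate-stage artifacts
#'   (reads.fastq, genome.fa, annotation.gff3, utrs.bed, truth.tsv) are read
#'   back from `outdir` instead of being regenerated.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            preprocess = list(),
                            align = list(),
                            varmask = list(),
                            spectrum = list(),
                            context = list(),
                            regions = list(),
                            accuracy = error_budget(),
                            seed = 1L,
                            outdir = NULL,
                            stages = list()) {
  defaults <- list(
    preprocess = list(min_length = 16, adapter = NULL, min_overlap = 3,
                      drop_n_3prime_adjacent = TRUE, blacklist = NULL),
    align = list(seed_len = 14, seed_mismatches = 2, unique_only = TRUE,
                 circular = FALSE),
    varmask = list(min_depth = 10, min_alt_fraction = 0.8),
    spectrum = list(phred_min = 30, window = 11),
    context = list(min_count = 50, halfwidth = 5, substitution = "G>A"),
    regions = list(mode = "bacteria"),
    stages = list(simulate = TRUE, varmask = TRUE, context = TRUE,
                  regions = TRUE, accuracy = TRUE, truth = TRUE))
  merge1 <- function(d, u) { d[names(u)] <- u; d }
  sim$seed <- as.integer(seed)
  structure(list(
    sim = sim,
    preprocess = merge1(defaults$preprocess, preprocess),
    align = merge1(defaults$align, align),
    varmask = merge1(defaults$varmask, varmask),
    spectrum = merge1(defaults$spectrum, spectrum),
    context = merge1(defaults$context, context),
    regions = merge1(defaults$regions, regions),
    accuracy = accuracy,
    seed = as.integer(seed), outdir = outdir,
    stages = merge1(defaults$stages, stages)
  ), class = "pipeline_config")
}

persist <- function(outdir, name, writer) {
  if (!is.null(outdir)) writer(file.path(outdir, name))
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> align -> variant masking -> positional spectrum
#' -> hotspots/context -> region rates -> accuracy model -> truth comparison,
#' with artifacts persisted to `config$outdir` (FASTA/GFF3/BED/FASTQ/SAM/
#' VCF/TSV) and per-stage record counts logged via `message()`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages?
#' @return a `run_report` list: filter_report, alignment_summary, variants,
#'   error_table, misincorporated_ec_percent, sweep, hotspots, pfm,
#'   region_table, accuracy, truth_comparison (synthetic runs only), plus the
#'   inputs needed to inspect the run.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }

  # --- simulate (or load persisted inputs) --------------------------------
  if (isTRUE(config$stages$simulate)) {
    sim <- simulate_netseq(config$sim)
    say("simulate: %d reads from %d ECs, %d planted variants",
        nrow(sim$reads), nrow(sim$ecs), nrow(sim$variants))
    persist(outdir, "genome.fa", function(p) write_genome_fasta(sim$reference, p))
    persist(outdir, "annotation.gff3", function(p) write_gff3(sim$annotation, p))
    persist(outdir, "utrs.bed", function(p) {
      utr <- sim$annotation[grepl("UTR", sim$annotation$type), , drop = FALSE]
      write_bed(utr, p)
    })
    persist(outdir, "reads.fastq", function(p) write_reads_fastq(sim$reads, p))
    persist(outdir, "truth.tsv", function(p) write_truth_table(sim$truth, p))
    genome <- sim$reference
    annotation <- as_annotation_set(sim$annotation, config$regions$mode)
    reads <- sim$reads
    truth <- sim$truth
  } else {
    if (is.null(outdir)) stop("stage 'simulate' is off but no outdir to load from")
    genome <- read_genome_fasta(file.path(outdir, "genome.fa"))
    utr_bed <- file.path(outdir, "utrs.bed")
    annotation <- load_annotation(file.path(outdir, "annotation.gff3"),
                                  utr_bed = if (file.exists(utr_bed)) utr_bed,
                                  mode = config$regions$mode)
    reads <- read_reads_fastq(file.path(outdir, "reads.fastq"))
    truth_path <- file.path(outdir, "truth.tsv")
    truth <- if (file.exists(truth_path)) read_truth_table(truth_path)
    say("load: %d reads from %s", nrow(reads), outdir)
  }

  # --- preprocess ----------------------------------------------------------
  pp <- config$preprocess
  if (!is.null(pp$adapter)) reads <- trim_adapter(reads, pp$adapter, pp$min_overlap)
  flt <- filter_reads(reads, pp$min_length, pp$drop_n_3prime_adjacent)
  reads <- flt$reads
  report <- flt$report
  say("preprocess: %d in, %d surviving", report$input, report$surviving)

  # --- align ---------------------------------------------------------------
  al <- config$align
  alignments <- align_reads(reads, genome, al$seed_len, al$seed_mismatches,
                            al$unique_only, al$circular)
  blacklist <- pp$blacklist
  if (is.character(blacklist)) blacklist <- read_bed(blacklist)
  bl <- apply_blacklist(alignments, blacklist)
  alignments <- bl$alignments
  report$dropped_blacklist <- bl$n_dropped
  aln_summary <- alignment_summary(alignments)
  say("align: %d aligned, %d multimapped, %d unaligned, %d blacklisted",
      aln_summary$aligned, aln_summary$multimapped, aln_summary$unaligned,
      bl$n_dropped)
  persist(outdir, "alignments.sam",
          function(p) write_sam(alignments, reads, genome, p))

  # --- variant masking -----------------------------------------------------
  variants <- NULL
  if (isTRUE(config$stages$varmask)) {
    cols <- pileup(alignments, reads, genome)
    variants <- call_variants(cols, config$varmask$min_depth,
                              config$varmask$min_alt_fraction)
    say("varmask: %d variant position(s) called", nrow(variants))
    persist(outdir, "variants.vcf", function(p) write_vcf(variants, p))
  }

  # --- spectrum ------------------------------------------------------------
  sp <- config$spectrum
  extract <- function() extract_mismatch_events(alignments, reads, genome,
                                                variants, sp$phred_min,
                                                sp$window)
  ex <- if (quiet) suppressMessages(extract()) else extract()
  table <- positional_error_table(ex$events, ex$denominators)
  ec_percent <- misincorporated_ec_fraction(table)
  sweep <- threshold_sweep(ex$events)
  say("spectrum: %d events; misincorporated ECs %.3f%%",
      nrow(ex$events), ec_percent)
  persist(outdir, "events.tsv", function(p) write_tsv_plain(
    dplyr::mutate(ex$events, genomic_position = .data$genomic_position + 1L), p))
  persist(outdir, "error_table.tsv",
          function(p) write_tsv_plain(tidy(table), p))
  persist(outdir, "error_table.json", function(p) jsonlite::write_json(
    list(total = table$total, specific = table$specific), p, digits = NA))

  # --- hotspots & context --------------------------------------------------
  hotspots <- pfm <- NULL
  if (isTRUE(config$stages$context)) {
    cx <- config$context
    hotspots <- call_hotspots(ex$events, cx$substitution, cx$min_count)
    hotspots <- hotspot_contexts(hotspots, genome, cx$halfwidth, al$circular)
    if (nrow(hotspots) > 0) {
      pfm <- position_frequency_matrix(hotspots$context)
    }
    say("context: %d hotspot(s) (> %d events, %s)", nrow(hotspots),
        cx$min_count, cx$substitution)
    persist(outdir, "hotspots.bed", function(p) write_hotspots(hotspots, p))
    if (!is.null(pfm)) {
      persist(outdir, "pfm.tsv", function(p) write_tsv_plain(tidy(pfm), p))
    }
  }

  # --- region rates --------------------------------------------------------
  region_table <- NULL
  if (isTRUE(config$stages$regions)) {
    region_table <- region_rate_table(ex$events, hotspots, annotation)
    persist(outdir, "region_table.tsv",
            function(p) write_tsv_plain(region_table, p))
  }

  # --- accuracy model ------------------------------------------------------
  accuracy <- NULL
  if (isTRUE(config$stages$accuracy)) {
    accuracy <- accuracy_by_offset(table, config$accuracy)
    persist(outdir, "accuracy.json",
            function(p) jsonlite::write_json(accuracy, p, digits = NA))
  }

  report_obj <- structure(list(
    filter_report = report,
    alignment_summary = aln_summary,
    variants = variants,
    events = ex$events,
    denominators = ex$denominators,
    error_table = table,
    misincorporated_ec_percent = ec_percent,
    sweep = sweep,
    hotspots = hotspots,
    pfm = pfm,
    region_table = region_table,
    accuracy = accuracy,
    truth_comparison = NULL,
    config = config
  ), class = "run_report")

  # --- truth comparison (synthetic runs) ----------------------------------
  if (isTRUE(config$stages$truth) && !is.null(truth)) {
    report_obj$truth_comparison <- compare_to_truth(report_obj, truth)
    say("truth: injected %.3f%% vs recovered %.3f%% at the 3' terminus",
        report_obj$truth_comparison$injected_percent,
        report_obj$truth_comparison$recovered_percent)
  }
  persist(outdir, "report.json", function(p) write_run_report_json(report_obj, p))
  report_obj
}

#' Compare a run report against the simulation ground truth
#'
#' Reports the injected versus recovered misincorporated-EC percentage, a
#' per-substitution confusion between injected misincorporation events and
#' recovered offset-0 events, and hotspot recall/precision against positions
#' where the generator injected more than the hotspot threshold of events.
#'
#' @param report a `run_report` (or a list with `events`, `error_table`,
#'   `hotspots`, `config`).
#' @param truth truth list from [synthesize_reads()].
#' @return list: injected_percent, recovered_percent, substitution_confusion
#'   (tibble), hotspot_recall, hotspot_precision.
#' @export
compare_to_truth <- function(report, truth) {
  injected <- 100 * mean(truth$reads$is_misincorporated_ec)
  recovered <- report$misincorporated_ec_percent

  inj_ev <- truth$events[truth$events$layer == "misincorporation", , drop = FALSE]
  rec_ev <- report$events[report$events$offset == 0, , drop = FALSE]
  key_inj <- paste(inj_ev$read_id, inj_ev$offset)
  key_rec <- paste(rec_ev$read_id, rec_ev$offset)
  shared <- intersect(key_inj, key_rec)
  confusion <- if (length(shared)) {
    dplyr::count(
      tibble::tibble(
        injected = paste0(inj_ev$template_base, ">", inj_ev$read_base)[
          match(shared, key_inj)],
        recovered = rec_ev$substitution[match(shared, key_rec)]),
      .data$injected, .data$recovered, name = "n")
  } else {
    tibble::tibble(injected = character(), recovered = character(),
                   n = integer())
  }

  hotspot_recall <- hotspot_precision <- NA_real_
  if (!is.null(report$hotspots)) {
    min_count <- report$config$context$min_count
    truth_pos <- dplyr::count(inj_ev, .data$contig, .data$pos3, .data$strand)
    truth_hot <- truth_pos[truth_pos$n > min_count, , drop = FALSE]
    called <- paste(report$hotspots$contig, report$hotspots$position,
                    report$hotspots$strand)
    truthk <- paste(truth_hot$contig, truth_hot$pos3, truth_hot$strand)
    if (nrow(truth_hot) > 0) hotspot_recall <- mean(truthk %in% called)
    if (length(called) > 0) hotspot_precision <- mean(called %in% truthk)
  }
  list(injected_percent = injected, recovered_percent = recovered,
       substitution_confusion = confusion,
       hotspot_recall = hotspot_recall, hotspot_precision = hotspot_precision)
}

write_run_report_json <- function(report, path) {
  out <- list(
    filter_report = report$filter_report,
    alignment_summary = report$alignment_summary,
    n_variants = if (!is.null(report$variants)) nrow(report$variants),
    error_table = list(total = report$error_table$total,
                       specific = report$error_table$specific),
    misincorporated_ec_percent = report$misincorporated_ec_percent,
    threshold_sweep = report$sweep,
    n_hotspots = if (!is.null(report$hotspots)) nrow(report$hotspots),
    region_table = report$region_table,
    accuracy = report$accuracy,
    truth_comparison = if (!is.null(report$truth_comparison)) {
      tc <- report$truth_comparison
      list(injected_percent = tc$injected_percent,
           recovered_percent = tc$recovered_percent,
           hotspot_recall = tc$hotspot_recall,
           hotspot_precision = tc$hotspot_precision)
    })
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("NET-seq fidelity run\n")
  cat(sprintf("  reads: %d in, %d aligned (%d multimapped, %d unaligned)\n",
              x$filter_report$input, x$alignment_summary$aligned,
              x$alignment_summary$multimapped, x$alignment_summary$unaligned))
  if (!is.null(x$variants)) {
    cat(sprintf("  variants masked: %d\n", nrow(x$variants)))
  }
  cat(sprintf("  misincorporated ECs: %.3f%% of reads\n",
              x$misincorporated_ec_percent))
  if (!is.null(x$hotspots)) cat(sprintf("  hotspots: %d\n", nrow(x$hotspots)))
  if (!is.null(x$truth_comparison)) {
    cat(sprintf("  truth: injected %.3f%%, recovered %.3f%%\n",
                x$truth_comparison$injected_percent,
                x$truth_comparison$recovered_percent))
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x a `run_report`.
#' @param ... unused.
#' @export
glance.run_report <- function(x, ...) {
  tibble::tibble(
    reads_in = x$filter_report$input,
    aligned = x$alignment_summary$aligned,
    multimapped = x$alignment_summary$multimapped,
    unaligned = x$alignment_summary$unaligned,
    n_variants = if (!is.null(x$variants)) nrow(x$variants) else NA_integer_,
    misincorporated_ec_percent = x$misincorporated_ec_percent,
    n_hotspots = if (!is.null(x$hotspots)) nrow(x$hotspots) else NA_integer_,
    tp_fraction_3prime = if (!is.null(x$accuracy)) {
      x$accuracy$tp_fraction_percent[x$accuracy$offset == 0]
    } else NA_real_)
}
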