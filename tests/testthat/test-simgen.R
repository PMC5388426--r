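test_that("genome generation is deterministic and respects GC content", {
  cfg <- sim_config(genome_length = 100000, gc_fraction = 0.5, n_genes = 10,
                    seed = 5)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$annotation, g2$annotation)

  # empirical GC within 3 binomial standard deviations of expectation
  counts <- table(strsplit(g1$genome[[1]], "")[[1]])
  gc <- sum(counts[c("C", "G")])
  expect_lt(abs(gc - 50000), 3 * sqrt(100000 * 0.25))
})

test_that("gene models are well formed and non-overlapping", {
  cfg <- sim_config(genome_length = 50000, n_genes = 15, seed = 2)
  ann <- generate_genome(cfg)$annotation
  cds <- ann[ann$type == "CDS", ]
  expect_true(all((cds$end - cds$start) %% 3 == 0))
  spans <- netfidelity:::transcript_spans(ann)
  o <- order(spans$start)
  expect_true(all(spans$start[o][-1] >= spans$end[o][-nrow(spans)]))
  # each gene has 5'UTR / CDS / 3'UTR in transcript order
  for (gid in unique(ann$gene_id)) {
    g <- ann[ann$gene_id == gid, ]
    g <- g[order(g$start), ]
    expected <- if (g$strand[1] == "+") {
      c("five_prime_UTR", "CDS", "three_prime_UTR")
    } else {
      c("three_prime_UTR", "CDS", "five_prime_UTR")
    }
    expect_identical(g$type, expected)
  }
})

test_that("degenerate genome cases behave", {
  cfg <- sim_config(genome_length = 5000, n_genes = 0, seed = 1)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$annotation), 0)
  expect_equal(nchar(g$genome[[1]]), 5000)
  expect_error(generate_genome(sim_config(genome_length = 1000, n_genes = 5,
                                          seed = 1)),
               "too small")
})

test_that("EC positions respect transcript bounds and abundance weights", {
  cfg <- sim_config(genome_length = 20000, n_genes = 4, n_ecs = 5,
                    seed = 9)
  sim <- generate_genome(cfg)
  tx <- netfidelity:::transcript_spans(sim$annotation)
  w <- setNames(c(1, 0, 0, 0), tx$gene_id)
  ecs <- sample_elongation_complexes(sim$genome, sim$annotation, cfg, w)
  expect_equal(nrow(ecs), 5)
  expect_true(all(ecs$gene_id == tx$gene_id[1]))
  span <- tx[1, ]
  expect_true(all(ecs$pos3 >= span$start & ecs$pos3 < span$end))
  # the full longest read must fit inside the transcript upstream of pos3
  if (span$strand == "+") {
    expect_true(all(ecs$pos3 - cfg$read_length_max + 1 >= span$start))
  } else {
    expect_true(all(ecs$pos3 + cfg$read_length_max - 1 < span$end))
  }
})

test_that("per-gene EC counts are multinomial under uniform weights", {
  cfg <- sim_config(genome_length = 40000, n_genes = 8, n_ecs = 8000, seed = 3)
  sim <- generate_genome(cfg)
  tx <- netfidelity:::transcript_spans(sim$annotation)
  w <- setNames(rep(1, nrow(tx)), tx$gene_id)
  ecs <- sample_elongation_complexes(sim$genome, sim$annotation, cfg, w)
  counts <- table(factor(ecs$gene_id, levels = tx$gene_id))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("error-free reads are exact transcript-space genomic substrings", {
  cfg <- sim_config(genome_length = 20000, n_genes = 5, n_ecs = 500,
                    misinc_fraction = 0, readthrough_rate = 0,
                    rt_error_rate = 0, pcr_error_rate = 0, seq_error_rate = 0,
                    seed = 11)
  sim <- simulate_netseq(cfg)
  len <- nchar(sim$reads$sequence)
  plus <- sim$ecs$strand == "+"
  expected <- character(nrow(sim$ecs))
  g <- sim$reference[sim$ecs$contig]
  expected[plus] <- substring(g[plus], sim$ecs$pos3[plus] - len[plus] + 2,
                              sim$ecs$pos3[plus] + 1)
  expected[!plus] <- revcomp(substring(g[!plus], sim$ecs$pos3[!plus] + 1,
                                       sim$ecs$pos3[!plus] + len[!plus]))
  expect_identical(sim$reads$sequence, unname(expected))
  expect_equal(nrow(sim$truth$events), 0)
  expect_false(any(sim$truth$reads$is_misincorporated_ec))
})

test_that("an all-G>A spectrum converts every G-ended template and flags all ECs", {
  spec <- setNames(rep(0, 12), netfidelity:::SUBSTITUTIONS)
  spec["G>A"] <- 1
  cfg <- sim_config(genome_length = 20000, n_genes = 5, n_ecs = 2000,
                    misinc_fraction = 1, substitution_spectrum = spec,
                    readthrough_rate = 0, rt_error_rate = 0,
                    pcr_error_rate = 0, seq_error_rate = 0, seed = 13)
  sim <- simulate_netseq(cfg)
  expect_true(all(sim$truth$reads$is_misincorporated_ec))
  ev <- sim$truth$events
  expect_true(all(ev$layer == "misincorporation"))
  expect_true(all(ev$offset == 0))
  expect_true(all(ev$template_base == "G" & ev$read_base == "A"))
  # recount from the truth table: every read whose template 3' base is G
  # must now end in A
  g_template <- ev$read_id
  last <- substring(sim$reads$sequence, nchar(sim$reads$sequence))
  expect_true(all(last[sim$reads$read_id %in% g_template] == "A"))
})

test_that("sequencing-layer event count matches its Poisson expectation", {
  cfg <- sim_config(genome_length = 30000, n_genes = 6, n_ecs = 20000,
                    misinc_fraction = 0, readthrough_rate = 0,
                    rt_error_rate = 0, pcr_error_rate = 0,
                    seq_error_rate = 0.001, seed = 17)
  sim <- simulate_netseq(cfg)
  n_bases <- sum(nchar(sim$reads$sequence))
  lambda <- 0.001 * n_bases
  n_seq <- sum(sim$truth$events$layer == "sequencing")
  expect_lt(abs(n_seq - lambda), 3 * sqrt(lambda))
})

test_that("truth records conserve reads and match emitted sequences", {
  sim <- small_sim(seed = 23, n_ecs = 3000, variant_positions = 0)
  expect_equal(nrow(sim$truth$reads), nrow(sim$reads))
  ev <- sim$truth$events
  # last event per (read, offset) must agree with the emitted base
  last <- dplyr::slice_tail(
    dplyr::group_by(ev, .data$read_id, .data$offset), n = 1)
  rl <- nchar(sim$reads$sequence)[match(last$read_id, sim$reads$read_id)]
  emitted <- substring(sim$reads$sequence[match(last$read_id, sim$reads$read_id)],
                       rl + last$offset, rl + last$offset)
  expect_identical(emitted, last$read_base)
  expect_true(all(ev$offset <= 0))
  expect_true(all(ev$offset[ev$layer == "misincorporation"] == 0))
  expect_true(all(ev$offset[ev$layer == "readthrough"] %in% c(-1L, -2L)))
})

test_that("misincorporated-EC fraction converges to misinc_fraction", {
  sim <- small_sim(seed = 31, n_ecs = 20000, misinc = 0.05)
  phat <- mean(sim$truth$reads$is_misincorporated_ec)
  ci <- 2.576 * sqrt(0.05 * 0.95 / 20000)
  expect_lt(abs(phat - 0.05), ci)
})

test_that("without motif boost, misincorporation is independent of the C-1G motif", {
  cfg <- sim_config(genome_length = 10000, n_genes = 3, n_ecs = 30000,
                    misinc_fraction = 0.1, hotspot_motif_boost = 1, seed = 37)
  sim <- simulate_netseq(cfg)
  len <- nchar(sim$reads$sequence)
  # template bases at 0 and -1 from the EC position on the reference
  plus <- sim$ecs$strand == "+"
  g <- sim$reference[sim$ecs$contig]
  t0 <- ifelse(plus, substring(g, sim$ecs$pos3 + 1, sim$ecs$pos3 + 1),
               chartr("ACGT", "TGCA",
                      substring(g, sim$ecs$pos3 + 1, sim$ecs$pos3 + 1)))
  tm1pos <- ifelse(plus, sim$ecs$pos3, sim$ecs$pos3 + 2)
  tm1 <- ifelse(plus, substring(g, tm1pos + 1, tm1pos + 1),
                chartr("ACGT", "TGCA", substring(g, tm1pos + 1, tm1pos + 1)))
  motif <- tm1 == "C" & t0 == "G"
  tab <- table(motif, sim$truth$reads$is_misincorporated_ec)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("config validation rejects malformed spectra and rates", {
  expect_error(sim_config(substitution_spectrum = rep(1 / 12, 12)), "named")
  bad <- default_substitution_spectrum()
  bad["G>A"] <- bad["G>A"] + 0.01
  expect_error(sim_config(substitution_spectrum = bad), "sum to 1")
  expect_error(sim_config(misinc_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(read_length_min = 10), "seed length")
  expect_error(synthesize_reads(tibble::tibble(), c(chr1 = "ACGT"),
                                sim_config()),
               "empty")
})
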