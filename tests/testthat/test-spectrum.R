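aligned_row <- function(read_id, contig, start, strand, read_length,
                        n_mismatch = 0L) {
  tibble::tibble(read_id = read_id, status = "aligned", contig = contig,
                 start = start, strand = strand, read_length = read_length,
                 n_mismatch = n_mismatch,
                 mismatch_offsets = list(integer(0)))
}

test_that("event extraction applies the quality threshold per mismatch", {
  genome <- rand_genome(300, seed = 1)
  rd <- substr(genome, 101, 120)                       # aligned at 100, len 20
  last <- substr(rd, 20, 20)
  substr(rd, 20, 20) <- setdiff(c("A", "C", "G", "T"), last)[1]  # offset 0
  mid <- substr(rd, 15, 15)
  substr(rd, 15, 15) <- setdiff(c("A", "C", "G", "T"), mid)[1]   # offset -5
  # Q35 at offset 0 (passes), Q29 at offset -5 (fails: one below threshold)
  q <- strrep("I", 20)
  substr(q, 20, 20) <- intToUtf8(35 + 33)
  substr(q, 15, 15) <- intToUtf8(29 + 33)
  reads <- tibble::tibble(read_id = "r1", sequence = rd, qualities = q)
  aln <- aligned_row("r1", "chr1", 100L, "+", 20L)
  out <- extract_mismatch_events(aln, reads, genome)
  expect_equal(nrow(out$events), 1)
  expect_equal(out$events$offset, 0)
  expect_equal(out$events$quality, 35)
  expect_equal(out$events$genomic_position, 119)
  # the low-quality mismatch still counts in the denominator
  expect_true(all(out$denominators$denominator_reads == 1))
  # exactly Q30 passes (threshold is >=)
  substr(q, 15, 15) <- intToUtf8(30 + 33)
  reads$qualities <- q
  out2 <- extract_mismatch_events(aln, reads, genome)
  expect_equal(sort(out2$events$offset), c(-5L, 0L))
  # quality-filtered denominators drop sub-threshold bases
  substr(q, 10, 10) <- intToUtf8(5 + 33)
  reads$qualities <- q
  out3 <- extract_mismatch_events(aln, reads, genome,
                                  quality_filtered_denominator = TRUE)
  d <- out3$denominators
  expect_equal(d$denominator_reads[d$offset == -10], 0)
  expect_equal(d$denominator_reads[d$offset == 0], 1)
})

test_that("minus-strand events report transcript-space template bases", {
  genome <- c(chr1 = "TTTTTTTTTTGGGGGGGGGGGGGGGGGGGG")
  # minus-strand read over genomic [10, 30): transcript = revcomp(G...G) = C...C
  rd <- strrep("C", 19)
  rd <- paste0(rd, "A")  # 3' terminal A: template C (complement of genomic G)
  reads <- tibble::tibble(read_id = "m1", sequence = rd,
                          qualities = strrep("I", 20))
  aln <- aligned_row("m1", "chr1", 10L, "-", 20L)
  out <- extract_mismatch_events(aln, reads, genome)
  expect_equal(nrow(out$events), 1)
  expect_identical(out$events$substitution, "C>A")
  # minus-strand 3' terminus maps to the leftmost genomic coordinate
  expect_equal(out$events$genomic_position, 10)
  expect_identical(out$events$strand, "-")
})

test_that("N in read or template is never an event; short reads truncate", {
  genome <- c(chr1 = paste0(strrep("A", 10), "N", strrep("A", 30)))
  rd <- paste0(strrep("A", 9), "N", strrep("A", 4), "C")  # len 15, at start 1
  reads <- tibble::tibble(read_id = "n1", sequence = rd,
                          qualities = strrep("I", 15))
  aln <- aligned_row("n1", "chr1", 1L, "+", 15L)
  out <- extract_mismatch_events(aln, reads, genome)
  # read N at offset -5 and template N at offset -6: neither is an event;
  # the C over template A at offset 0 is
  expect_equal(out$events$offset, 0L)
  d <- out$denominators
  expect_equal(d$denominator_reads[d$offset == -5], 0)   # read base N
  expect_equal(d$denominator_reads[d$offset == -6], 1)   # template N, read A
  # a 5-nt-aligned read contributes only offsets 0..-4
  aln5 <- aligned_row("s1", "chr1", 20L, "+", 5L)
  reads5 <- tibble::tibble(read_id = "s1", sequence = "AAAAA",
                           qualities = "IIIII")
  d5 <- extract_mismatch_events(aln5, reads5, genome)$denominators
  expect_equal(d5$denominator_reads[d5$offset >= -4], rep(1L, 5))
  expect_equal(d5$denominator_reads[d5$offset < -4], rep(0L, 6))
})

test_that("positional error table arithmetic is exact", {
  # 1000 reads, 30 with an offset-0 mismatch -> 3.0%
  genome <- rand_genome(5000, seed = 9)
  starts <- seq(0, 999) * 4 %% 4800
  rd <- substring(genome, starts + 1, starts + 20)
  flip <- 1:30
  last <- substring(rd[flip], 20, 20)
  substring(rd[flip], 20, 20) <- vapply(last, function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  reads <- reads_tbl(unname(rd))
  aln <- aligned_row(reads$read_id, "chr1", as.integer(starts), "+", 20L)
  out <- extract_mismatch_events(aln, reads, genome)
  tab <- positional_error_table(out$events, out$denominators)
  t0 <- tab$total[tab$total$offset == 0, ]
  expect_equal(t0$denominator_reads, 1000)
  expect_equal(t0$mismatch_reads, 30)
  expect_equal(t0$total_rate_percent, 3.0)
  expect_equal(misincorporated_ec_fraction(tab), 3.0)
  # specific rates sum to the total when each read has at most one event
  s0 <- tab$specific[tab$specific$offset == 0, ]
  expect_equal(sum(s0$count), 30)
  expect_equal(sum(s0$rate_percent), 3.0)
  # tidy/glance accessors
  td <- tidy(tab)
  expect_equal(nrow(td), 11 * 12)
  gl <- glance(tab)
  expect_equal(gl$misincorporated_ec_percent, 3.0)
  expect_equal(gl$n_offsets, 11)
})

test_that("zero-denominator offsets give NA rates and EC fraction errors", {
  out <- extract_mismatch_events(
    aligned_row(character(0), character(0), integer(0), character(0),
                integer(0)),
    tibble::tibble(read_id = character(), sequence = character(),
                   qualities = character()),
    c(chr1 = "ACGT"))
  tab <- positional_error_table(out$events, out$denominators)
  expect_true(all(is.na(tab$total$total_rate_percent)))
  expect_error(misincorporated_ec_fraction(tab), "zero denominator")
})

test_that("spectrum recount matches the naive oracle on a small simulation", {
  sim <- small_sim(seed = 404, n_ecs = 400, misinc = 0.1)
  aln <- align_reads(sim$reads, sim$reference)
  out <- extract_mismatch_events(aln, sim$reads, sim$reference, sim$variants)
  oo <- oracle_recount(aln, sim$reads, as.list(sim$reference),
                       variants = sim$variants)
  tab <- positional_error_table(out$events, out$denominators)
  expect_equal(tab$total$denominator_reads,
               unname(oo$denominators[as.character(tab$total$offset)]))
  # the oracle counts events (not distinct reads); compare specific counts
  spec <- tidyr::pivot_wider(tab$specific[, c("offset", "substitution", "count")],
                             names_from = "substitution",
                             values_from = "count")
  for (i in seq_len(nrow(spec))) {
    expect_equal(unlist(spec[i, netfidelity:::SUBSTITUTIONS]),
                 oo$specific[as.character(spec$offset[i]), ],
                 ignore_attr = TRUE)
  }
})

test_that("error-free alignments yield an all-zero table", {
  cfg <- sim_config(genome_length = 20000, n_genes = 5, n_ecs = 500,
                    misinc_fraction = 0, readthrough_rate = 0,
                    rt_error_rate = 0, pcr_error_rate = 0, seq_error_rate = 0,
                    seed = 7)
  sim <- simulate_netseq(cfg)
  aln <- align_reads(sim$reads, sim$reference)
  out <- extract_mismatch_events(aln, sim$reads, sim$reference)
  expect_equal(nrow(out$events), 0)
  tab <- positional_error_table(out$events, out$denominators)
  expect_true(all(tab$total$mismatch_reads == 0))
  expect_true(all(tab$total$total_rate_percent == 0))
})

test_that("recovered EC fraction tracks the injected misincorporation rate", {
  sim <- small_sim(seed = 500, n_ecs = 20000, misinc = 0.05)
  aln <- align_reads(sim$reads, sim$reference)
  out <- extract_mismatch_events(aln, sim$reads, sim$reference, sim$variants)
  tab <- positional_error_table(out$events, out$denominators)
  f <- misincorporated_ec_fraction(tab)
  # 99% binomial interval around 5%, plus slack for experimental-noise layers
  expect_lt(abs(f - 5), 2.576 * sqrt(5 * 95 / 20000) + 0.3)
  # interior offsets (excluding readthrough at -1/-2) sit near the noise floor
  interior <- tab$total$total_rate_percent[tab$total$offset <= -3]
  expect_true(all(interior < 0.5))
  expect_identical(glance(tab)$modal_substitution_3prime, "G>A")
})

test_that("threshold sweep counts strictly-greater locations", {
  ev <- tibble::tibble(
    read_id = sprintf("r%02d", 1:62),
    contig = "chr1",
    genomic_position = c(rep(100L, 60), 200L, 300L),
    strand = "+",
    offset = 0L,
    template_base = "G", read_base = "A", quality = 38L,
    substitution = "G>A")
  sw <- threshold_sweep(ev, thresholds = c(0L, 1L, 50L, 59L, 60L))
  expect_equal(sw$n_positions, c(3L, 1L, 1L, 1L, 0L))
  expect_equal(sw$n_ecs, c(62L, 60L, 60L, 60L, 0L))
  # default grid is non-increasing in both series
  sim <- small_sim(seed = 77, n_ecs = 8000, misinc = 0.1)
  aln <- align_reads(sim$reads, sim$reference)
  out <- extract_mismatch_events(aln, sim$reads, sim$reference, sim$variants)
  sw2 <- threshold_sweep(out$events)
  expect_true(all(diff(sw2$n_positions) <= 0))
  expect_true(all(diff(sw2$n_ecs) <= 0))
})
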