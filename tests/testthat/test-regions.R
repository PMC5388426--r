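toy_annotation <- function() {
  build_annotation_set(
    tibble::tibble(
      contig = "chr1",
      strand = c("+", "+", "+", "-"),
      start = c(100L, 200L, 500L, 700L),
      end = c(200L, 260L, 620L, 800L),
      class = c("transcribed_untranslated", "translated", "translated",
                "transcribed_untranslated")),
    c(chr1 = 1000L), "bacteria")
}

test_that("GFF3/BED round trip preserves the coordinate convention", {
  cfg <- sim_config(genome_length = 20000, n_genes = 4, seed = 3)
  sim <- generate_genome(cfg)
  gff <- tempfile(fileext = ".gff3")
  bed <- tempfile(fileext = ".bed")
  write_gff3(sim$annotation, gff)
  utr <- sim$annotation[grepl("UTR", sim$annotation$type), ]
  write_bed(utr, bed)

  # a feature written from internal [100, 200) must read back identically
  loaded <- load_annotation(gff, bed)
  direct <- as_annotation_set(sim$annotation)
  key <- function(a) paste(a$contig, a$strand, a$start, a$end, a$class)
  expect_setequal(key(loaded), key(direct))
  expect_equal(attr(loaded, "contig_lengths"),
               c(chr1 = cfg$genome_length))

  # and the GFF3 text itself is 1-based inclusive
  lines <- readLines(gff)
  cds <- sim$annotation[sim$annotation$type == "CDS", ][1, ]
  expect_true(any(grepl(sprintf("\t%d\t%d\t", cds$start + 1, cds$end), lines)))
})

test_that("annotation validation catches bad intervals and overlaps", {
  expect_error(build_annotation_set(
    tibble::tibble(contig = "chr1", strand = "+", start = -5L, end = 10L,
                   class = "translated"),
    c(chr1 = 100L), "bacteria"), "bounds")
  expect_error(build_annotation_set(
    tibble::tibble(contig = "chr1", strand = "+", start = 0L, end = 200L,
                   class = "translated"),
    c(chr1 = 100L), "bacteria"), "bounds")
  # same-strand CDS/UTR overlap is an error
  expect_error(build_annotation_set(
    tibble::tibble(contig = "chr1", strand = "+", start = c(0L, 50L),
                   end = c(100L, 150L),
                   class = c("translated", "transcribed_untranslated")),
    c(chr1 = 1000L), "bacteria"), "overlap")
  # opposite strands may overlap
  ok <- build_annotation_set(
    tibble::tibble(contig = "chr1", strand = c("+", "-"), start = c(0L, 50L),
                   end = c(100L, 150L),
                   class = c("translated", "transcribed_untranslated")),
    c(chr1 = 1000L), "bacteria")
  expect_s3_class(ok, "annotation_set")
})

test_that("position classification is strand-aware with translated precedence", {
  ann <- toy_annotation()
  expect_identical(
    classify_position("chr1", c(150, 210, 550, 750, 50, 999), rep("+", 6), ann),
    c("transcribed_untranslated", "translated", "translated", "other",
      "other", "other"))
  # minus-strand queries only match minus-strand features
  expect_identical(classify_position("chr1", c(150, 750), c("-", "-"), ann),
                   c("other", "transcribed_untranslated"))
  # half-open: end coordinate itself is outside
  expect_identical(classify_position("chr1", c(199, 200, 259, 260), rep("+", 4),
                                     ann),
                   c("transcribed_untranslated", "translated", "translated",
                     "other"))
})

test_that("yeast mode routes introns into the transcribed class", {
  cfg <- sim_config(genome_length = 20000, n_genes = 3, seed = 5)
  sim <- generate_genome(cfg)
  gff <- tempfile(fileext = ".gff3")
  write_gff3(sim$annotation, gff)
  intron <- tempfile(fileext = ".bed")
  write_bed(tibble::tibble(contig = "chr1", start = 10L, end = 60L,
                           name = "intron1", strand = "+"), intron)
  y <- load_annotation(gff, utr_bed = NULL, intron_bed = intron, mode = "yeast")
  expect_identical(classify_position("chr1", 20, "+", y),
                   "transcribed_untranslated")
  # bacteria mode ignores the intron file
  b <- load_annotation(gff, utr_bed = NULL, intron_bed = intron,
                       mode = "bacteria")
  expect_identical(classify_position("chr1", 20, "+", b), "other")
})

test_that("region rate arithmetic is exact on a constructed table", {
  ann <- toy_annotation()
  # 10 locations in the 180 bp of translated sequence, 2 elsewhere
  ev <- dplyr::bind_rows(
    lapply(1:10, function(i) {
      tibble::tibble(read_id = sprintf("t%02d_%d", i, 1:3), contig = "chr1",
                     genomic_position = 200L + i, strand = "+", offset = 0L,
                     template_base = "G", read_base = "A", quality = 38L,
                     substitution = "G>A")
    }),
    tibble::tibble(read_id = c("o1", "o2"), contig = "chr1",
                   genomic_position = c(50L, 900L), strand = "+", offset = 0L,
                   template_base = "G", read_base = "A", quality = 38L,
                   substitution = "G>A"))
  tab <- region_rate_table(ev, hotspots = NULL, ann)
  expect_identical(tab$class,
                   c("translated", "transcribed_untranslated", "other"))
  tr <- tab[tab$class == "translated", ]
  expect_equal(tr$region_length, 60 + 120)
  expect_equal(tr$n_locations, 10)
  expect_equal(tr$n_ecs, 30)
  expect_equal(tr$locations_per_100kb, 1e5 * 10 / 180)
  ot <- tab[tab$class == "other", ]
  # other = two-strand genome minus annotated footprints
  expect_equal(ot$region_length, 2 * 1000 - (180 + 100 + 100))
  expect_equal(ot$n_locations, 2)
})

test_that("region rates match a brute-force reclassification on a simulation", {
  sim <- small_sim(seed = 202, n_ecs = 6000, misinc = 0.08)
  ann <- as_annotation_set(sim$annotation)
  aln <- align_reads(sim$reads, sim$reference)
  out <- extract_mismatch_events(aln, sim$reads, sim$reference)
  tab <- region_rate_table(out$events, NULL, ann)
  # brute force: classify every distinct offset-0 location by linear scan
  e0 <- out$events[out$events$offset == 0, ]
  locs <- unique(e0[, c("contig", "genomic_position", "strand")])
  brute <- vapply(seq_len(nrow(locs)), function(i) {
    hit <- ann[ann$contig == locs$contig[i] & ann$strand == locs$strand[i] &
                 ann$start <= locs$genomic_position[i] &
                 locs$genomic_position[i] < ann$end, ]
    if (nrow(hit) == 0) "other" else hit$class[1]
  }, character(1))
  expect_equal(tab$n_locations[match("translated", tab$class)],
               sum(brute == "translated"))
  expect_equal(tab$n_locations[match("transcribed_untranslated", tab$class)],
               sum(brute == "transcribed_untranslated"))
  expect_equal(tab$n_locations[match("other", tab$class)],
               sum(brute == "other"))
  expect_equal(sum(tab$n_ecs), nrow(e0))
  # lengths: annotated footprints + other = two-strand genome
  expect_equal(sum(tab$region_length),
               2 * sum(attr(ann, "contig_lengths")))
})

test_that("density normalisation is uniform under uniform placement", {
  # place synthetic locations uniformly over both strands: per-100kb
  # densities should then agree across classes within sampling error
  cfg <- sim_config(genome_length = 50000, n_genes = 10, seed = 77)
  sim <- generate_genome(cfg)
  ann <- as_annotation_set(sim$annotation)
  set.seed(1)
  n <- 20000
  ev <- tibble::tibble(
    read_id = sprintf("u%05d", 1:n), contig = "chr1",
    genomic_position = sample(0:49999, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE), offset = 0L,
    template_base = "G", read_base = "A", quality = 38L,
    substitution = "G>A")
  ev <- dplyr::distinct(ev, .data$genomic_position, .data$strand,
                        .keep_all = TRUE)
  tab <- region_rate_table(ev, NULL, ann)
  dens <- tab$n_locations / tab$region_length
  expect_lt(max(dens) / min(dens), 1.2)
})
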