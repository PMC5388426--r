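# Independent brute-force oracles used to cross-check the package's
# implementations on small instances. Kept deliberately naive.

rand_genome <- function(L, seed, gc = 0.5, name = "chr1") {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
             collapse = "")
  setNames(s, name)
}

# exhaustive alignment scorer: evaluates EVERY placement on both strands
oracle_align <- function(read, genome, seed_len = 14, seed_mm = 2,
                         unique_only = TRUE) {
  read <- unname(read)
  rl <- nchar(read)
  if (rl < seed_len) return(list(status = "too_short"))
  rch <- strsplit(read, "")[[1]]
  best <- list()
  best_mm <- Inf
  for (ctg in names(genome)) {
    fwd <- genome[[ctg]]
    L <- nchar(fwd)
    if (rl > L) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      sch <- strsplit(s, "")[[1]]
      np <- L - rl + 1
      tot <- integer(np)
      seed_tot <- integer(np)
      for (j in seq_len(rl)) {
        seg <- sch[j:(j + np - 1)]
        mm <- (seg != rch[j]) | seg == "N" | rch[j] == "N"
        tot <- tot + mm
        if (j > rl - seed_len) seed_tot <- seed_tot + mm
      }
      ok <- which(seed_tot <= seed_mm)
      for (p0 in ok) {
        p <- p0 - 1L  # 0-based start on this strand string
        start <- if (strand == "+") p else L - p - rl
        cand <- list(contig = ctg, strand = strand, start = start,
                     mm = tot[p0])
        if (tot[p0] < best_mm) {
          best <- list(cand); best_mm <- tot[p0]
        } else if (tot[p0] == best_mm) {
          best <- c(best, list(cand))
        }
      }
    }
  }
  if (length(best) == 0) return(list(status = "unaligned"))
  if (unique_only && length(best) > 1) return(list(status = "multimapped"))
  c(list(status = "aligned"), best[[1]])
}

# naive (read x offset) double-loop recount of the positional error table
oracle_recount <- function(alignments, reads, genome, variants = NULL,
                           phred_min = 30, window = 11) {
  acc <- alignments[alignments$status == "aligned", , drop = FALSE]
  offs <- 0:(-(window - 1))
  denom <- setNames(rep(0L, window), offs)
  mism <- setNames(rep(0L, window), offs)
  spec <- matrix(0L, nrow = window, ncol = 12,
                 dimnames = list(offs, netfidelity:::SUBSTITUTIONS))
  varkey <- if (!is.null(variants) && nrow(variants)) {
    paste(variants$contig, variants$pos)
  } else character(0)
  for (i in seq_len(nrow(acc))) {
    rd <- reads$sequence[reads$read_id == acc$read_id[i]]
    qu <- utf8ToInt(reads$qualities[reads$read_id == acc$read_id[i]]) - 33L
    rl <- nchar(rd)
    for (o in offs) {
      if (rl + o < 1) next
      rb <- substr(rd, rl + o, rl + o)
      if (rb == "N") next
      denom[as.character(o)] <- denom[as.character(o)] + 1L
      gpos <- if (acc$strand[i] == "+") acc$start[i] + rl - 1 + o
              else acc$start[i] - o
      tb <- substr(genome[[acc$contig[i]]], gpos + 1, gpos + 1)
      if (acc$strand[i] == "-") tb <- chartr("ACGTN", "TGCAN", tb)
      if (tb == "N" || rb == tb) next
      if (qu[rl + o] < phred_min) next
      if (paste(acc$contig[i], gpos) %in% varkey) next
      mism[as.character(o)] <- mism[as.character(o)] + 1L
      lab <- paste0(tb, ">", rb)
      spec[as.character(o), lab] <- spec[as.character(o), lab] + 1L
    }
  }
  list(denominators = denom, mismatch_reads = mism, specific = spec)
}

# Monte-Carlo oracle for the error-propagation model: simulates the three
# experimental layers on n bases with true misincorporation rate r_true
oracle_error_layers <- function(r_true, budget, n, seed = 1) {
  set.seed(seed)
  template <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  base <- template
  flip <- runif(n) < r_true
  base[flip] <- vapply(template[flip],
                       function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                       character(1))
  for (rate in c(budget$p_rt, budget$n_cycles * budget$p_pcr, budget$p_seq)) {
    hit <- which(runif(n) < rate)
    base[hit] <- vapply(base[hit],
                        function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                        character(1))
  }
  mean(base != template)
}

# tiny exhaustive scan for the longest adapter-prefix / read-suffix overlap
oracle_trim <- function(read, adapter, min_overlap) {
  rl <- nchar(read)
  if (min(rl, nchar(adapter)) < min_overlap) return(read)
  for (k in seq(min(rl, nchar(adapter)), min_overlap)) {
    if (substr(read, rl - k + 1, rl) == substr(adapter, 1, k)) {
      return(substr(read, 1, rl - k))
    }
  }
  read
}

# small ready-made simulation shared by several tests
small_sim <- function(seed = 42, n_ecs = 4000, misinc = 0.05, ...) {
  simulate_netseq(sim_config(genome_length = 20000, n_genes = 6,
                             n_ecs = n_ecs, misinc_fraction = misinc,
                             seed = seed, ...))
}

reads_tbl <- function(sequence, qualities = NULL, prefix = "r") {
  n <- length(sequence)
  if (is.null(qualities)) qualities <- strrep("I", nchar(sequence))
  tibble::tibble(read_id = sprintf("%s%03d", prefix, seq_len(n)),
                 sequence = unname(sequence), qualities = unname(qualities))
}
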