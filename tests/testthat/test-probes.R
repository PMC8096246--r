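test_that("tiling yields the closed-form probe count on N-free sequences", {
  ps <- tile_probes(random_dna(2500), probe_len = 30, gap = 20)
  expect_equal(nrow(ps$probes), 50L)
  expect_equal(nrow(tile_probes(random_dna(5000))$probes), 100L)
  expect_warning(short <- tile_probes(random_dna(29)), "shorter")
  expect_equal(nrow(short$probes), 0L)
  # property: count matches floor((L - 30)/50) + 1 over random lengths
  set.seed(55)
  for (L in sample(30:4000, 15)) {
    n <- nrow(tile_probes(random_dna(L, seed = L))$probes)
    expect_equal(n, floor((L - 30) / 50) + 1)
  }
})

test_that("probe coordinates are 0-based half-open and re-match the target", {
  seq <- random_dna(1234, seed = 3)
  ps <- tile_probes(seq, 30, 20)
  expect_true(all(ps$probes$end - ps$probes$start == 30))
  expect_true(all(diff(ps$probes$start) >= 50))     # gap >= 20
  for (i in seq_len(nrow(ps$probes)))
    expect_equal(substr(seq, ps$probes$start[i] + 1, ps$probes$end[i]),
                 ps$probes$core[i])
})

test_that("N-containing windows are skipped without moving the grid", {
  seq <- random_dna(180, seed = 4)
  # second window is positions 51..80 (1-based); poison it with an N
  substr(seq, 60, 60) <- "N"
  ps <- tile_probes(seq, 30, 20)
  expect_equal(ps$probes$start, c(0L, 100L, 150L))
  expect_error(tile_probes("ACGTX"), "only A, C, G, T or N")
})

test_that("filtering removes low-complexity and non-unique probes with reasons", {
  target <- paste0(random_dna(50, seed = 6),
                   strrep("A", 30),
                   random_dna(120, seed = 7))
  ps <- tile_probes(target, 30, 20)
  f <- filter_probes(ps)
  expect_equal(nrow(f$probes), nrow(ps$probes) - 1L)
  filt <- attr(f, "filtered")
  expect_equal(nrow(filt), 1L)
  expect_equal(filt$start, 50L)
  expect_true(filt$reason %in% c("homopolymer", "low_complexity"))

  # uniqueness: duplicate probe 2's first 16-mer elsewhere in the background
  seq2 <- random_dna(300, seed = 8)
  ps2 <- tile_probes(seq2, 30, 20)
  dup <- substr(ps2$probes$core[2], 1, 16)
  background <- c(seq2, paste0(random_dna(40, seed = 9), dup,
                               random_dna(40, seed = 10)))
  f2 <- filter_probes(ps2, background = background)
  expect_false(ps2$probes$core[2] %in% f2$probes$core)
  expect_equal(attr(f2, "filtered")$reason, "non_unique_kmer")
  # brute-force oracle: every surviving probe's 16-mers occur exactly once
  bg <- paste(background, collapse = "|")
  for (core in f2$probes$core) {
    kms <- substring(core, 1:15, 16:30)
    hits <- vapply(kms, function(k)
      length(gregexpr(k, bg, fixed = TRUE)[[1]]), integer(1))
    expect_true(all(hits == 1L))
  }

  # disabled rules: identity; enabled rules: idempotent
  id <- filter_probes(ps, min_entropy = NULL, max_run = NULL)
  expect_equal(id$probes, ps$probes)
  expect_equal(filter_probes(f)$probes, f$probes)

  # GC bounds rule
  gc_ps <- tile_probes(paste0(strrep("GC", 15), random_dna(170, seed = 11)))
  fgc <- filter_probes(gc_ps, min_entropy = NULL, max_run = NULL,
                       gc_bounds = c(0.2, 0.8))
  expect_equal(attr(fgc, "filtered")$reason, "gc_out_of_bounds")
})

test_that("the common 3' tail turns 30-mer cores into 50-nt oligos", {
  ps <- append_common_tail(tile_probes(random_dna(500, seed = 12)))
  expect_true(all(nchar(ps$probes$full_seq) == 50L))
  expect_true(all(substr(ps$probes$full_seq, 31, 50) ==
                    "TAGTTTCAGCTTTCCGCAAC"))
  expect_true(all(substr(ps$probes$full_seq, 1, 30) == ps$probes$core))
  # custom 10-nt tail: 40-nt oligos
  ps10 <- append_common_tail(tile_probes(random_dna(500, seed = 12)),
                             tail = "ACGTACGTAC")
  expect_true(all(nchar(ps10$probes$full_seq) == 40L))
  # empty set passes through; invalid tails rejected
  empty <- suppressWarnings(tile_probes(random_dna(10)))
  expect_equal(nrow(append_common_tail(empty)$probes), 0L)
  expect_error(append_common_tail(ps, "ACGTN"), "A, C, G or T")
  expect_error(append_common_tail(ps, ""), "nonempty")
})

test_that("probe sets round-trip through FASTA and TSV", {
  ps <- append_common_tail(tile_probes(random_dna(400, seed = 13),
                                       target_name = "gene1"))
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  write_probes(ps, fa, tsv)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(seqs), setNames(
    ps$probes$full_seq,
    sprintf("gene1|%d-%d", ps$probes$start, ps$probes$end)))
  tab <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(tab$start, ps$probes$start)
  expect_equal(tab$full_seq, ps$probes$full_seq)
})
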