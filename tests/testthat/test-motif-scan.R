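test_that("pattern compilation follows the block/gap grammar", {
  short <- compile_pattern("GTTn{3}AAC")
  expect_equal(short$span, 9L)
  expect_equal(short$blocks, c("GTT", "AAC"))
  expect_equal(short$gaps, 3L)

  long <- compile_pattern("GTTn{3}AACn{5}GTT")
  expect_equal(long$span, 17L)
  expect_length(long$blocks, 3)

  bare <- compile_pattern("GTT")
  expect_equal(bare$span, 3L)
  expect_length(bare$gaps, 0)

  expect_error(compile_pattern("GTTn{3}"), "malformed")
  expect_error(compile_pattern("gtt"), "malformed")
  expect_error(compile_pattern("GTTn{3}n{2}AAC"), "malformed")
})

test_that("literal and nested matches are found at the right offsets", {
  pats <- surr_patterns()
  h <- scan_sequence("GTTAAAAAC", pats$surr_short)
  expect_equal(nrow(h), 1)
  expect_equal(h$promoter_offset, 0L)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$strand, "promoter")

  seq <- "GTTAAAAACTTTTTGTT"
  expect_equal(scan_sequence(seq, pats$surr_long)$promoter_offset, 0L)
  expect_equal(scan_sequence(seq, pats$surr_short)$promoter_offset, 0L)

  expect_equal(nrow(scan_sequence("", pats$surr_short)), 0)
  expect_equal(nrow(scan_sequence("ACGT", pats$surr_short)), 0)
})

test_that("N in the sequence never matches a conserved position", {
  pats <- surr_patterns()
  expect_equal(nrow(scan_sequence("GTTAAANAC", pats$surr_short)), 0)
  # N in a gap position is fine
  expect_equal(nrow(scan_sequence("GTTNNNAAC", pats$surr_short)), 1)
})

test_that("short SurR motif match set is closed under reverse complement", {
  # exhaustive: all 4^9 nine-mers
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, rep(list(bases), 9))
  mers <- do.call(paste0, grid)
  ok3 <- function(x, at, want) substr(x, at, at + 2) == want
  match_fwd <- ok3(mers, 1, "GTT") & ok3(mers, 7, "AAC")
  rc <- stringi::stri_reverse(chartr("ACGT", "TGCA", mers))
  match_rc <- ok3(rc, 1, "GTT") & ok3(rc, 7, "AAC")
  expect_identical(match_fwd, match_rc)

  # hence both_strands cannot add or remove short-motif hits
  withr::with_seed(41, seqs <- random_dna(200, 50))
  pat <- surr_patterns()$surr_short
  for (s in seqs) {
    expect_identical(scan_sequence(s, pat, both_strands = TRUE)$promoter_offset,
                     scan_sequence(s, pat, both_strands = FALSE)$promoter_offset)
  }
})

test_that("reverse-complement scanning maps offsets as |seq| - span - offset", {
  pat <- surr_patterns()$surr_long
  withr::with_seed(42, seqs <- random_dna(300, 60))
  for (s in seqs) {
    fwd_only <- oracle_scan(s, pat$blocks, pat$gaps)
    rc_only <- oracle_scan(oracle_revcomp(s), pat$blocks, pat$gaps)
    expected <- sort(union(fwd_only, nchar(s) - pat$span - rc_only))
    got <- scan_sequence(s, pat, both_strands = TRUE)$promoter_offset
    expect_identical(got, as.integer(expected))
  }
})

test_that("hit sets match a brute-force sliding-window oracle on random 200-mers", {
  pats <- surr_patterns()
  withr::with_seed(43, seqs <- random_dna(60, 200))
  for (s in seqs) {
    for (pat in pats) {
      expect_identical(
        scan_sequence(s, pat, both_strands = FALSE)$promoter_offset,
        as.integer(oracle_scan(s, pat$blocks, pat$gaps))
      )
    }
  }
})

test_that("hits are monotone in the mismatch budget", {
  pat <- surr_patterns()$surr_short
  withr::with_seed(44, seqs <- random_dna(40, 120))
  for (s in seqs) {
    h0 <- scan_sequence(s, pat, max_mismatch = 0)$promoter_offset
    h1 <- scan_sequence(s, pat, max_mismatch = 1)$promoter_offset
    h2 <- scan_sequence(s, pat, max_mismatch = 2)$promoter_offset
    expect_true(all(h0 %in% h1))
    expect_true(all(h1 %in% h2))
  }
})

test_that("chance-hit rate on random promoters matches the binomial expectation", {
  pat <- surr_patterns()$surr_short
  n <- 10000
  withr::with_seed(45, seqs <- random_dna(n, 200))
  hits <- vapply(seqs,
                 function(s) nrow(scan_sequence(s, pat)), numeric(1),
                 USE.NAMES = FALSE)
  expected <- (200 - 9 + 1) * 4^-6 # 192 windows, 6 conserved positions
  se <- stats::sd(hits) / sqrt(n)
  expect_lt(abs(mean(hits) - expected), 3 * se)
})

test_that("promoter scans report distances, sort order and mutated-motif hits", {
  # construct a promoter with a short motif ending 21 bp and a long motif
  # ending 127 bp upstream of the start codon (5'-anchor convention)
  base <- strsplit(paste(rep("C", 200), collapse = ""), "")[[1]]
  put <- function(chars, dist, motif) {
    m <- strsplit(motif, "")[[1]]
    at <- (200 - dist + 1):(200 - dist + length(m))
    chars[at] <- m
    chars
  }
  base <- put(base, 21, "GTTAAAAAC")
  base <- put(base, 127, "GTTCCCAACGGGGGGTT")
  promoters <- tibble::tibble(locus_tag = c("P1", "Pempty"),
                              sequence = c(paste(base, collapse = ""),
                                           paste(rep("A", 200), collapse = "")))
  hits <- scan_promoters(promoters, surr_patterns())
  # the long hit at 127 carries a nested short hit at the same offset
  expect_equal(nrow(hits), 3)
  expect_equal(hits$distance, c(21L, 127L, 127L)) # sorted ascending
  expect_setequal(hits$pattern_id[2:3], c("surr_short", "surr_long"))
  expect_equal(hits$matched_seq[1], "GTTAAAAAC")
  expect_false("Pempty" %in% hits$locus_tag)
  collapsed <- collapse_nested_hits(hits, surr_patterns())
  expect_equal(collapsed$distance, c(21L, 127L))
  expect_equal(collapsed$pattern_id, c("surr_short", "surr_long"))

  # 3-prime anchor shifts distances by span - 1
  hits3 <- scan_promoters(promoters, surr_patterns(), distance_from = "3prime")
  long3 <- hits3[hits3$pattern_id == "surr_long", ]
  short3 <- hits3[hits3$pattern_id == "surr_short", ]
  expect_equal(long3$distance, 127L - 16L)
  expect_setequal(short3$distance, c(21L - 8L, 127L - 8L))

  # a single mismatched (mutated) motif is reported with mismatches = 1 and
  # excluded from promoters_with_motif by default
  mut <- put(strsplit(paste(rep("C", 200), collapse = ""), "")[[1]],
             50, "GTTAAAACC")
  pm <- tibble::tibble(locus_tag = "Pmut",
                       sequence = paste(mut, collapse = ""))
  mh <- scan_promoters(pm, surr_patterns(), max_mismatch = 1)
  expect_true(any(mh$mismatches == 1 & mh$distance == 50))
  expect_length(promoters_with_motif(mh), 0)
  expect_equal(promoters_with_motif(mh, include_mismatched = TRUE), "Pmut")

  expect_error(scan_promoters(dplyr::bind_rows(pm, pm), surr_patterns()),
               "duplicate locus tags")
})

test_that("nested short-within-long hits are reported under both patterns and collapsible", {
  # the long motif starts with a complete short motif
  seq200 <- paste0(paste(rep("C", 183), collapse = ""), "GTTAAAAACTTTTTGTT")
  prom <- tibble::tibble(locus_tag = "P", sequence = seq200)
  hits <- scan_promoters(prom, surr_patterns())
  expect_equal(sort(hits$pattern_id), c("surr_long", "surr_short"))
  expect_equal(hits$distance, c(17L, 17L)) # same 5' anchor
  kept <- collapse_nested_hits(hits, surr_patterns())
  expect_equal(kept$pattern_id, "surr_long")
})

test_that("promoters_with_motif collapses hits to distinct locus tags", {
  empty <- scan_promoters(tibble::tibble(locus_tag = character(0),
                                         sequence = character(0)),
                          surr_patterns())
  expect_length(promoters_with_motif(empty), 0)

  hits <- tibble::tibble(
    locus_tag = c("A", "A", "A"), pattern_id = c("surr_short", "surr_short",
                                                 "surr_long"),
    distance = c(10L, 50L, 100L), promoter_offset = 0L,
    strand = "promoter", matched_seq = "x", mismatches = 0L
  )
  expect_equal(promoters_with_motif(hits), "A")
  expect_equal(promoters_with_motif(hits, pattern_ids = "surr_long"), "A")
  expect_length(promoters_with_motif(hits, pattern_ids = "other"), 0)
})

test_that("hit BED output places motifs at their genomic coordinates", {
  cfg <- sim_config(n_genes = 50, motif_fraction = 0.3, seed = 303)
  gen <- generate_genome(cfg)
  prom <- extract_promoters(gen$genes, gen$genome)
  pats <- surr_patterns()
  hits <- scan_promoters(prom, pats)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(hits, prom, pats, bed)
  b <- readr::read_tsv(bed, col_names = c("chrom", "start", "end", "name",
                                          "score", "strand"),
                       show_col_types = FALSE)
  expect_equal(nrow(b), nrow(hits))
  # reading each BED interval along its BED strand must spell the matched
  # sequence as reported on the hit's strand
  spans <- substring(gen$genome$sequence, b$start + 1, b$end)
  spelled <- ifelse(b$strand == "+", spans, oracle_revcomp(spans))
  expect_identical(spelled, hits$matched_seq)
})
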