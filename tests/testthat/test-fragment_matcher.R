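test_that("seed index enumerates k-mer occurrences", {
  rs <- reference_set("r1", "ACGTACGTACGTACGTACGTA", "tRNA")
  rs <- build_seed_index(rs, 19)
  expect_equal(seed_index_size(rs), 3L)  # 21 - 19 + 1 distinct 19-mers

  rs19 <- build_seed_index(reference_set("r1", rand_seq(19), "tRNA"), 19)
  expect_equal(seed_index_size(rs19), 1L)

  polyA <- build_seed_index(reference_set("r1", strrep("A", 25), "tRNA"), 19)
  expect_equal(seed_index_size(polyA), 1L)
  occ <- seed_index_lookup(polyA, strrep("A", 19))
  expect_equal(nrow(occ), 7L)
  expect_equal(sort(occ[, "offset"]), 0:6)

  expect_warning(build_seed_index(reference_set("short", "ACGTACGT", "tRNA"), 19),
                 "shorter than seed")
})

test_that("exact embeddings are found at the right position, once", {
  set.seed(5)
  ref <- rand_seq(112)
  rs <- reference_set("Y4_syn", ref, "YRNA")
  q <- substr(ref, 67, 92)  # 26-mer at 0-based offset 66 (1-based start 67)

  h <- find_hits(q, rs, match_params(max_mismatches = 0))
  expect_equal(nrow(h), 1L)
  expect_equal(h$ref_start, 66L)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$coverage, 1.0)
})

test_that("a substitution is invisible at MM=0 and counted at MM=1", {
  set.seed(5)
  ref <- rand_seq(112)
  rs <- reference_set("Y4_syn", ref, "YRNA")
  q <- substr(ref, 67, 92)
  set.seed(6)
  qc <- substitute_base(q, 4)  # suffix 19-mer seed survives

  expect_equal(nrow(find_hits(qc, rs, match_params(max_mismatches = 0))), 0L)
  h1 <- find_hits(qc, rs, match_params(max_mismatches = 1))
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$mismatches, 1L)
  # two substitutions exceed MM=1 for both matcher paths
  set.seed(7)
  q2 <- substitute_base(qc, 23)
  expect_equal(nrow(find_hits(q2, rs, match_params(max_mismatches = 1))), 0L)
  expect_equal(nrow(brute_force_hits(q2, rs, match_params(max_mismatches = 1))), 0L)
})

test_that("coverage below 1 is reached by end-trimming only", {
  set.seed(5)
  ref <- rand_seq(112)
  rs <- reference_set("Y4_syn", ref, "YRNA")
  # 32-mer whose last 31 bases sit at the reference start: one base must trim
  q32 <- paste0("T", substr(ref, 1, 31))
  h <- find_hits(q32, rs, match_params())
  expect_equal(nrow(h), 1L)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$coverage, 31 / 32)
  expect_equal(h$query_start, 1L)
  expect_identical(h, brute_force_hits(q32, rs, match_params()))
})

test_that("queries shorter than the seed fall back to the exhaustive path", {
  set.seed(15)
  ref <- rand_seq(90)
  rs <- reference_set("t1", ref, "tRNA")
  q <- substr(ref, 11, 26)  # 16-mer < seed
  h <- find_hits(q, rs, match_params(max_mismatches = 0, min_coverage = 1))
  expect_true(nrow(h) >= 1L)
  expect_true(any(h$ref_start == 10L & h$mismatches == 0L))
})

test_that("minus-strand hits are reported only in both-strand mode", {
  set.seed(21)
  ref <- rand_seq(100)
  rs <- reference_set("r", ref, "snRNA")
  q_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(ref, 31, 58))))
  expect_equal(nrow(find_hits(q_rc, rs, match_params(max_mismatches = 0))), 0L)
  h <- find_hits(q_rc, rs, match_params(max_mismatches = 0, strand_mode = "both"))
  expect_equal(h$strand, "-")
  expect_equal(h$ref_start, 30L)
})

test_that("seeded search equals the brute-force oracle when a seed survives", {
  set.seed(1234)
  params_grid <- list(match_params(max_mismatches = 0),
                      match_params(max_mismatches = 1),
                      match_params(min_coverage = 1, max_mismatches = 1),
                      match_params())
  for (case in 1:60) {
    reflen <- sample(60:200, 1)
    ref <- rand_seq(reflen)
    rs <- reference_set("ref", ref, "tRNA")
    L <- sample(24:35, 1)
    off <- sample(0:(reflen - L), 1)
    q <- substr(ref, off + 1, off + L)
    for (k in seq_len(sample(0:2, 1))) q <- substitute_base(q, sample(L, 1))
    p <- params_grid[[1 + (case %% length(params_grid))]]
    f <- find_hits(q, rs, p)
    b <- brute_force_hits(q, rs, p)
    expect_true(all(hit_keys(f) %in% hit_keys(b)),
                info = sprintf("case %d: seeded not subset of brute", case))
    seeded <- vapply(seq_len(nrow(b)), function(i)
      aligned_seed_survives(q, ref, b[i, ]), logical(1))
    expect_true(all(hit_keys(b)[seeded] %in% hit_keys(f)),
                info = sprintf("case %d: brute seeded hit missed", case))
  }
})

test_that("the MM=1 hit set contains the MM=0 hit set", {
  set.seed(77)
  for (case in 1:25) {
    ref <- rand_seq(sample(60:150, 1))
    rs <- reference_set("ref", ref, "tRNA")
    L <- sample(24:35, 1)
    off <- sample(0:(nchar(ref) - L), 1)
    q <- substr(ref, off + 1, off + L)
    if (case %% 2 == 0) q <- substitute_base(q, sample(L, 1))
    h0 <- find_hits(q, rs, match_params(max_mismatches = 0))
    h1 <- find_hits(q, rs, match_params(max_mismatches = 1))
    expect_true(all(hit_keys(h0) %in% hit_keys(h1)))
  }
})

test_that("lowering the coverage threshold never loses a matched diagonal", {
  diag_keys <- function(h) unique(paste(h$reference_id, h$strand,
                                        h$ref_start - h$query_start))
  set.seed(88)
  for (case in 1:20) {
    ref <- rand_seq(sample(60:150, 1))
    rs <- reference_set("ref", ref, "tRNA")
    L <- sample(28:35, 1)
    off <- sample(0:(nchar(ref) - L), 1)
    q <- substr(ref, off + 1, off + L)
    if (case %% 2 == 0) q <- substitute_base(q, sample(L, 1))
    h_tight <- find_hits(q, rs, match_params(min_coverage = 1, max_mismatches = 1))
    h_loose <- find_hits(q, rs, match_params(min_coverage = 0.94, max_mismatches = 1))
    expect_true(all(diag_keys(h_tight) %in% diag_keys(h_loose)))
  }
})

test_that("screening attributes each query to a single best class", {
  set.seed(31)
  refsets <- tiny_refsets()
  # one query planted verbatim in both a tRNA and an rRNA reference
  shared <- rand_seq(26)
  refsets[[1]]$seq[1] <- paste0(substr(refsets[[1]]$seq[1], 1, 30), shared,
                                substr(refsets[[1]]$seq[1], 57, 75))
  refsets[[1]] <- reference_set(refsets[[1]]$id, refsets[[1]]$seq, "tRNA")
  refsets[[2]]$seq[1] <- paste0(shared, substr(refsets[[2]]$seq[1], 27, 300))
  refsets[[2]] <- reference_set(refsets[[2]]$id, refsets[[2]]$seq, "rRNA")

  qs <- query_set(c("dual", "nohit"), c(shared, rand_seq(26)))
  scr <- screen_database(qs, refsets, match_params(max_mismatches = 0))
  expect_equal(scr$table$TOTAL, 1L)
  expect_equal(scr$table$rRNA + scr$table$tRNA, 1L)
  expect_equal(scr$best_hits$ncrna_class, "rRNA")  # class priority tie-break
  expect_equal(scr$table$TOTAL, sum(scr$table$rRNA, scr$table$tRNA))
  # multi-count mode reports the query under both classes
  multi <- screen_database(qs, refsets, match_params(max_mismatches = 0),
                           attribution = "multi")
  expect_equal(multi$table$rRNA, 1L)
  expect_equal(multi$table$tRNA, 1L)
  expect_equal(multi$table$TOTAL, 1L)
})

test_that("screening an empty reference panel yields zero counts", {
  qs <- query_set("a", rand_seq(26))
  expect_error(screen_database(qs, list(tiny_refsets()[[1]], tiny_refsets()[[1]]),
                               match_params()), "duplicate")
  scr <- screen_database(qs, list(), match_params())
  expect_equal(scr$table$TOTAL, 0L)
  expect_equal(scr$table$percent, 0)
})
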