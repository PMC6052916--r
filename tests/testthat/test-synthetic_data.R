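test_that("the generator is byte-reproducible under its seed", {
  cfg <- synthetic_config(seed = 13, n_genuine = 40, n_contaminants = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  cfg2 <- synthetic_config(seed = 14, n_genuine = 40, n_contaminants = 10)
  db_a <- simulate_database(cfg, simulate_references(cfg))
  db_b <- simulate_database(cfg2, simulate_references(cfg2))
  expect_false(identical(db_a$truth, db_b$truth))
})

test_that("reference panels honour per-class counts and length ranges", {
  cfg <- synthetic_config(seed = 2, n_refs_per_class = 5)
  refs <- simulate_references(cfg)
  expect_equal(length(refs), 8L)
  expect_equal(sum(vapply(refs, function(r) length(r$seq), integer(1))), 40L)
  for (cls in names(refs)) {
    rng <- cfg$ref_length_ranges[[cls]]
    expect_true(all(nchar(refs[[cls]]$seq) >= rng[1] &
                    nchar(refs[[cls]]$seq) <= rng[2]), info = cls)
  }
  # degenerate range pins the length exactly
  cfg_fix <- synthetic_config(seed = 2, ref_length_ranges = list(tRNA = c(70, 70)))
  expect_equal(nchar(simulate_references(cfg_fix)$tRNA$seq), rep(70L, 5))
})

test_that("the truth table covers every database id exactly once", {
  cfg <- synthetic_config(seed = 91, n_genuine = 60, n_contaminants = 15)
  db <- simulate_database(cfg, simulate_references(cfg))
  expect_equal(sort(db$truth$id), sort(db$queries$id))
  expect_equal(anyDuplicated(db$truth$id), 0L)
  expect_equal(sum(db$truth$is_contaminant), 15L)
  expect_true(all(db$queries$rpm >= 0))
})

test_that("genuine sequences share no seed k-mer with any reference", {
  cfg <- synthetic_config(seed = 33, n_genuine = 80, n_contaminants = 0)
  refs <- simulate_references(cfg)
  db <- simulate_database(cfg, refs)
  indexed <- lapply(refs, build_seed_index, seed_len = 19)
  for (s in db$queries$seq) {
    starts <- seq_len(nchar(s) - 18L)
    kmers <- substring(s, starts, starts + 18L)
    hit <- any(vapply(indexed, function(rs)
      any(!vapply(lapply(kmers, seed_index_lookup, refset = rs), is.null,
                  logical(1))), logical(1)))
    expect_false(hit)
  }
})

test_that("contaminants are verbatim reference windows when unmutated", {
  cfg <- synthetic_config(seed = 44, n_genuine = 0, n_contaminants = 25)
  refs <- simulate_references(cfg)
  db <- simulate_database(cfg, refs)
  truth <- db$truth
  for (i in seq_len(nrow(truth))) {
    rs <- refs[[truth$source_class[i]]]
    ref_seq <- rs$seq[rs$id == truth$source_reference_id[i]]
    L <- nchar(db$queries$seq[i])
    window <- substr(ref_seq, truth$source_offset[i] + 1L,
                     truth$source_offset[i] + L)
    expect_equal(db$queries$seq[i], window)
  }
})

test_that("exact-count substitutions stay in the seed-preserving core", {
  cfg <- synthetic_config(seed = 45, n_genuine = 0, n_contaminants = 30,
                          contaminant_n_mut = 1)
  refs <- simulate_references(cfg)
  db <- simulate_database(cfg, refs)
  expect_true(all(db$truth$n_mutations == 1L))
  for (i in seq_len(nrow(db$truth))) {
    tr <- db$truth[i, ]
    rs <- refs[[tr$source_class]]
    ref_seq <- rs$seq[rs$id == tr$source_reference_id]
    frag <- db$queries$seq[i]
    L <- nchar(frag)
    window <- substr(ref_seq, tr$source_offset + 1L, tr$source_offset + L)
    diff_pos <- which(strsplit(frag, "")[[1]] != strsplit(window, "")[[1]])
    expect_length(diff_pos, 1L)
    p0 <- diff_pos - 1L  # 0-based
    # a full 19-mer window away from the substitution survives...
    expect_true(p0 >= 19L || p0 <= L - 20L)
    # ...and the substitution sits clear of the coverage trim margin
    t_max <- L - as.integer(ceiling(0.94 * L - 1e-9))
    expect_true(p0 >= t_max && p0 < L - t_max)
  }
})

test_that("the rate-based mutation mode perturbs roughly the expected bases", {
  cfg <- synthetic_config(seed = 46, n_genuine = 0, n_contaminants = 200,
                          contaminant_mutation_rate = 0.05)
  db <- simulate_database(cfg, simulate_references(cfg))
  total_bases <- sum(nchar(db$queries$seq))
  observed <- sum(db$truth$n_mutations)
  expect_lt(abs(observed - 0.05 * total_bases),
            4 * sqrt(0.05 * 0.95 * total_bases))
})

test_that("the abundance shift knob enriches contaminants in the high tail", {
  cfg <- synthetic_config(seed = 47, n_genuine = 400, n_contaminants = 400,
                          rpm_contaminant_shift = 2)
  db <- simulate_database(cfg, simulate_references(cfg))
  med_cont <- stats::median(db$queries$rpm[db$truth$is_contaminant])
  med_gen <- stats::median(db$queries$rpm[!db$truth$is_contaminant])
  expect_gt(med_cont, med_gen)
})
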