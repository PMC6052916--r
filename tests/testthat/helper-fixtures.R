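# In-code fixtures shared across test files. Everything is generated under
# explicit seeds; no binary data.

DNA <- c("A", "C", "G", "T")

rand_seq <- function(L) paste(sample(DNA, L, replace = TRUE), collapse = "")

# substitute the base at 1-based position pos with a different one
substitute_base <- function(x, pos) {
  old <- substr(x, pos, pos)
  substr(x, pos, pos) <- sample(setdiff(DNA, old), 1L)
  x
}

# a small two-class reference panel with a known embedded window
tiny_refsets <- function(seed = 11L) {
  set.seed(seed)
  list(
    reference_set(c("tRNA_a", "tRNA_b"), c(rand_seq(75), rand_seq(80)), "tRNA"),
    reference_set("rRNA_a", rand_seq(300), "rRNA")
  )
}

hit_keys <- function(h) {
  if (nrow(h) == 0L) return(character(0))
  paste(h$reference_id, h$strand, h$ref_start, h$ref_end,
        h$query_start, h$query_end, h$mismatches, sep = "|")
}

# does the aligned region of this plus-strand hit retain an exact seed?
aligned_seed_survives <- function(qseq, refseq, hit, seed_len = 19L) {
  qs <- hit$query_start; qe <- hit$query_end; rs <- hit$ref_start
  if (qe - qs < seed_len) return(FALSE)
  for (p in qs:(qe - seed_len)) {
    qk <- substr(qseq, p + 1L, p + seed_len)
    rk <- substr(refseq, rs + (p - qs) + 1L, rs + (p - qs) + seed_len)
    if (qk == rk) return(TRUE)
  }
  FALSE
}

# exhaustive-enumeration oracle for the upper-tail overlap probability:
# all n-subsets of a universe whose first K elements form the class
enumerate_overlap_tail <- function(N, K, n, q) {
  combos <- utils::combn(N, n)
  hits <- colSums(combos <= K)
  mean(hits >= q)
}
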