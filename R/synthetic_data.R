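# Seed-reproducible simulator: ncRNA reference sets plus a candidate piRNA
# database that mixes "genuine" piRNAs (tunable 5'U / position-10 A bias,
# 26-31 nt) with planted reference-derived fragments, under a complete
# ground-truth table. Genuine sequences are rejection-sampled to share no
# seed-length k-mer with any reference, so recall/precision of the screen is
# exact by construction rather than probabilistic.

DEFAULT_REF_LENGTH_RANGES <- list(
  rRNA   = c(1500L, 2000L),
  tRNA   = c(70L, 90L),
  miRNA  = c(60L, 90L),
  snRNA  = c(100L, 200L),
  snoRNA = c(60L, 150L),
  YRNA   = c(90L, 115L),
  m_tRNA = c(60L, 75L),
  m_rRNA = c(950L, 1600L)
)

#' Configuration of the synthetic small-RNA database generator
#'
#' @param seed Integer RNG seed; the full output (references, database,
#'   abundances, truth) is reproducible byte-for-byte under it. Must be below
#'   2^30.
#' @param n_refs_per_class References simulated per ncRNA class.
#' @param ref_length_ranges Named list of per-class (min, max) lengths in nt.
#' @param n_genuine Number of genuine piRNAs.
#' @param p_1U Probability of T at position 1 of a genuine piRNA
#'   (default 0.866, the database-wide 5'U fraction).
#' @param p_10A Probability of A at position 10 (default 0.3; the
#'   ping-pong signature is much weaker than the 5'U bias).
#' @param genuine_length_range (min, max) genuine length in nt, default
#'   c(26, 31).
#' @param n_contaminants Number of planted reference-derived fragments.
#' @param contaminant_length_range (min, max) fragment length in nt, default
#'   c(26, 35) — fragments run slightly longer than canonical piRNAs, as
#'   tRNA halves do.
#' @param contaminant_mutation_rate Per-base substitution probability applied
#'   to each planted fragment (default 0).
#' @param contaminant_n_mut Optional exact number of substitutions per
#'   fragment; overrides the rate when set.
#' @param mutation_placement Placement rule for exact-count substitutions:
#'   \code{"seed_preserving_core"} (default) keeps every substitution at
#'   least the coverage trim margin away from both fragment ends and leaves
#'   at least one intact \code{seed_len}-mer, so a single substitution is
#'   always counted by MM accounting and never erased by end-trimming;
#'   \code{"seed_preserving"} only guarantees the intact seed;
#'   \code{"uniform"} places uniformly.
#' @param rpm_meanlog,rpm_sdlog Log-normal abundance parameters (defaults
#'   3 and 1.5: median ~20 RPM with a heavy upper tail).
#' @param rpm_contaminant_shift Added to \code{rpm_meanlog} for contaminants
#'   (default 0: abundance independent of contamination status; positive
#'   values emulate fragment-dominated high-abundance tails).
#' @param seed_len Seed length used for the rejection sampling and for
#'   seed-preserving mutation placement (default 19).
#' @param min_coverage Coverage threshold mirrored by the core placement rule
#'   (default 0.94).
#' @return A validated \code{synthetic_config} object.
#' @export
synthetic_config <- function(seed = 1L,
                             n_refs_per_class = 5L,
                             ref_length_ranges = DEFAULT_REF_LENGTH_RANGES,
                             n_genuine = 1000L,
                             p_1U = 0.866,
                             p_10A = 0.3,
                             genuine_length_range = c(26L, 31L),
                             n_contaminants = 40L,
                             contaminant_length_range = c(26L, 35L),
                             contaminant_mutation_rate = 0,
                             contaminant_n_mut = NULL,
                             mutation_placement = c("seed_preserving_core",
                                                    "seed_preserving",
                                                    "uniform"),
                             rpm_meanlog = 3,
                             rpm_sdlog = 1.5,
                             rpm_contaminant_shift = 0,
                             seed_len = 19L,
                             min_coverage = 0.94) {
  mutation_placement <- match.arg(mutation_placement)
  seed <- as.integer(seed)
  stopifnot(seed >= 0L, seed < 2^30,
            n_refs_per_class >= 1L, n_genuine >= 0L, n_contaminants >= 0L,
            p_1U >= 0, p_1U <= 1, p_10A >= 0, p_10A <= 1,
            contaminant_mutation_rate >= 0, contaminant_mutation_rate <= 1,
            length(genuine_length_range) == 2L,
            genuine_length_range[1L] <= genuine_length_range[2L],
            length(contaminant_length_range) == 2L,
            contaminant_length_range[1L] <= contaminant_length_range[2L],
            rpm_sdlog >= 0, seed_len >= 1L,
            min_coverage > 0, min_coverage <= 1)
  stopifnot(length(ref_length_ranges) >= 1L,
            !is.null(names(ref_length_ranges)))
  for (r in ref_length_ranges) stopifnot(length(r) == 2L, r[1L] <= r[2L])
  if (!is.null(contaminant_n_mut)) {
    contaminant_n_mut <- as.integer(contaminant_n_mut)
    stopifnot(contaminant_n_mut >= 0L)
  }
  structure(list(seed = seed, n_refs_per_class = as.integer(n_refs_per_class),
                 ref_length_ranges = ref_length_ranges,
                 n_genuine = as.integer(n_genuine), p_1U = p_1U, p_10A = p_10A,
                 genuine_length_range = as.integer(genuine_length_range),
                 n_contaminants = as.integer(n_contaminants),
                 contaminant_length_range = as.integer(contaminant_length_range),
                 contaminant_mutation_rate = contaminant_mutation_rate,
                 contaminant_n_mut = contaminant_n_mut,
                 mutation_placement = mutation_placement,
                 rpm_meanlog = rpm_meanlog, rpm_sdlog = rpm_sdlog,
                 rpm_contaminant_shift = rpm_contaminant_shift,
                 seed_len = as.integer(seed_len),
                 min_coverage = min_coverage),
            class = "synthetic_config")
}

BASES <- c("A", "C", "G", "T")

random_seq <- function(L) paste(sample(BASES, L, replace = TRUE), collapse = "")

# uniform integer draw on [lo, hi], safe for degenerate ranges (sample() on a
# length-one vector would draw from 1:x instead)
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

#' Simulate class-labelled ncRNA reference sets
#'
#' I.i.d. uniform-base sequences per class, with lengths uniform within the
#' configured per-class ranges. Deterministic under \code{config$seed}.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return Named list of \code{\link{reference_set}} objects, one per class.
#' @export
simulate_references <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  out <- list()
  for (cls in names(config$ref_length_ranges)) {
    rng <- config$ref_length_ranges[[cls]]
    n <- config$n_refs_per_class
    lens <- sample_range(rng[1L], rng[2L], n)
    seqs <- vapply(lens, random_seq, character(1))
    ids <- sprintf("%s_ref_%03d", cls, seq_len(n))
    out[[cls]] <- reference_set(ids, seqs, cls, normalize = FALSE)
  }
  out
}

# does any seed_len-mer of x occur in any of the indexed reference sets?
shares_seed_kmer <- function(x, indexed_refsets, seed_len) {
  L <- nchar(x)
  if (L < seed_len) return(FALSE)
  starts <- seq_len(L - seed_len + 1L)
  kmers <- substring(x, starts, starts + seed_len - 1L)
  for (rs in indexed_refsets) {
    for (k in kmers) if (!is.null(rs$index[[k]])) return(TRUE)
  }
  FALSE
}

sample_genuine <- function(config, indexed_refsets) {
  rng <- config$genuine_length_range
  for (try in seq_len(1000L)) {
    L <- sample_range(rng[1L], rng[2L])
    ch <- sample(BASES, L, replace = TRUE)
    ch[1L] <- if (stats::runif(1) < config$p_1U) "T" else sample(c("A", "C", "G"), 1L)
    if (L >= 10L)
      ch[10L] <- if (stats::runif(1) < config$p_10A) "A" else sample(c("C", "G", "T"), 1L)
    x <- paste(ch, collapse = "")
    if (!shares_seed_kmer(x, indexed_refsets, config$seed_len)) return(x)
  }
  stop("rejection sampling failed after 1000 tries; use a larger reference space")
}

# 0-based positions that keep at least one intact seed_len window when all of
# them are mutated; optionally also inside the untrimmable core
valid_mutation_positions <- function(L, seed_len, core, min_coverage) {
  pos <- 0:(L - 1L)
  keep <- pos >= seed_len | pos <= L - seed_len - 1L
  if (core) {
    t_max <- L - as.integer(ceiling(min_coverage * L - 1e-9))
    keep <- keep & pos >= t_max & pos < L - t_max
  }
  pos[keep]
}

# a set of positions leaves an intact seed window iff some window
# [s, s+seed_len) contains none of them
leaves_intact_seed <- function(pos, L, seed_len) {
  if (L < seed_len) return(FALSE)
  for (s in 0:(L - seed_len)) {
    if (!any(pos >= s & pos < s + seed_len)) return(TRUE)
  }
  FALSE
}

mutate_fragment <- function(x, config) {
  L <- nchar(x)
  if (!is.null(config$contaminant_n_mut)) {
    k <- config$contaminant_n_mut
    if (k == 0L) return(list(seq = x, n_mut = 0L))
    if (config$mutation_placement == "uniform") {
      pos <- sample(0:(L - 1L), k)
    } else {
      core <- config$mutation_placement == "seed_preserving_core"
      valid <- valid_mutation_positions(L, config$seed_len, core,
                                        config$min_coverage)
      if (length(valid) < k)
        stop("fragment too short for the requested seed-preserving mutations")
      pos <- NULL
      for (try in seq_len(1000L)) {
        cand <- if (length(valid) == 1L) valid else sample(valid, k)
        if (leaves_intact_seed(cand, L, config$seed_len)) { pos <- cand; break }
      }
      if (is.null(pos)) stop("could not place mutations while keeping a seed intact")
    }
  } else {
    hit <- stats::runif(L) < config$contaminant_mutation_rate
    pos <- (0:(L - 1L))[hit]
    if (length(pos) == 0L) return(list(seq = x, n_mut = 0L))
  }
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    old <- ch[p + 1L]
    ch[p + 1L] <- sample(setdiff(BASES, old), 1L)
  }
  list(seq = paste(ch, collapse = ""), n_mut = length(pos))
}

#' Simulate a contaminated candidate piRNA database with ground truth
#'
#' Generates \code{n_genuine} genuine piRNAs (5'U and position-10 A biases
#' applied independently, remaining positions uniform, rejection-sampled so
#' that no genuine sequence shares any seed-length k-mer with any reference)
#' and \code{n_contaminants} fragments sampled as windows of the reference
#' sequences with substitutions per the configured mode. Mean RPM abundances
#' are drawn log-normally, by default independent of contamination status.
#' Records are shuffled; the truth table covers every id exactly once.
#' Deterministic under \code{config$seed} (an offset stream from the same
#' seed, so references and database can be generated independently).
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param refsets Reference sets from \code{\link{simulate_references}} (or
#'   any list of \code{\link{reference_set}}).
#' @return List with \code{queries} (a \code{\link{query_set}} with rpm) and
#'   \code{truth} (data.frame: id, is_contaminant, source_class,
#'   source_reference_id, source_offset (0-based), n_mutations).
#' @export
simulate_database <- function(config, refsets) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  indexed <- lapply(refsets, ensure_index, seed_len = config$seed_len)

  ids <- character(0); seqs <- character(0)
  is_cont <- logical(0); src_cls <- character(0); src_ref <- character(0)
  src_off <- integer(0); n_mut <- integer(0)

  for (i in seq_len(config$n_genuine)) {
    ids <- c(ids, sprintf("sim_g%05d", i))
    seqs <- c(seqs, sample_genuine(config, indexed))
    is_cont <- c(is_cont, FALSE); src_cls <- c(src_cls, NA_character_)
    src_ref <- c(src_ref, NA_character_); src_off <- c(src_off, NA_integer_)
    n_mut <- c(n_mut, 0L)
  }

  classes <- names(refsets) %||% vapply(refsets, function(r) r$ncrna_class, character(1))
  rng <- config$contaminant_length_range
  for (i in seq_len(config$n_contaminants)) {
    ci <- sample(length(refsets), 1L)
    rs <- refsets[[ci]]
    ri <- sample(length(rs$seq), 1L)
    reflen <- nchar(rs$seq[ri])
    L <- sample_range(rng[1L], min(rng[2L], reflen))
    off <- sample_range(0L, reflen - L)
    frag <- substr(rs$seq[ri], off + 1L, off + L)
    mut <- mutate_fragment(frag, config)
    ids <- c(ids, sprintf("sim_c%04d", i))
    seqs <- c(seqs, mut$seq)
    is_cont <- c(is_cont, TRUE); src_cls <- c(src_cls, rs$ncrna_class)
    src_ref <- c(src_ref, rs$id[ri]); src_off <- c(src_off, off)
    n_mut <- c(n_mut, mut$n_mut)
  }

  n <- length(ids)
  perm <- sample.int(n)
  rpm <- stats::rlnorm(n,
                       meanlog = config$rpm_meanlog +
                         config$rpm_contaminant_shift * is_cont[perm],
                       sdlog = config$rpm_sdlog)
  queries <- query_set(ids[perm], seqs[perm], rpm = rpm,
                       name = "simulated", normalize = FALSE)
  truth <- data.frame(id = ids[perm], is_contaminant = is_cont[perm],
                      source_class = src_cls[perm],
                      source_reference_id = src_ref[perm],
                      source_offset = src_off[perm],
                      n_mutations = n_mut[perm],
                      stringsAsFactors = FALSE)
  list(queries = queries, truth = truth)
}

#' Write a full simulated dataset to disk
#'
#' Writes one FASTA per reference class, the database FASTA, the abundance
#' TSV, the truth TSV, and the configuration echoed as JSON. Re-running with
#' the same configuration reproduces the directory contents exactly.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param dir Output directory (created if needed).
#' @return Invisible list with the simulated objects and file paths.
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refsets <- simulate_references(config)
  db <- simulate_database(config, refsets)
  paths <- list()
  for (cls in names(refsets)) {
    p <- file.path(dir, sprintf("refs_%s.fasta", cls))
    write_fasta(data.frame(id = refsets[[cls]]$id, seq = refsets[[cls]]$seq,
                           stringsAsFactors = FALSE), p)
    paths[[paste0("refs_", cls)]] <- p
  }
  paths$database <- file.path(dir, "database.fasta")
  write_fasta(db$queries, paths$database)
  paths$abundances <- file.path(dir, "abundances.tsv")
  ab <- data.frame(id = db$queries$id, sequence = db$queries$seq,
                   rpm = db$queries$rpm, detected_in = db$queries$detected_in,
                   stringsAsFactors = FALSE)
  utils::write.table(ab, paths$abundances, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(db$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$config <- file.path(dir, "config.json")
  cfg <- unclass(config)
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null",
                              digits = NA, pretty = TRUE), paths$config)
  invisible(list(refsets = refsets, queries = db$queries, truth = db$truth,
                 paths = paths))
}
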