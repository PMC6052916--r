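# Ungapped mismatch-tolerant matching of candidate piRNAs inside ncRNA
# references. The screening thresholds mirror common short-fragment mapping
# practice: a 19-nt exact seed, >= 94% of the query length aligned, and
# >= 94% identity (equivalently, an explicit mismatch allowance MM).

RAW_N <- charToRaw("N")

# Fixed class priority used to attribute a query hitting several classes to a
# single one (ties broken in this order).
NCRNA_CLASS_ORDER <- c("rRNA", "tRNA", "miRNA", "snRNA", "snoRNA", "YRNA",
                       "m_tRNA", "m_rRNA")

#' Matching parameters
#'
#' @param seed_len Exact seed length in nt the index-based search requires
#'   (default 19).
#' @param min_coverage Minimum fraction of the query length that must align
#'   (default 0.94). Coverage below 1 is achieved only by trimming bases from
#'   the query ends, never by internal gaps.
#' @param min_identity Minimum fraction of aligned positions that must match
#'   (default 0.94); the implied mismatch allowance is
#'   \code{floor((1 - min_identity) * aligned_length)}.
#' @param max_mismatches Optional integer MM override; when set it replaces
#'   the identity-derived allowance (coverage threshold still applies).
#' @param strand_mode \code{"sense_only"} (default; fragments of an ncRNA are
#'   sense by definition) or \code{"both"}.
#' @return A \code{match_params} object.
#' @export
match_params <- function(seed_len = 19L, min_coverage = 0.94,
                         min_identity = 0.94, max_mismatches = NULL,
                         strand_mode = c("sense_only", "both")) {
  strand_mode <- match.arg(strand_mode)
  seed_len <- as.integer(seed_len)
  stopifnot(seed_len >= 1L,
            min_coverage > 0, min_coverage <= 1,
            min_identity > 0, min_identity <= 1)
  if (!is.null(max_mismatches)) {
    max_mismatches <- as.integer(max_mismatches)
    stopifnot(max_mismatches >= 0L)
  }
  structure(list(seed_len = seed_len, min_coverage = min_coverage,
                 min_identity = min_identity, max_mismatches = max_mismatches,
                 strand_mode = strand_mode),
            class = "match_params")
}

#' Construct a class-labelled reference set
#'
#' @param id Character vector of reference identifiers.
#' @param seq Character vector of reference sequences (normalized unless
#'   \code{normalize = FALSE}).
#' @param ncrna_class Class label, e.g. one of
#'   \code{c("rRNA","tRNA","miRNA","snRNA","snoRNA","YRNA","m_tRNA","m_rRNA")}
#'   (other labels are accepted).
#' @param normalize Run \code{\link{normalize_sequence}} on \code{seq}?
#' @return A \code{reference_set} object (no seed index yet; see
#'   \code{\link{build_seed_index}}).
#' @export
reference_set <- function(id, seq, ncrna_class, normalize = TRUE) {
  id <- as.character(id)
  seq <- as.character(seq)
  stopifnot(length(id) == length(seq), length(ncrna_class) == 1L)
  if (anyDuplicated(id)) stop("duplicate reference ids")
  if (length(seq) > 0L && normalize) seq <- normalize_sequence(seq)
  structure(list(ncrna_class = as.character(ncrna_class), id = id, seq = seq,
                 raw = lapply(seq, charToRaw), index = NULL, seed_len = NA_integer_),
            class = "reference_set")
}

#' Read one reference class from FASTA
#'
#' @param path FASTA path.
#' @param ncrna_class Class label for every sequence in the file.
#' @return A \code{\link{reference_set}}.
#' @export
read_reference_fasta <- function(path, ncrna_class) {
  qs <- read_fasta(path)
  reference_set(qs$id, qs$seq, ncrna_class, normalize = FALSE)
}

#' Build the k-mer seed index of a reference set
#'
#' Enumerates every length-\code{seed_len} substring occurrence of every
#' reference (k-mers containing N are excluded). References shorter than the
#' seed are skipped from the index with a warning; they remain searchable via
#' \code{\link{brute_force_hits}}.
#'
#' @param refset A \code{\link{reference_set}}.
#' @param seed_len Seed length in nt (default 19).
#' @return The reference set with its \code{index} environment populated:
#'   each k-mer key maps to an integer matrix with columns \code{ref} (record
#'   index) and \code{offset} (0-based).
#' @export
build_seed_index <- function(refset, seed_len = 19L) {
  stopifnot(inherits(refset, "reference_set"))
  seed_len <- as.integer(seed_len)
  acc <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(refset$seq)) {
    s <- refset$seq[i]
    L <- nchar(s)
    if (L < seed_len) {
      warning(sprintf("reference '%s' (%d nt) shorter than seed (%d nt); not indexed",
                      refset$id[i], L, seed_len))
      next
    }
    starts <- seq_len(L - seed_len + 1L)
    kmers <- substring(s, starts, starts + seed_len - 1L)
    keep <- !grepl("N", kmers, fixed = TRUE)
    for (j in which(keep)) {
      k <- kmers[j]
      acc[[k]] <- c(acc[[k]], i, starts[j] - 1L)
    }
  }
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (k in ls(acc, all.names = TRUE)) {
    m <- matrix(acc[[k]], ncol = 2L, byrow = TRUE)
    colnames(m) <- c("ref", "offset")
    idx[[k]] <- m
  }
  refset$index <- idx
  refset$seed_len <- seed_len
  refset
}

#' Number of distinct k-mer keys in a seed index
#' @param refset An indexed \code{\link{reference_set}}.
#' @return Integer count of keys.
#' @export
seed_index_size <- function(refset) {
  stopifnot(!is.null(refset$index))
  length(ls(refset$index, all.names = TRUE))
}

#' Look up a k-mer in a seed index
#' @param refset An indexed \code{\link{reference_set}}.
#' @param kmer Character scalar of length \code{seed_len}.
#' @return Integer matrix of (ref, offset) occurrences, or NULL.
#' @export
seed_index_lookup <- function(refset, kmer) {
  stopifnot(!is.null(refset$index))
  refset$index[[kmer]]
}

ensure_index <- function(refset, seed_len) {
  if (is.null(refset$index) || !identical(refset$seed_len, as.integer(seed_len)))
    refset <- suppressWarnings(build_seed_index(refset, seed_len))
  refset
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# trim geometry for a query of length L: minimum aligned length and maximum
# total end-trim compatible with the coverage threshold
trim_geometry <- function(L, params) {
  a_min <- as.integer(ceiling(params$min_coverage * L - 1e-9))
  list(a_min = a_min, t_max = L - a_min)
}

mm_allowance <- function(A, params) {
  if (!is.null(params$max_mismatches)) return(params$max_mismatches)
  as.integer(floor((1 - params$min_identity) * A + 1e-9))
}

# Best ungapped alignment of the (possibly end-trimmed) query on one diagonal
# of one reference. d is the 0-based reference offset of query position 0.
# Returns c(mm, A, l, r) or NULL. Ranking: fewest mismatches, then longest
# aligned length, then smallest left trim.
best_on_diagonal <- function(qraw, rraw, d, params) {
  L <- length(qraw)
  reflen <- length(rraw)
  geom <- trim_geometry(L, params)
  best <- NULL
  for (l in 0:geom$t_max) {
    for (r in 0:(geom$t_max - l)) {
      A <- L - l - r
      rs <- d + l
      re <- d + L - r
      if (rs < 0L || re > reflen) next
      a <- qraw[(l + 1L):(L - r)]
      b <- rraw[(rs + 1L):re]
      mm <- sum(a != b | a == RAW_N | b == RAW_N)
      if (mm > mm_allowance(A, params)) next
      cand <- c(mm = mm, A = A, l = l, r = r)
      if (is.null(best) ||
          mm < best[["mm"]] ||
          (mm == best[["mm"]] && A > best[["A"]]) ||
          (mm == best[["mm"]] && A == best[["A"]] && l < best[["l"]])) {
        best <- cand
      }
    }
  }
  best
}

empty_hits <- function() {
  data.frame(query_id = character(0), ncrna_class = character(0),
             reference_id = character(0), ref_start = integer(0),
             ref_end = integer(0), query_start = integer(0),
             query_end = integer(0), strand = character(0),
             mismatches = integer(0), coverage = numeric(0),
             stringsAsFactors = FALSE)
}

sort_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$mismatches, -hits$coverage, hits$reference_id,
             hits$ref_start, hits$strand)
  hits <- hits[o, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

as_query <- function(query, query_id) {
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    list(id = query$id, seq = query$seq)
  } else {
    stopifnot(is.character(query), length(query) == 1L)
    list(id = query_id %||% "query", seq = query)
  }
}

hit_row <- function(qid, refset, i, st, d, best, L) {
  data.frame(query_id = qid, ncrna_class = refset$ncrna_class,
             reference_id = refset$id[i],
             ref_start = as.integer(d + best[["l"]]),
             ref_end = as.integer(d + L - best[["r"]]),
             query_start = as.integer(best[["l"]]),
             query_end = as.integer(L - best[["r"]]),
             strand = st, mismatches = as.integer(best[["mm"]]),
             coverage = best[["A"]] / L, stringsAsFactors = FALSE)
}

#' Find reference placements of a query via the seed index
#'
#' Reports the best ungapped alignment per (reference, strand, diagonal) that
#' satisfies the coverage and mismatch thresholds, restricted to diagonals on
#' which the query and reference share an exact \code{seed_len}-mer. Queries
#' shorter than the seed fall back to \code{\link{brute_force_hits}}
#' automatically. Coordinates are 0-based half-open; for minus-strand hits the
#' query coordinates refer to the reverse-complemented query.
#'
#' @param query Character scalar sequence or one-row query data.frame.
#' @param refset A \code{\link{reference_set}} (indexed on demand).
#' @param params \code{\link{match_params}}.
#' @param query_id Id used in the output when \code{query} is a bare string.
#' @return Hit data.frame sorted by (mismatches, -coverage, reference_id,
#'   ref_start); zero rows when nothing passes.
#' @export
find_hits <- function(query, refset, params = match_params(),
                      query_id = NULL) {
  qq <- as_query(query, query_id)
  L <- nchar(qq$seq)
  if (L < params$seed_len)
    return(brute_force_hits(qq$seq, refset, params, query_id = qq$id))
  refset <- ensure_index(refset, params$seed_len)
  strands <- if (params$strand_mode == "both") c("+", "-") else "+"
  rows <- list()
  for (st in strands) {
    qseq <- if (st == "+") qq$seq else revcomp(qq$seq)
    qraw <- charToRaw(qseq)
    starts <- seq_len(L - params$seed_len + 1L)
    kmers <- substring(qseq, starts, starts + params$seed_len - 1L)
    diag_seen <- character(0)
    for (j in seq_along(kmers)) {
      occ <- refset$index[[kmers[j]]]
      if (is.null(occ)) next
      for (k in seq_len(nrow(occ))) {
        i <- occ[k, "ref"]
        d <- occ[k, "offset"] - (starts[j] - 1L)
        key <- paste(i, d, sep = ":")
        if (key %in% diag_seen) next
        diag_seen <- c(diag_seen, key)
        best <- best_on_diagonal(qraw, refset$raw[[i]], d, params)
        if (!is.null(best))
          rows[[length(rows) + 1L]] <- hit_row(qq$id, refset, i, st, d, best, L)
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  sort_hits(do.call(rbind, rows))
}

#' Exhaustive brute-force matcher (verification oracle)
#'
#' Enumerates every end-trim split and every reference offset on both strands
#' (per \code{strand_mode}) with no seed requirement, then reduces to the best
#' alignment per (reference, strand, diagonal) under the same ranking as
#' \code{\link{find_hits}}. On any input where the aligned region retains an
#' exact \code{seed_len}-mer, its output equals \code{find_hits}; it
#' additionally finds seed-free placements the indexed search cannot.
#'
#' @inheritParams find_hits
#' @return Hit data.frame in the same format and order as
#'   \code{\link{find_hits}}.
#' @export
brute_force_hits <- function(query, refset, params = match_params(),
                             query_id = NULL) {
  qq <- as_query(query, query_id)
  L <- nchar(qq$seq)
  geom <- trim_geometry(L, params)
  strands <- if (params$strand_mode == "both") c("+", "-") else "+"
  rows <- list()
  for (st in strands) {
    qseq <- if (st == "+") qq$seq else revcomp(qq$seq)
    qchars <- strsplit(qseq, "", fixed = TRUE)[[1L]]
    for (i in seq_along(refset$seq)) {
      rchars <- strsplit(refset$seq[i], "", fixed = TRUE)[[1L]]
      reflen <- length(rchars)
      # all passing placements, keyed by diagonal
      cand <- list()
      for (l in 0:geom$t_max) {
        for (r in 0:(geom$t_max - l)) {
          A <- L - l - r
          if (A > reflen) next
          allow <- mm_allowance(A, params)
          qsub <- qchars[(l + 1L):(L - r)]
          for (rs in 0:(reflen - A)) {
            rsub <- rchars[(rs + 1L):(rs + A)]
            mm <- sum(qsub != rsub | qsub == "N" | rsub == "N")
            if (mm > allow) next
            d <- rs - l
            key <- as.character(d)
            prev <- cand[[key]]
            if (is.null(prev) ||
                mm < prev[["mm"]] ||
                (mm == prev[["mm"]] && A > prev[["A"]]) ||
                (mm == prev[["mm"]] && A == prev[["A"]] && l < prev[["l"]])) {
              cand[[key]] <- c(mm = mm, A = A, l = l, r = r, d = d)
            }
          }
        }
      }
      for (best in cand)
        rows[[length(rows) + 1L]] <-
          hit_row(qq$id, refset, i, st, best[["d"]], best, L)
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  sort_hits(do.call(rbind, rows))
}

class_priority <- function(cls) {
  p <- match(cls, NCRNA_CLASS_ORDER)
  # unknown classes rank after the canonical eight, alphabetically
  p[is.na(p)] <- length(NCRNA_CLASS_ORDER) + rank(cls[is.na(p)])
  p
}

#' Screen a candidate piRNA database against ncRNA reference classes
#'
#' Runs the matcher for every query over every reference class and tabulates
#' the overlap in the layout of a per-class count table: one column per class,
#' a TOTAL of distinct queries with at least one hit, and the percentage
#' TOTAL / n_queries * 100. Under the default single attribution each query is
#' counted once, in its best class (ranking: fewest mismatches, highest
#' coverage, then the fixed class priority rRNA > tRNA > miRNA > snRNA >
#' snoRNA > YRNA > m_tRNA > m_rRNA). \code{attribution = "multi"} instead
#' counts a query in every class where it has a hit (TOTAL still counts
#' distinct queries).
#'
#' @param queries A \code{\link{query_set}}.
#' @param refsets List of \code{\link{reference_set}} objects with distinct
#'   class labels.
#' @param params \code{\link{match_params}}.
#' @param attribution \code{"single"} (default) or \code{"multi"}.
#' @param database Label used in the output table (defaults to the query-set
#'   name).
#' @return An \code{overlap_screen} object: list with \code{table} (one-row
#'   data.frame: database, n_queries, one column per class, TOTAL, percent),
#'   \code{best_hits} (best hit per matched query), and the inputs' metadata.
#' @export
screen_database <- function(queries, refsets, params = match_params(),
                            attribution = c("single", "multi"),
                            database = NULL) {
  attribution <- match.arg(attribution)
  stopifnot(is.data.frame(queries))
  classes <- vapply(refsets, function(r) r$ncrna_class, character(1))
  if (anyDuplicated(classes)) stop("duplicate ncRNA class labels across reference sets")
  database <- database %||% (attr(queries, "name") %||% "database")
  refsets <- lapply(refsets, ensure_index, seed_len = params$seed_len)

  best_rows <- list()
  all_rows <- list()
  for (qi in seq_len(nrow(queries))) {
    hits <- lapply(refsets, function(rs)
      find_hits(queries$seq[qi], rs, params, query_id = queries$id[qi]))
    hits <- do.call(rbind, c(hits, list(empty_hits())))
    if (nrow(hits) == 0L) next
    all_rows[[length(all_rows) + 1L]] <- hits
    o <- order(hits$mismatches, -hits$coverage,
               class_priority(hits$ncrna_class), hits$reference_id,
               hits$ref_start)
    best_rows[[length(best_rows) + 1L]] <- hits[o[1L], , drop = FALSE]
  }
  best_hits <- if (length(best_rows)) do.call(rbind, best_rows) else empty_hits()
  rownames(best_hits) <- NULL

  counts <- stats::setNames(integer(length(classes)), classes)
  if (attribution == "single") {
    tb <- table(best_hits$ncrna_class)
  } else {
    per_class <- lapply(all_rows, function(h) unique(h$ncrna_class))
    tb <- table(unlist(per_class))
  }
  counts[names(tb)] <- as.integer(tb)
  total <- nrow(best_hits)
  n_queries <- nrow(queries)
  tabrow <- data.frame(database = database, n_queries = n_queries,
                       check.names = FALSE, stringsAsFactors = FALSE)
  for (cls in names(counts)) tabrow[[cls]] <- counts[[cls]]
  tabrow$TOTAL <- total
  tabrow$percent <- if (n_queries > 0L) overlap_percent(total, n_queries) else NA_real_
  structure(list(table = tabrow, best_hits = best_hits,
                 attribution = attribution, params = params),
            class = "overlap_screen")
}

#' Overlap percentage of a screen
#'
#' The percentage an overlap table reports for a database:
#' \code{100 * n_matched / n_queries}.
#'
#' @param n_matched Number of distinct queries with at least one hit.
#' @param n_queries Database size.
#' @return Percentage (full precision; tables render it to two decimals).
#' @export
overlap_percent <- function(n_matched, n_queries) {
  stopifnot(n_queries > 0, n_matched >= 0, n_matched <= n_queries)
  100 * n_matched / n_queries
}

#' @export
print.overlap_screen <- function(x, ...) {
  tab <- x$table
  tab$percent <- sprintf("%.2f", tab$percent)
  cat("Overlap screen (", x$attribution, " attribution)\n", sep = "")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a Table-1-style overlap table
#'
#' @param screens List of \code{overlap_screen} objects (or a single one).
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_overlap_table <- function(screens, path) {
  if (inherits(screens, "overlap_screen")) screens <- list(screens)
  tab <- do.call(rbind, lapply(screens, function(s) s$table))
  tab$percent <- sprintf("%.2f", tab$percent)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
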