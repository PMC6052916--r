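# Ratio-of-ratios Enrichment Score over two-way category partitions, plus an
# upper-tail hypergeometric overlap test. ES = (query B/A) / (reference B/A):
# ES > 1 means category B is over-represented in the query relative to the
# reference database.

#' Construct a two-way category partition
#'
#' @param count_A,count_B Non-negative counts of sequences in the two
#'   mutually exclusive, exhaustive categories.
#' @param label_A,label_B Category labels.
#' @param weight_A,weight_B Optional non-negative read weights (summed RPM or
#'   raw reads) for the two categories.
#' @return A \code{category_partition} object.
#' @export
category_partition <- function(count_A, count_B, label_A = "A", label_B = "B",
                               weight_A = NULL, weight_B = NULL) {
  stopifnot(count_A >= 0, count_B >= 0)
  if (!is.null(weight_A)) stopifnot(weight_A >= 0)
  if (!is.null(weight_B)) stopifnot(weight_B >= 0)
  structure(list(label_A = label_A, label_B = label_B,
                 count_A = as.numeric(count_A), count_B = as.numeric(count_B),
                 weight_A = weight_A, weight_B = weight_B),
            class = "category_partition")
}

#' @export
print.category_partition <- function(x, ...) {
  cat(sprintf("Partition: %s = %g, %s = %g", x$label_A, x$count_A,
              x$label_B, x$count_B))
  if (!is.null(x$weight_A))
    cat(sprintf("  (weights %g / %g)", x$weight_A, x$weight_B))
  cat("\n")
  invisible(x)
}

#' Partition a sequence set into categories A/B
#'
#' Two predicates are supported, mirroring the two ways a piRNA database is
#' split: \code{"starts_with_U"} puts sequences whose first base is T (U in
#' RNA) in category A and the rest in B; \code{"matches_ncRNA"} puts
#' sequences with no ncRNA match in A and matched ncRNA fragments in B
#' (requires an annotation table). Weights are summed from \code{rpm} when
#' any are present.
#'
#' @param queries A \code{\link{query_set}}.
#' @param predicate \code{"starts_with_U"} or \code{"matches_ncRNA"}.
#' @param annotations Annotation data.frame from
#'   \code{\link{annotate_queries}}, required for \code{matches_ncRNA}; every
#'   query id must be annotated.
#' @return A \code{\link{category_partition}}.
#' @export
partition_sequences <- function(queries,
                                predicate = c("starts_with_U", "matches_ncRNA"),
                                annotations = NULL) {
  predicate <- match.arg(predicate)
  stopifnot(is.data.frame(queries))
  if (nrow(queries) == 0L) stop("cannot partition an empty sequence set")
  if (predicate == "starts_with_U") {
    in_A <- substr(queries$seq, 1L, 1L) == "T"
    labs <- c("5'U", "no 5'U")
  } else {
    if (is.null(annotations)) stop("matches_ncRNA needs an annotation table")
    idx <- match(queries$id, annotations$id)
    if (anyNA(idx)) {
      missing <- queries$id[is.na(idx)]
      stop("missing annotations for: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    in_A <- annotations$category[idx] != "ncRNA_fragment"
    labs <- c("no ncRNA match", "ncRNA match")
  }
  wA <- wB <- NULL
  if ("rpm" %in% names(queries) && any(!is.na(queries$rpm))) {
    wA <- sum(queries$rpm[in_A], na.rm = TRUE)
    wB <- sum(queries$rpm[!in_A], na.rm = TRUE)
  }
  category_partition(sum(in_A), sum(!in_A), labs[1L], labs[2L], wA, wB)
}

es_ratio <- function(qA, qB, rA, rB, pseudocount) {
  if (pseudocount) {
    qA <- qA + 0.5; qB <- qB + 0.5; rA <- rA + 0.5; rB <- rB + 0.5
  }
  if (rA <= 0 || rB <= 0)
    stop("reference category empty: reference ratio undefined")
  flags <- character(0)
  if (qB == 0) {
    es <- 0
    if (qA == 0) flags <- "query_empty"
  } else if (qA == 0) {
    es <- Inf
    flags <- "query_A_zero"
  } else {
    es <- (qB / qA) / (rB / rA)
  }
  list(es = es, flags = flags)
}

#' Enrichment Score of a query partition against a reference partition
#'
#' ES = (query_B / query_A) / (ref_B / ref_A). A query with category A empty
#' but B occupied yields +Inf with a degeneracy flag (the score is then a
#' lower bound, conventionally reported as "ES > x"); a query with B empty
#' yields 0. A pseudocount option (+0.5 on all four cells) gives a finite
#' score in degenerate cases. The weighted variant substitutes summed read
#' weights for counts.
#'
#' @param ref,query \code{\link{category_partition}} objects; reference must
#'   have both categories non-empty.
#' @param use_weights Also compute the read-weighted ES (both partitions must
#'   carry weights)?
#' @param pseudocount Add 0.5 to all four cells before forming ratios?
#' @return An \code{enrichment_result} object: list with \code{es_by_count},
#'   \code{es_by_weight} (or NULL), the two partitions and \code{flags}.
#' @export
enrichment_score <- function(ref, query, use_weights = FALSE,
                             pseudocount = FALSE) {
  stopifnot(inherits(ref, "category_partition"),
            inherits(query, "category_partition"))
  cnt <- es_ratio(query$count_A, query$count_B, ref$count_A, ref$count_B,
                  pseudocount)
  es_w <- NULL
  flags <- cnt$flags
  if (use_weights) {
    if (is.null(ref$weight_A) || is.null(query$weight_A))
      stop("weighted ES requested but weights are missing")
    w <- es_ratio(query$weight_A, query$weight_B, ref$weight_A, ref$weight_B,
                  pseudocount)
    es_w <- w$es
    if (length(w$flags))
      flags <- union(flags, paste0("weight_", w$flags))
  }
  structure(list(es_by_count = cnt$es, es_by_weight = es_w,
                 ref_partition = ref, query_partition = query,
                 flags = flags),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("ES (by count) = %g", x$es_by_count))
  if (!is.null(x$es_by_weight)) cat(sprintf(", ES (by weight) = %g", x$es_by_weight))
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Serialize an enrichment result as JSON
#'
#' @param result An \code{\link{enrichment_score}} result.
#' @param path Optional output path; when NULL the JSON string is returned.
#' @return The JSON string (invisibly when written to \code{path}).
#' @export
enrichment_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "enrichment_result"))
  strip <- function(p) p[c("label_A", "label_B", "count_A", "count_B",
                           "weight_A", "weight_B")]
  obj <- list(es_by_count = result$es_by_count,
              es_by_weight = result$es_by_weight,
              ref_partition = strip(result$ref_partition),
              query_partition = strip(result$query_partition),
              flags = result$flags)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of drawing at least \code{n_query_in_class} members of a class
#' of size \code{n_class_in_universe} when sampling \code{n_query} sequences
#' without replacement from a universe of \code{universe_size}:
#' P(X >= n_query_in_class).
#'
#' @param universe_size Total number of sequences in the universe.
#' @param n_class_in_universe Number of class members in the universe.
#' @param n_query Query size.
#' @param n_query_in_class Observed overlap.
#' @return The upper-tail p-value.
#' @export
overlap_pvalue <- function(universe_size, n_class_in_universe, n_query,
                           n_query_in_class) {
  stopifnot(universe_size >= 0, n_class_in_universe >= 0, n_query >= 0,
            n_query_in_class >= 0)
  if (n_class_in_universe > universe_size || n_query > universe_size)
    stop("class and query must fit inside the universe")
  if (n_query_in_class > min(n_class_in_universe, n_query))
    stop("overlap exceeds class or query size")
  stats::phyper(n_query_in_class - 1, n_class_in_universe,
                universe_size - n_class_in_universe, n_query,
                lower.tail = FALSE)
}
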