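# Thin stage drivers tying the modules together; the numbered scripts under
# analysis/ and scripts/acceptance.R are built on these.

#' Screen a database at one or more mismatch allowances
#'
#' Runs \code{\link{screen_database}} once per MM value (coverage threshold
#' unchanged) and optionally writes the overlap table and per-hit
#' annotations.
#'
#' @param queries A \code{\link{query_set}}.
#' @param refsets List of \code{\link{reference_set}} objects.
#' @param mm Integer vector of mismatch allowances (default c(0, 1)).
#' @param base_params \code{\link{match_params}} supplying the remaining
#'   thresholds.
#' @param out_dir Optional output directory for TSVs.
#' @return List with \code{screens} (one \code{overlap_screen} per MM, named
#'   "MM0", "MM1", ...) and \code{table} (their rows combined, with an
#'   \code{MM} column).
#' @export
run_screen <- function(queries, refsets, mm = c(0L, 1L),
                       base_params = match_params(), out_dir = NULL) {
  if (nrow(queries) == 0L) warning("no queries to screen")
  screens <- list()
  rows <- list()
  for (m in mm) {
    p <- match_params(seed_len = base_params$seed_len,
                      min_coverage = base_params$min_coverage,
                      min_identity = base_params$min_identity,
                      max_mismatches = m,
                      strand_mode = base_params$strand_mode)
    s <- screen_database(queries, refsets, p)
    key <- sprintf("MM%d", m)
    screens[[key]] <- s
    rows[[key]] <- cbind(MM = m, s$table)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- tab
    out$percent <- sprintf("%.2f", out$percent)
    utils::write.table(out, file.path(out_dir, "overlap_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (key in names(screens)) {
      utils::write.table(screens[[key]]$best_hits,
                         file.path(out_dir, sprintf("best_hits_%s.tsv", key)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(screens = screens, table = tab)
}

#' Enrichment scores of a query set against a reference database
#'
#' Computes the ES for both partition predicates (5' base and ncRNA
#' identity), by sequence count and — when abundances are present — by summed
#' read weight.
#'
#' @param ref_queries Reference database \code{\link{query_set}}.
#' @param query_queries Query \code{\link{query_set}}.
#' @param ref_annotations,query_annotations Annotation tables covering the
#'   two sets (needed for the ncRNA predicate).
#' @param use_weights Compute read-weighted ES variants?
#' @return data.frame with one row per (predicate, weighting) combination.
#' @export
run_enrichment <- function(ref_queries, query_queries,
                           ref_annotations = NULL, query_annotations = NULL,
                           use_weights = FALSE) {
  preds <- c("starts_with_U", "matches_ncRNA")
  rows <- list()
  for (pred in preds) {
    if (pred == "matches_ncRNA" &&
        (is.null(ref_annotations) || is.null(query_annotations))) next
    rp <- partition_sequences(ref_queries, pred, ref_annotations)
    qp <- partition_sequences(query_queries, pred, query_annotations)
    res <- enrichment_score(rp, qp, use_weights = use_weights)
    rows[[length(rows) + 1L]] <- data.frame(
      predicate = pred, weighting = "count", es = res$es_by_count,
      flags = paste(res$flags, collapse = ";"), stringsAsFactors = FALSE)
    if (use_weights && !is.null(res$es_by_weight)) {
      rows[[length(rows) + 1L]] <- data.frame(
        predicate = pred, weighting = "reads", es = res$es_by_weight,
        flags = paste(res$flags, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Contamination report over abundance cutoffs, with composition
#'
#' One contamination summary per cutoff, plus positional composition and
#' length statistics of the ncRNA-fragment and remaining subsets.
#'
#' @param annotations Annotation data.frame carrying rpm values.
#' @param cutoffs Numeric vector of RPM cutoffs.
#' @param n_positions Positions for the composition matrices.
#' @return List with \code{summaries} (data.frame),
#'   \code{composition_ncRNA}, \code{composition_other},
#'   \code{lengths_ncRNA}, \code{lengths_other}.
#' @export
run_contamination_report <- function(annotations, cutoffs = c(10, 50),
                                     n_positions = 15L) {
  summaries <- contamination_summaries(annotations, cutoffs)
  is_nc <- annotations$category == "ncRNA_fragment"
  comp_nc <- if (any(is_nc))
    positional_composition(annotations$sequence[is_nc], n_positions) else NULL
  comp_other <- if (any(!is_nc))
    positional_composition(annotations$sequence[!is_nc], n_positions) else NULL
  list(summaries = summaries,
       composition_ncRNA = comp_nc,
       composition_other = comp_other,
       lengths_ncRNA = length_stats(annotations$sequence[is_nc]),
       lengths_other = length_stats(annotations$sequence[!is_nc]))
}
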