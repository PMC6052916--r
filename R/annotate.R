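# Per-sequence alternative annotation (best ncRNA hit, externally provided
# label, or unannotated) and abundance-threshold contamination summaries.

#' Map an alternative-annotation label to an ncRNA class
#'
#' Annotation labels in published re-annotation tables name the source
#' transcript (e.g. "RNAY4", "MT_tRNA-Val", "snoRNA 85", "miR-532-5p") or an
#' externally provided non-ncRNA label ("piRNACluster Chr5", "CDS: MT_CO2").
#' This maps a label to one of the eight reference classes, or \code{NA} for
#' provided labels that are not ncRNA fragments.
#'
#' @param label Character vector of labels.
#' @return Character vector of class names
#'   (rRNA/tRNA/miRNA/snRNA/snoRNA/YRNA/m_tRNA/m_rRNA) or \code{NA}.
#' @export
classify_label <- function(label) {
  out <- rep(NA_character_, length(label))
  rules <- list(
    YRNA    = "^(RNA?Y|RNY)",
    m_rRNA  = "^MT[_-]rRNA",
    m_tRNA  = "^MT[_-]tRNA",
    tRNA    = "^tRNA",
    rRNA    = "^rRNA",
    snoRNA  = "^snoRNA",
    snRNA   = "^snRNA",
    miRNA   = "^(miR|let-|mir)"
  )
  for (cls in names(rules)) {
    hit <- is.na(out) & grepl(rules[[cls]], label)
    out[hit] <- cls
  }
  out
}

#' Annotate queries with their best ncRNA hit or a provided label
#'
#' For each query the best hit across all reference classes is chosen per the
#' matcher's ranking plus the fixed class priority; matched queries get
#' category \code{"ncRNA_fragment"}. Queries with no hit fall back to an
#' externally provided label (e.g. piRNA-cluster membership or a CDS
#' annotation that the matcher does not compute) when one is supplied, and to
#' \code{"unannotated"} otherwise. A provided label never overrides a
#' matcher-found ncRNA fragment.
#'
#' @param queries A \code{\link{query_set}}.
#' @param refsets List of \code{\link{reference_set}} objects.
#' @param params \code{\link{match_params}}.
#' @param provided Optional named character vector mapping query ids to
#'   provided labels.
#' @return Annotation data.frame with columns id, sequence, length,
#'   best_class, reference_id, ref_start (1-based), strand, mismatches,
#'   category, rpm, detected_in.
#' @export
annotate_queries <- function(queries, refsets, params = match_params(),
                             provided = NULL) {
  screen <- screen_database(queries, refsets, params)
  bh <- screen$best_hits
  idx <- match(queries$id, bh$query_id)
  has_hit <- !is.na(idx)
  category <- ifelse(has_hit, "ncRNA_fragment", "unannotated")
  if (!is.null(provided)) {
    prov <- provided[match(queries$id, names(provided))]
    use_prov <- !has_hit & !is.na(prov)
    category[use_prov] <- prov[use_prov]
  }
  data.frame(
    id = queries$id,
    sequence = queries$seq,
    length = nchar(queries$seq),
    best_class = ifelse(has_hit, bh$ncrna_class[idx], NA_character_),
    reference_id = ifelse(has_hit, bh$reference_id[idx], NA_character_),
    ref_start = ifelse(has_hit, bh$ref_start[idx] + 1L, NA_integer_),
    strand = ifelse(has_hit, bh$strand[idx], NA_character_),
    mismatches = ifelse(has_hit, bh$mismatches[idx], NA_integer_),
    category = category,
    rpm = if ("rpm" %in% names(queries)) queries$rpm else NA_real_,
    detected_in = if ("detected_in" %in% names(queries)) queries$detected_in else NA_integer_,
    stringsAsFactors = FALSE)
}

#' Contamination summary above an abundance cutoff
#'
#' Among records with mean abundance >= \code{rpm_cutoff}, the number and
#' percentage whose category is \code{"ncRNA_fragment"}. Provided labels
#' (piRNA-cluster membership, CDS hits) count as non-ncRNA. The percentage is
#' kept at full precision; the print method renders it to the nearest
#' integer, matching how such percentages are conventionally quoted.
#'
#' @param records Annotation data.frame with \code{rpm} and \code{category}
#'   columns; every record must carry an rpm value.
#' @param rpm_cutoff Non-negative abundance cutoff in RPM.
#' @return A \code{contamination_summary} object: list with
#'   \code{rpm_cutoff}, \code{n_total}, \code{n_ncRNA},
#'   \code{percent_ncRNA} (NA when no record passes the cutoff) and
#'   \code{defined}.
#' @export
contamination_summary <- function(records, rpm_cutoff) {
  stopifnot(is.data.frame(records), rpm_cutoff >= 0)
  if (nrow(records) > 0L && anyNA(records$rpm)) {
    stop("records without rpm: ",
         paste(utils::head(records$id[is.na(records$rpm)], 5L), collapse = ", "))
  }
  keep <- if (nrow(records) == 0L) logical(0) else records$rpm >= rpm_cutoff
  n_total <- sum(keep)
  n_nc <- sum(keep & records$category == "ncRNA_fragment")
  pct <- if (n_total > 0L) 100 * n_nc / n_total else NA_real_
  structure(list(rpm_cutoff = rpm_cutoff, n_total = as.integer(n_total),
                 n_ncRNA = as.integer(n_nc), percent_ncRNA = pct,
                 defined = n_total > 0L),
            class = "contamination_summary")
}

#' @export
print.contamination_summary <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("RPM >= %g: no sequences pass the cutoff (percent undefined)\n",
                x$rpm_cutoff))
  } else {
    cat(sprintf("RPM >= %g: %d/%d ncRNA fragments (%.0f%%)\n",
                x$rpm_cutoff, x$n_ncRNA, x$n_total, x$percent_ncRNA))
  }
  invisible(x)
}

#' Contamination summaries over several cutoffs
#'
#' @param records Annotation data.frame (see
#'   \code{\link{contamination_summary}}).
#' @param cutoffs Numeric vector of RPM cutoffs.
#' @return data.frame with one row per cutoff: rpm_cutoff, n_total, n_ncRNA,
#'   percent_ncRNA.
#' @export
contamination_summaries <- function(records, cutoffs) {
  rows <- lapply(cutoffs, function(ct) {
    s <- contamination_summary(records, ct)
    data.frame(rpm_cutoff = s$rpm_cutoff, n_total = s$n_total,
               n_ncRNA = s$n_ncRNA, percent_ncRNA = s$percent_ncRNA)
  })
  do.call(rbind, rows)
}

#' Serialize a contamination summary as JSON
#'
#' @param summary A \code{\link{contamination_summary}}.
#' @param path Optional output path.
#' @return JSON string (invisibly when written).
#' @export
contamination_json <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "contamination_summary"))
  obj <- list(cutoff = summary$rpm_cutoff, n_total = summary$n_total,
              n_ncRNA = summary$n_ncRNA, percent = summary$percent_ncRNA)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

extdata <- function(f) {
  p <- system.file("extdata", f, package = "pirnascreen", mustWork = TRUE)
  p
}

#' Bundled plasma piRNA abundance table
#'
#' The 25 piRNAs reported in human blood plasma at >= 10 RPM mean abundance
#' across 40 individuals, with their published alternative annotations
#' (ncRNA source and start where applicable; piRNA-cluster or CDS labels
#' otherwise). Ships as plain TSV under \code{extdata}.
#'
#' @return A \code{\link{query_set}} with extra columns \code{alternative},
#'   \code{start_type} and \code{reported_length}.
#' @export
load_plasma_pirnas <- function() {
  df <- utils::read.delim(extdata("plasma_pirnas.tsv"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  qs <- query_set(df$id, df$sequence, rpm = df$rpm,
                  detected_in = df$detected_in, name = "plasma")
  qs$alternative <- df$alternative
  qs$start_type <- df$start_type
  qs$reported_length <- df$reported_length
  qs
}

#' Annotation records for the bundled plasma piRNAs
#'
#' Builds an annotation table from the published labels (no matching is run:
#' the source references are not bundled, so the labels are taken as
#' provided). Labels naming an ncRNA source become category
#' \code{"ncRNA_fragment"} with the class from \code{\link{classify_label}};
#' piRNA-cluster and CDS labels are carried through as provided labels.
#'
#' @return Annotation data.frame as from \code{\link{annotate_queries}}.
#' @export
plasma_annotations <- function() {
  qs <- load_plasma_pirnas()
  cls <- classify_label(qs$alternative)
  is_nc <- !is.na(cls)
  start_num <- suppressWarnings(as.integer(qs$start_type))
  data.frame(
    id = qs$id,
    sequence = qs$seq,
    length = qs$length,
    best_class = cls,
    reference_id = ifelse(is_nc, qs$alternative, NA_character_),
    ref_start = ifelse(is_nc, start_num, NA_integer_),
    strand = ifelse(is_nc, "+", NA_character_),
    mismatches = NA_integer_,
    category = ifelse(is_nc, "ncRNA_fragment",
                      trimws(paste(qs$alternative, qs$start_type))),
    rpm = qs$rpm,
    detected_in = qs$detected_in,
    stringsAsFactors = FALSE)
}

#' Bundled mouse-brain piRNA table
#'
#' The 20 piRNAs reported in mouse hippocampus, with read counts, published
#' alternative annotations, and reads observed in a MIWI RIP-seq study.
#'
#' @return data.frame with columns id, reads, alternative, sequence,
#'   miwi_ip_reads, chr17_cluster.
#' @export
load_brain_pirnas <- function() {
  utils::read.delim(extdata("mouse_brain_pirnas.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Bundled tumor piRNA table
#'
#' The 20 most abundant piRNAs found across tumor transcriptomes, with summed
#' normalized reads and published alternative annotations.
#'
#' @return data.frame with columns id, sum_rpm_cancer, alternative, sequence.
#' @export
load_tumor_pirnas <- function() {
  utils::read.delim(extdata("tumor_pirnas.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Bundled database overlap counts
#'
#' Published totals of ambiguous sequences (exact matches to ncRNA
#' references, MM = 0) in two human piRNA databases, together with the
#' database sizes.
#'
#' @return data.frame with columns database, n_sequences, n_ambiguous_mm0.
#' @export
load_db_overlap_counts <- function() {
  utils::read.delim(extdata("db_overlap_counts.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}
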