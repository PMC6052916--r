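`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a nucleotide sequence to the DNA alphabet
#'
#' Small-RNA databases mix RNA/DNA alphabets and letter cases. All internal
#' matching works on uppercase DNA: U is rewritten to T and any character
#' outside A/C/G/T becomes N. N never matches any base during alignment.
#'
#' @param raw Character vector of raw sequences (non-empty strings).
#' @return Character vector of the same length, uppercase over {A,C,G,T,N},
#'   with per-element length preserved.
#' @examples
#' normalize_sequence("ugAaC")  # "TGAAC"
#' @export
normalize_sequence <- function(raw) {
  if (length(raw) == 0L) stop("no sequences supplied")
  if (anyNA(raw) || any(!nzchar(raw))) stop("empty sequence not allowed")
  x <- chartr("U", "T", toupper(raw))
  gsub("[^ACGT]", "N", x)
}

#' Construct a query set
#'
#' A query set is a plain \code{data.frame} (class \code{query_set}) with one
#' row per candidate piRNA: columns \code{id}, \code{seq}, \code{length},
#' \code{rpm} (mean reads-per-million, \code{NA} when unknown) and
#' \code{detected_in} (number of individuals, \code{NA} when unknown).
#' Ids must be unique: database provenance matters in this application, so
#' duplicates are rejected rather than silently suffixed.
#'
#' @param id Character vector of unique identifiers.
#' @param seq Character vector of sequences (normalized unless
#'   \code{normalize = FALSE}).
#' @param rpm Optional numeric vector of non-negative mean RPM values.
#' @param detected_in Optional integer vector of detection counts.
#' @param name Label for the set (e.g. database name).
#' @param normalize Run \code{\link{normalize_sequence}} on \code{seq}?
#' @return A \code{query_set} data.frame.
#' @export
query_set <- function(id, seq, rpm = NA_real_, detected_in = NA_integer_,
                      name = "", normalize = TRUE) {
  id <- as.character(id)
  seq <- as.character(seq)
  stopifnot(length(id) == length(seq))
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate sequence ids: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (length(seq) > 0L && normalize) seq <- normalize_sequence(seq)
  rpm <- rep_len(as.numeric(rpm), length(id))
  if (any(!is.na(rpm) & rpm < 0)) stop("rpm must be >= 0")
  detected_in <- rep_len(as.integer(detected_in), length(id))
  qs <- data.frame(id = id, seq = seq, length = nchar(seq),
                   rpm = rpm, detected_in = detected_in,
                   stringsAsFactors = FALSE)
  attr(qs, "name") <- name
  class(qs) <- c("query_set", "data.frame")
  qs
}

# accept a query_set, data.frame with id/seq, or bare character vector
get_seqs <- function(queries) {
  if (is.character(queries)) return(queries)
  if (is.data.frame(queries) && "seq" %in% names(queries)) return(queries$seq)
  stop("expected a character vector or a data.frame with a 'seq' column")
}

#' Read a FASTA file into a query set
#'
#' Accepts any multi-record FASTA (wrapped or unwrapped) with
#' \code{">id [description]"} headers; the id is the first whitespace-delimited
#' token. Sequences are normalized to the DNA alphabet.
#'
#' @param path Path to a FASTA file.
#' @param name Label for the resulting set (defaults to the file name).
#' @return A \code{\link{query_set}}.
#' @export
read_fasta <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    return(query_set(character(0), character(0), name = name))
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop(sprintf("malformed FASTA: sequence line before any header at line %d",
                 nonblank[1L]))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  query_set(ids, as.character(ss), name = name)
}

#' Write a query set as FASTA
#'
#' @param queries A \code{\link{query_set}} or data.frame with id/seq columns.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(queries, path) {
  stopifnot(is.data.frame(queries), all(c("id", "seq") %in% names(queries)))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(queries) > 0L)
    writeLines(paste0(">", queries$id, "\n", queries$seq), con)
  invisible(path)
}

#' Read a sequence abundance table
#'
#' Reads a tab-delimited table with header columns \code{id},
#' \code{sequence} (or \code{seq}), and optionally \code{rpm} and
#' \code{detected_in}, as used for query sets carrying mean expression
#' (reads per million) and per-individual detection counts.
#'
#' @param path Path to a TSV file with a header row.
#' @param name Label for the resulting set.
#' @return A \code{\link{query_set}} with rpm/detected_in populated where
#'   present.
#' @export
read_abundance_table <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  seq_col <- intersect(c("sequence", "seq"), names(df))
  if (!("id" %in% names(df)) || length(seq_col) == 0L)
    stop("abundance table needs 'id' and 'sequence' columns")
  rpm <- rep(NA_real_, nrow(df))
  if ("rpm" %in% names(df)) {
    raw <- df$rpm
    has <- !is.na(raw) & nzchar(raw)
    num <- suppressWarnings(as.numeric(raw[has]))
    if (anyNA(num)) {
      bad <- which(has)[which(is.na(num))[1L]]
      stop(sprintf("non-numeric rpm value %s at row %d", sQuote(raw[which(has)[which(is.na(num))[1L]]]), bad))
    }
    rpm[has] <- num
  }
  det <- rep(NA_integer_, nrow(df))
  if ("detected_in" %in% names(df)) {
    raw <- df$detected_in
    has <- !is.na(raw) & nzchar(raw)
    det[has] <- as.integer(suppressWarnings(as.numeric(raw[has])))
  }
  query_set(df$id, df[[seq_col[1L]]], rpm = rpm, detected_in = det, name = name)
}

annotation_columns <- c("id", "sequence", "length", "best_class",
                        "reference_id", "ref_start", "strand", "mismatches",
                        "category", "rpm", "detected_in")

#' Write an annotation table
#'
#' Serializes per-sequence alternative annotations (best ncRNA hit, provided
#' label, or unannotated) as a TSV with a fixed column set and deterministic
#' row order (input order). \code{ref_start} is the 1-based start of the hit
#' inside the reference, matching the convention of human-readable reports.
#'
#' @param records Annotation data.frame as produced by
#'   \code{\link{annotate_queries}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_table <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(annotation_columns)),
                      annotation_columns))
  }
  missing <- setdiff(annotation_columns, names(records))
  for (m in missing) records[[m]] <- NA
  utils::write.table(records[annotation_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back an annotation table written by \code{write_annotation_table}
#'
#' @param path Path to the TSV.
#' @return Annotation data.frame.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  df
}
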