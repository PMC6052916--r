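# Positional base composition and length statistics. Bona fide primary
# piRNAs carry a strong 5' uridine bias (and a weaker position-10 adenine
# bias from ping-pong amplification); ncRNA fragments do not, and run longer.

#' Positional base-composition matrix
#'
#' Per-position A/C/G/T counts, frequencies and information content over the
#' first \code{n_positions} bases of a sequence set. Position p (1-based)
#' counts only sequences of length >= p — denominators shrink along the
#' ragged right edge rather than padding, which is how logos over
#' variable-length small RNAs are conventionally drawn. Ns are excluded from
#' the counted bases. Information content is
#' \code{2 + sum(f * log2(f))} bits with \code{0 * log(0) = 0}.
#'
#' @param queries A \code{\link{query_set}}, data.frame with a \code{seq}
#'   column, or character vector of sequences.
#' @param n_positions Number of 5' positions to tabulate (default 15).
#' @return A \code{positional_composition} object: list with \code{counts}
#'   and \code{freqs} (n_positions x 4 matrices), \code{info_bits},
#'   \code{n_at_position}, \code{n_seqs}, \code{n_positions}.
#' @export
positional_composition <- function(queries, n_positions = 15L) {
  seqs <- get_seqs(queries)
  n_positions <- as.integer(n_positions)
  stopifnot(n_positions >= 1L)
  if (length(seqs) == 0L) stop("no sequences: composition undefined")
  len <- nchar(seqs)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, n_positions, 4L, dimnames = list(NULL, bases))
  n_at <- integer(n_positions)
  for (p in seq_len(n_positions)) {
    covered <- seqs[len >= p]
    ch <- substr(covered, p, p)
    tb <- table(factor(ch, levels = bases))
    counts[p, ] <- as.integer(tb)
    n_at[p] <- sum(counts[p, ])
  }
  denom <- pmax(n_at, 1L)
  freqs <- counts / denom
  info <- apply(freqs, 1L, function(f) {
    nz <- f[f > 0]
    2 + sum(nz * log2(nz))
  })
  info[n_at == 0L] <- NA_real_
  structure(list(n_positions = n_positions, counts = counts, freqs = freqs,
                 info_bits = info, n_at_position = n_at,
                 n_seqs = length(seqs)),
            class = "positional_composition")
}

#' @export
print.positional_composition <- function(x, ...) {
  cat(sprintf("Positional composition over %d sequences (first %d positions)\n",
              x$n_seqs, x$n_positions))
  df <- data.frame(position = seq_len(x$n_positions), round(x$freqs, 3),
                   bits = round(x$info_bits, 3), n = x$n_at_position)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a composition matrix as TSV
#'
#' Rows are positions 1..n; columns are per-base counts, per-base
#' frequencies, information content in bits and the per-position denominator.
#'
#' @param pcm A \code{\link{positional_composition}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_composition_table <- function(pcm, path) {
  stopifnot(inherits(pcm, "positional_composition"))
  df <- data.frame(position = seq_len(pcm$n_positions))
  for (b in colnames(pcm$counts)) df[[paste0("count_", b)]] <- pcm$counts[, b]
  for (b in colnames(pcm$freqs)) df[[paste0("freq_", b)]] <- pcm$freqs[, b]
  df$info_bits <- pcm$info_bits
  df$n <- pcm$n_at_position
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fraction of sequences with a given base at a given position
#'
#' Computed over the sequences long enough to cover the position (Ns stay in
#' the denominator).
#'
#' @param queries Sequences (as in \code{\link{positional_composition}}).
#' @param position 1-based position.
#' @param base Single base, one of A/C/G/T (U is accepted and read as T).
#' @return List with \code{fraction} and the denominator \code{n}.
#' @export
base_fraction_at <- function(queries, position, base) {
  seqs <- get_seqs(queries)
  position <- as.integer(position)
  stopifnot(position >= 1L, is.character(base), nchar(base) == 1L)
  base <- chartr("U", "T", toupper(base))
  covered <- seqs[nchar(seqs) >= position]
  if (length(covered) == 0L)
    stop(sprintf("no sequence reaches position %d", position))
  ch <- substr(covered, position, position)
  list(fraction = mean(ch == base), n = length(covered))
}

#' Length-distribution statistics
#'
#' @param queries Sequences (as in \code{\link{positional_composition}}).
#' @param threshold Length cutoff in nt for the upper-tail fraction
#'   (default 30).
#' @return A \code{length_stats} object: list with \code{n}, \code{mean},
#'   \code{sd}, \code{threshold}, \code{frac_ge} (fraction of sequences with
#'   length >= threshold) and \code{defined} (\code{FALSE} when \code{n = 0},
#'   in which case mean/sd/frac_ge are \code{NA}).
#' @export
length_stats <- function(queries, threshold = 30L) {
  seqs <- get_seqs(queries)
  len <- nchar(seqs)
  n <- length(len)
  if (n == 0L) {
    return(structure(list(n = 0L, mean = NA_real_, sd = NA_real_,
                          threshold = as.integer(threshold),
                          frac_ge = NA_real_, defined = FALSE),
                     class = "length_stats"))
  }
  structure(list(n = n, mean = mean(len), sd = stats::sd(len),
                 threshold = as.integer(threshold),
                 frac_ge = mean(len >= threshold), defined = TRUE),
            class = "length_stats")
}

#' @export
print.length_stats <- function(x, ...) {
  if (!x$defined) {
    cat("Length stats: empty set (undefined)\n")
  } else {
    cat(sprintf("Length stats: n=%d, mean=%.2f nt, sd=%.2f nt, frac >= %d nt = %.3f\n",
                x$n, x$mean, x$sd, x$threshold, x$frac_ge))
  }
  invisible(x)
}

#' Compare the length distributions of two sequence sets
#'
#' Welch's unequal-variance two-sample t-test on per-sequence lengths,
#' two-tailed. Welch is the safer default when group sizes are very unequal
#' (a few hundred flagged sequences against a database of >100k).
#'
#' @param a,b Sequence sets (as in \code{\link{positional_composition}}).
#' @param name_a,name_b Labels used in error messages.
#' @return The \code{htest} object from \code{\link[stats]{t.test}}.
#' @export
compare_lengths <- function(a, b, name_a = "a", name_b = "b") {
  la <- nchar(get_seqs(a))
  lb <- nchar(get_seqs(b))
  if (length(la) < 2L) stop(sprintf("set '%s' has fewer than 2 sequences", name_a))
  if (length(lb) < 2L) stop(sprintf("set '%s' has fewer than 2 sequences", name_b))
  if (stats::var(la) == 0) stop(sprintf("set '%s' has zero length variance", name_a))
  if (stats::var(lb) == 0) stop(sprintf("set '%s' has zero length variance", name_b))
  stats::t.test(la, lb, var.equal = FALSE, alternative = "two.sided")
}
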