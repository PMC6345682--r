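# Amino-acid composition accounting for halophilic adaptation analysis:
# per-residue counts, query-vs-reference deltas, category summaries.

CATEGORY_SETS <- list(
  negative = c("D", "E"),
  positive = c("K", "R", "H"),
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W"),
  glycine = "G"
)

#' Count amino acids in a protein sequence
#'
#' @param sequence Protein sequence over the 20-letter alphabet; `X` is
#'   allowed and counted separately. Case-insensitive.
#' @return Named integer vector over the 20 amino acids plus `X`; counts sum
#'   to the sequence length.
#' @export
aa_counts <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  alphabet <- c(AA_ALPHABET, "X")
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    stop(sprintf("non-amino-acid character '%s' at position %d",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  counts <- table(factor(chars, levels = alphabet))
  stats::setNames(as.integer(counts), alphabet)
}

#' Composition difference between two sequences
#'
#' Per-amino-acid count differences (query minus reference), plus deltas for
#' the categories relevant to halophilic adaptation: negative (D, E),
#' positive (K, R, H), hydrophobic (A, V, L, I, M, F, W) and glycine.
#'
#' @param query_seq,reference_seq Protein sequences.
#' @param query_id,reference_id Labels for reporting.
#' @return An object of class `composition_delta` with fields `delta` (named
#'   integer vector), `category_deltas`, and the two ids. The deltas sum to
#'   the length difference.
#' @export
composition_delta <- function(query_seq, reference_seq,
                              query_id = "query", reference_id = "reference") {
  if (!nzchar(query_seq) || !nzchar(reference_seq)) {
    stop("both sequences must be non-empty", call. = FALSE)
  }
  d <- aa_counts(query_seq) - aa_counts(reference_seq)
  cats <- vapply(CATEGORY_SETS, function(set) sum(d[set]), integer(1))
  structure(
    list(query_id = query_id, reference_id = reference_id,
         delta = d, category_deltas = cats),
    class = "composition_delta"
  )
}

#' @export
print.composition_delta <- function(x, ...) {
  cat(sprintf("<composition_delta> %s - %s\n", x$query_id, x$reference_id))
  nz <- x$delta[x$delta != 0]
  if (length(nz)) {
    cat(paste(sprintf("  %s %+d", names(nz), nz), collapse = "\n"), "\n")
  }
  cat("  categories:",
      paste(sprintf("%s %+d", names(x$category_deltas), x$category_deltas),
            collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate composition deltas
#'
#' @param deltas A `composition_delta` or list of them.
#' @return data.frame with one row per amino acid and delta (one column per
#'   query), ordered by one-letter code, plus a `direction` annotation
#'   (increase / decrease / equal) for the first delta.
#' @export
composition_report <- function(deltas) {
  if (inherits(deltas, "composition_delta")) deltas <- list(deltas)
  if (!length(deltas)) stop("at least one composition delta required", call. = FALSE)
  aa <- c(AA_ALPHABET, "X")
  out <- data.frame(aa = aa, stringsAsFactors = FALSE)
  for (d in deltas) {
    out[[paste0(d$query_id, "_vs_", d$reference_id)]] <- as.integer(d$delta[aa])
  }
  first <- deltas[[1]]$delta[aa]
  out$direction <- ifelse(first > 0, "increase",
                          ifelse(first < 0, "decrease", "equal"))
  out
}
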