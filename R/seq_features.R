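# Sequence-level features: protein motif scanning (e.g. the Xi-class CPWA /
# CP[WFY][AS] catalytic motif), annotation transfer across an MSA (catalytic
# Cys, tyrosine triad), restriction-site scanning of cloning primers, and
# ORF translation.

#' Scan a protein sequence for a class-based motif
#'
#' Patterns use literal residues and bracketed residue classes, e.g.
#' `"CP[WFY][AS]"`. All occurrences (including overlapping ones) are
#' returned with 1-based start positions; matching is case-insensitive.
#'
#' @param sequence Protein sequence.
#' @param pattern Motif pattern.
#' @param sequence_id Label for reporting.
#' @param offset Integer added to reported positions, for numbering tagged
#'   constructs against the native sequence (default 0).
#' @return data.frame: sequence_id, pattern, start, match.
#' @export
scan_protein_motif <- function(sequence, pattern, sequence_id = "seq",
                               offset = 0) {
  if (!grepl("^(\\[[A-Za-z]+\\]|[A-Za-z])+$", pattern)) {
    stop("malformed motif pattern: '", pattern, "'", call. = FALSE)
  }
  seq_u <- toupper(sequence)
  rx <- paste0("(?=(", toupper(pattern), "))")
  m <- gregexpr(rx, seq_u, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(sequence_id = character(), pattern = character(),
                      start = integer(), match = character(),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  lens <- attr(m, "capture.length")[, 1]
  data.frame(
    sequence_id = sequence_id, pattern = pattern,
    start = starts + offset,
    match = substring(seq_u, starts, starts + lens - 1),
    stringsAsFactors = FALSE
  )
}

#' Read an alignment (aligned FASTA or Clustal)
#'
#' @param path Alignment file path.
#' @param format `"auto"` (default), `"fasta"` or `"clustal"`.
#' @return Named character vector of equal-length aligned sequences.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(startsWith(lines, ">"))) "fasta" else "clustal"
  }
  if (format == "fasta") {
    msa <- read_fasta(path)
  } else {
    body <- lines[!grepl("^(CLUSTAL|MUSCLE)", lines)]
    body <- body[grepl("^\\S+\\s+\\S+", body) & !grepl("^\\s", body)]
    parts <- regmatches(body, regexec("^(\\S+)\\s+([A-Za-z.\\-]+)\\s*\\d*$", body))
    parts <- parts[vapply(parts, length, 1L) == 3]
    ids <- vapply(parts, `[`, "", 2)
    segs <- vapply(parts, `[`, "", 3)
    msa <- vapply(split(segs, factor(ids, levels = unique(ids))),
                  paste, "", collapse = "")
  }
  if (length(unique(nchar(msa))) > 1) {
    stop("aligned sequences have unequal lengths", call. = FALSE)
  }
  msa
}

#' Transfer reference positions across an alignment
#'
#' Maps 1-based ungapped positions in a reference sequence (e.g. the
#' catalytic Cys or the tyrosine triad) onto every other sequence via shared
#' alignment columns. The residue found at each mapped position is reported
#' verbatim; targets with a gap at the column are flagged.
#'
#' @param msa Named character vector of aligned sequences.
#' @param reference_id Name of the reference sequence in `msa`.
#' @param positions Integer vector of ungapped reference positions.
#' @return data.frame: target_id, ref_position, ref_residue, column,
#'   mapped_position (NA when gapped), mapped_residue, gapped.
#' @export
transfer_annotations <- function(msa, reference_id, positions) {
  if (!reference_id %in% names(msa)) {
    stop("reference '", reference_id, "' absent from alignment", call. = FALSE)
  }
  ref <- strsplit(msa[[reference_id]], "")[[1]]
  ref_upos <- cumsum(ref != "-" & ref != ".")
  cols <- vapply(positions, function(p) {
    cl <- which(ref_upos == p & ref != "-" & ref != ".")[1]
    if (is.na(cl)) stop("position ", p, " beyond reference length", call. = FALSE)
    cl
  }, integer(1))

  out <- do.call(rbind, lapply(setdiff(names(msa), reference_id), function(id) {
    tgt <- strsplit(msa[[id]], "")[[1]]
    tgt_upos <- cumsum(tgt != "-" & tgt != ".")
    gapped <- tgt[cols] %in% c("-", ".")
    data.frame(
      target_id = id, ref_position = positions, ref_residue = ref[cols],
      column = cols,
      mapped_position = ifelse(gapped, NA_integer_, tgt_upos[cols]),
      mapped_residue = ifelse(gapped, NA_character_, tgt[cols]),
      gapped = gapped, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Scan DNA for restriction sites
#'
#' Forward-strand scan with IUPAC ambiguity expansion; offsets are 0-based so
#' they feed directly into sequence slicing.
#'
#' @param dna DNA sequence over the IUPAC alphabet (case-insensitive; query
#'   must be A/C/G/T/N).
#' @param enzymes Named character vector or list, enzyme name -> IUPAC
#'   recognition pattern (e.g. `c(BamHI = "GGATCC", BspHI = "TCATGA")`).
#' @return data.frame: enzyme, pattern, offset (0-based), strand.
#' @export
scan_restriction_sites <- function(dna, enzymes) {
  dna_u <- toupper(dna)
  chars <- strsplit(dna_u, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop(sprintf("invalid base '%s' at position %d", chars[bad[1]], bad[1]),
         call. = FALSE)
  }
  rows <- lapply(names(enzymes), function(nm) {
    pat <- toupper(enzymes[[nm]])
    pchars <- strsplit(pat, "")[[1]]
    if (!all(pchars %in% names(IUPAC_DNA))) {
      stop("invalid IUPAC pattern for ", nm, ": ", pat, call. = FALSE)
    }
    rx <- paste0("(?=", paste(vapply(pchars, function(ch) {
      set <- IUPAC_DNA[[ch]]
      if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
    }, ""), collapse = ""), ")")
    m <- gregexpr(rx, dna_u, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(enzyme = nm, pattern = pat, offset = as.integer(m) - 1L,
               strand = "+", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(enzyme = character(), pattern = character(),
                      offset = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Translate an open reading frame
#'
#' Standard genetic code. The sequence length must be divisible by 3; a
#' terminal stop codon ends the translation (so a stop-terminated ORF of
#' n nucleotides yields n/3 - 1 amino acids); an internal stop is an error.
#' A non-ATG start only warns.
#'
#' @param dna DNA sequence (case-insensitive).
#' @return Protein sequence string.
#' @export
translate_orf <- function(dna) {
  dna_u <- gsub("U", "T", toupper(dna))
  n <- nchar(dna_u)
  if (n %% 3 != 0) {
    stop("ORF length ", n, " is not divisible by 3", call. = FALSE)
  }
  codons <- substring(dna_u, seq(1, n, 3), seq(3, n, 3))
  if (codons[1] != "ATG") warning("ORF does not start with ATG", call. = FALSE)
  aa <- GENETIC_CODE_TABLE[codons]
  if (any(is.na(aa))) {
    stop("untranslatable codon '", codons[which(is.na(aa))[1]], "' at codon ",
         which(is.na(aa))[1], call. = FALSE)
  }
  stops <- which(aa == "*")
  if (length(stops)) {
    if (stops[1] < length(codons)) {
      stop("internal stop codon at codon ", stops[1], call. = FALSE)
    }
    aa <- aa[-length(aa)]
  } else {
    warning("ORF has no terminal stop codon", call. = FALSE)
  }
  paste(aa, collapse = "")
}

#' Reverse-complement a DNA sequence
#' @param dna DNA string.
#' @return Reverse complement string (uppercase).
#' @export
reverse_complement <- function(dna) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(dna), "")[[1]]]), collapse = "")
}

# ---- FASTA helpers ------------------------------------------------------

#' Read a FASTA file into a named character vector
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  stats::setNames(gsub("\\s", "", seqs), ids)
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  out <- unlist(lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    c(paste0(">", id),
      substring(s, seq(1, nchar(s), width),
                pmin(nchar(s), seq(width, nchar(s) + width - 1, width))))
  }))
  writeLines(out, path)
  invisible(path)
}
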