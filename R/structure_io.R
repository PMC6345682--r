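# PDB-format structure model: fixed-column parsing and writing, SEQRES
# bookkeeping, missing-residue accounting, sequence extraction.
#
# The model is deliberately tolerant of His-tag constructs: author residue
# numbers may be negative (e.g. the tag initiator Met(-6)) and ordering is
# always by (resseq, icode) with a blank insertion code sorting first.

#' Construct a structure model
#'
#' Low-level constructor used by [read_structure()] and the synthetic fixture
#' generators. `atom` holds protein (ATOM) records after altloc resolution;
#' `het` holds HETATM ligand/solvent records kept apart from the polymer.
#'
#' @param id Entry code string.
#' @param atom data.frame with columns serial, name, altloc, resname, chain,
#'   resseq, icode, x, y, z, occupancy, bfactor, element.
#' @param het data.frame with the same columns for HETATM records (may be
#'   empty).
#' @param seqres Named list, chain id -> character vector of 3-letter codes.
#' @param cell Named numeric vector (a, b, c, alpha, beta, gamma) or `NULL`.
#' @param space_group Space-group symbol or `NULL`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(id, atom, het = empty_atom_frame(),
                            seqres = list(), cell = NULL, space_group = NULL) {
  atom <- as.data.frame(atom)
  het <- as.data.frame(het)
  stopifnot(all(c("name", "resname", "chain", "resseq", "x", "y", "z") %in% names(atom)))
  if (!all(is.finite(c(atom$x, atom$y, atom$z)))) {
    stop("non-finite coordinates in atom table", call. = FALSE)
  }
  if (!is.null(cell)) {
    cell <- cell[c("a", "b", "c", "alpha", "beta", "gamma")]
    if (any(!is.finite(cell)) || any(cell[1:3] <= 0) ||
        any(cell[4:6] <= 0) || any(cell[4:6] >= 180)) {
      stop("invalid unit cell: lengths must be positive, angles in (0, 180)",
           call. = FALSE)
    }
  }
  structure(
    list(id = id, atom = atom, het = het, seqres = seqres,
         cell = cell, space_group = space_group),
    class = "structure_model"
  )
}

empty_atom_frame <- function() {
  data.frame(
    serial = integer(), name = character(), altloc = character(),
    resname = character(), chain = character(), resseq = integer(),
    icode = character(), x = numeric(), y = numeric(), z = numeric(),
    occupancy = numeric(), bfactor = numeric(), element = character(),
    stringsAsFactors = FALSE
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model '%s'>\n", x$id))
  cat(sprintf("  chains: %s\n", paste(chain_ids(x), collapse = ", ")))
  cat(sprintf("  protein atoms: %d, het atoms: %d\n", nrow(x$atom), nrow(x$het)))
  if (!is.null(x$cell)) {
    cat(sprintf("  cell: a=%.1f b=%.1f c=%.1f alpha=%.1f beta=%.1f gamma=%.1f\n",
                x$cell["a"], x$cell["b"], x$cell["c"],
                x$cell["alpha"], x$cell["beta"], x$cell["gamma"]))
  }
  invisible(x)
}

#' Chain identifiers of a structure
#' @param struct A `structure_model`.
#' @return Character vector of chain ids (protein chains, in file order).
#' @export
chain_ids <- function(struct) unique(struct$atom$chain)

parse_num <- function(s, line_no, what, default = NA_real_) {
  s <- trimws(s)
  if (s == "") return(default)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) {
    stop(sprintf("malformed %s field on line %d: '%s'", what, line_no, s),
         call. = FALSE)
  }
  v
}

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM/SEQRES/CRYST1/TER records from fixed-column PDB text.
#' Negative author residue numbers (His-tag numbering such as Met(-6)) are
#' first-class. Alternate locations are resolved per atom: the conformer with
#' the highest occupancy wins, ties broken by the lexicographically smallest
#' altloc id. HETATM records (waters, ligands) are kept in a separate table
#' and excluded from sequences and superpositions.
#'
#' @param x Path to a PDB file, or PDB content as a single string / character
#'   vector of lines.
#' @param id Entry code to record; defaults to the file base name or "XXXX".
#' @return A [structure_model()].
#' @export
read_structure <- function(x, id = NULL) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    if (is.null(id)) id <- toupper(sub("\\.(pdb|ent)$", "", basename(x)))
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (is.null(id)) id <- "XXXX"

  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records: empty structure", call. = FALSE)

  idx <- which(is_atom)
  ln <- lines[idx]
  f <- function(a, b) substr(ln, a, b)
  serial <- suppressWarnings(as.integer(trimws(f(7, 11))))
  name <- trimws(f(13, 16))
  altloc <- trimws(f(17, 17))
  resname <- trimws(f(18, 20))
  chain <- f(22, 22)
  resseq <- suppressWarnings(as.integer(trimws(f(23, 26))))
  icode <- trimws(f(27, 27))
  xyz_txt <- cbind(f(31, 38), f(39, 46), f(47, 54))
  occ_txt <- f(55, 60)
  b_txt <- f(61, 66)
  element <- trimws(f(77, 78))

  bad <- which(is.na(resseq) | name == "" | resname == "")
  if (length(bad)) {
    stop(sprintf("malformed fixed-column record on line %d: '%s'",
                 idx[bad[1]], lines[idx[bad[1]]]), call. = FALSE)
  }
  xyz <- suppressWarnings(apply(xyz_txt, 2, function(col) as.numeric(trimws(col))))
  xyz <- matrix(xyz, ncol = 3)
  badc <- which(!is.finite(xyz[, 1]) | !is.finite(xyz[, 2]) | !is.finite(xyz[, 3]))
  if (length(badc)) {
    stop(sprintf("malformed coordinate field on line %d: '%s'",
                 idx[badc[1]], lines[idx[badc[1]]]), call. = FALSE)
  }
  occupancy <- vapply(seq_along(ln), function(i)
    parse_num(occ_txt[i], idx[i], "occupancy", default = 1), numeric(1))
  bfactor <- vapply(seq_along(ln), function(i)
    parse_num(b_txt[i], idx[i], "B-factor", default = 0), numeric(1))
  if (any(occupancy < 0 | occupancy > 1)) {
    j <- which(occupancy < 0 | occupancy > 1)[1]
    stop(sprintf("occupancy outside [0, 1] on line %d", idx[j]), call. = FALSE)
  }
  # fall back on the atom name's leading letter when the element column is blank
  blank_el <- element == ""
  element[blank_el] <- substr(gsub("[^A-Za-z].*$", "", name[blank_el]), 1, 1)

  atoms <- data.frame(
    serial = serial, name = name, altloc = altloc, resname = resname,
    chain = chain, resseq = resseq, icode = icode,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = occupancy, bfactor = bfactor, element = element,
    het = rec[is_atom] == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- resolve_altloc(atoms)

  het <- atoms[atoms$het, setdiff(names(atoms), "het"), drop = FALSE]
  prot <- atoms[!atoms$het, setdiff(names(atoms), "het"), drop = FALSE]
  rownames(het) <- rownames(prot) <- NULL

  seqres <- parse_seqres(lines)
  cr <- parse_cryst1(lines)

  structure_model(id = id, atom = prot, het = het, seqres = seqres,
                  cell = cr$cell, space_group = cr$space_group)
}

resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, atoms$het)
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(ix) {
    if (length(ix) == 1) return(ix)
    sub <- atoms[ix, ]
    best <- ix[order(-sub$occupancy, sub$altloc)][1]
    best
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

parse_seqres <- function(lines) {
  sr <- lines[substr(lines, 1, 6) == "SEQRES"]
  if (!length(sr)) return(list())
  chains <- substr(sr, 12, 12)
  out <- lapply(split(sr, chains), function(block) {
    toks <- unlist(strsplit(trimws(substr(block, 20, 70)), "\\s+"))
    toks[toks != ""]
  })
  out
}

parse_cryst1 <- function(lines) {
  cl <- lines[substr(lines, 1, 6) == "CRYST1"]
  if (!length(cl)) return(NULL)
  cl <- cl[1]
  vals <- c(
    a = parse_num(substr(cl, 7, 15), 0, "cell a"),
    b = parse_num(substr(cl, 16, 24), 0, "cell b"),
    c = parse_num(substr(cl, 25, 33), 0, "cell c"),
    alpha = parse_num(substr(cl, 34, 40), 0, "cell alpha"),
    beta = parse_num(substr(cl, 41, 47), 0, "cell beta"),
    gamma = parse_num(substr(cl, 48, 54), 0, "cell gamma")
  )
  sg <- trimws(substr(cl, 56, 66))
  list(cell = vals, space_group = if (nzchar(sg)) sg else NULL)
}

#' Write a structure in PDB format
#'
#' Emits SEQRES, CRYST1, ATOM/HETATM, TER and END records with fixed columns.
#' Coordinates are written to 3 decimals; a read/write round trip preserves
#' names, numbering, coordinates, occupancies and B-factors.
#'
#' @param struct A [structure_model()].
#' @param path Output file path, or `NULL` to return the text invisibly.
#' @return The PDB text, invisibly.
#' @export
write_structure <- function(struct, path = NULL) {
  out <- character(0)
  if (!is.null(struct$cell)) {
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                          struct$cell["a"], struct$cell["b"], struct$cell["c"],
                          struct$cell["alpha"], struct$cell["beta"],
                          struct$cell["gamma"],
                          if (is.null(struct$space_group)) "P 1" else struct$space_group))
  }
  for (ch in names(struct$seqres)) {
    res <- struct$seqres[[ch]]
    n <- length(res)
    rows <- split(res, ceiling(seq_along(res) / 13))
    for (k in seq_along(rows)) {
      out <- c(out, sprintf("SEQRES %3d %s %4d  %s", k, ch, n,
                            paste(sprintf("%-3s", rows[[k]]), collapse = " ")))
    }
  }
  fmt_atom <- function(df, record) {
    sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, df$serial, format_atom_name(df$name, df$element), df$altloc,
            df$resname, df$chain, df$resseq, df$icode,
            df$x, df$y, df$z, df$occupancy, df$bfactor,
            toupper(df$element))
  }
  a <- struct$atom
  if (nrow(a)) {
    for (ch in chain_ids(struct)) {
      sub <- a[a$chain == ch, , drop = FALSE]
      out <- c(out, fmt_atom(sub, "ATOM"))
      last <- sub[nrow(sub), ]
      out <- c(out, sprintf("TER   %5d      %-3s %1s%4d%1s",
                            last$serial + 1L, last$resname, last$chain,
                            last$resseq, last$icode))
    }
  }
  if (nrow(struct$het)) out <- c(out, fmt_atom(struct$het, "HETATM"))
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(out, path)
  invisible(txt)
}

# PDB atom-name column convention: names start in column 14 unless the
# element symbol is two letters or the name is 4 characters long.
format_atom_name <- function(name, element) {
  vapply(seq_along(name), function(i) {
    nm <- name[i]
    if (nchar(nm) >= 4 || nchar(element[i]) == 2) {
      sprintf("%-4s", nm)
    } else {
      sprintf(" %-3s", nm)
    }
  }, character(1))
}

#' Modeled residues of a chain
#'
#' @param struct A [structure_model()].
#' @param chain Chain id.
#' @return data.frame with one row per modeled residue (resseq, icode,
#'   resname), ordered by (resseq, icode) with blank insertion codes first.
#' @export
modeled_residues <- function(struct, chain) {
  a <- struct$atom[struct$atom$chain == chain, , drop = FALSE]
  if (!nrow(a)) stop("no such chain: ", chain, call. = FALSE)
  key <- !duplicated(paste(a$resseq, a$icode))
  res <- a[key, c("resseq", "icode", "resname")]
  res <- res[order(res$resseq, res$icode), ]
  rownames(res) <- NULL
  res
}

#' Identify unmodeled (missing) residues of a chain
#'
#' Compares the deposited SEQRES sequence with the residues actually present
#' in the coordinates and reports each maximal run of unmodeled SEQRES
#' positions, tagged by location. The modeled sequence is embedded into the
#' SEQRES sequence greedily left-to-right; when sequence repeats make the
#' embedding ambiguous the leftmost embedding is used.
#'
#' @param struct A [structure_model()].
#' @param chain Chain id.
#' @return data.frame with columns start, end (1-based SEQRES positions),
#'   length, location (`"N-terminal"`, `"internal"`, `"C-terminal"`).
#' @export
missing_residues <- function(struct, chain) {
  seqres <- struct$seqres[[chain]]
  if (is.null(seqres) || !length(seqres)) {
    stop("missing_residues is not computable: chain ", chain,
         " has no SEQRES record", call. = FALSE)
  }
  sr1 <- three_to_one(seqres, warn = FALSE)
  mod <- modeled_residues(struct, chain)
  md1 <- three_to_one(mod$resname, warn = FALSE)

  matched <- logical(length(sr1))
  j <- 1L
  for (i in seq_along(md1)) {
    while (j <= length(sr1) && sr1[j] != md1[i]) j <- j + 1L
    if (j > length(sr1)) {
      stop("modeled sequence of chain ", chain,
           " cannot be embedded in its SEQRES sequence", call. = FALSE)
    }
    matched[j] <- TRUE
    j <- j + 1L
  }

  gaps <- rle(!matched)
  ends <- cumsum(gaps$lengths)
  starts <- ends - gaps$lengths + 1L
  keep <- gaps$values
  if (!any(keep)) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      location = character(), stringsAsFactors = FALSE))
  }
  st <- starts[keep]; en <- ends[keep]
  loc <- ifelse(st == 1L, "N-terminal",
                ifelse(en == length(sr1), "C-terminal", "internal"))
  data.frame(start = st, end = en, length = en - st + 1L, location = loc,
             stringsAsFactors = FALSE)
}

#' One-letter sequence of a chain
#'
#' @param struct A [structure_model()].
#' @param chain Chain id.
#' @param source `"seqres"` for the deposited construct sequence, `"modeled"`
#'   for the residues present in the coordinates.
#' @return One-letter sequence string; unknown 3-letter codes become `"X"`
#'   with a warning.
#' @export
chain_sequence <- function(struct, chain, source = c("modeled", "seqres")) {
  source <- match.arg(source)
  if (source == "seqres") {
    seqres <- struct$seqres[[chain]]
    if (is.null(seqres)) stop("chain ", chain, " has no SEQRES record", call. = FALSE)
    paste(three_to_one(seqres), collapse = "")
  } else {
    paste(three_to_one(modeled_residues(struct, chain)$resname), collapse = "")
  }
}

#' Normalize a PDB entry code
#'
#' Entry codes are case-insensitive; the letter "O" is corrected to the digit
#' "0" (print typography such as "4GOI" for the deposition 4G0I), with a
#' message logging the normalization.
#'
#' @param code Entry code string.
#' @return Normalized 4-character code.
#' @export
normalize_entry_code <- function(code) {
  up <- toupper(trimws(code))
  fixed <- paste0(substr(up, 1, 1), gsub("O", "0", substr(up, 2, nchar(up))))
  if (!identical(fixed, up)) {
    message(sprintf("entry code '%s' normalized to '%s' (letter O -> digit 0)",
                    code, fixed))
  }
  fixed
}
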