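# Shared lookup tables: residue codes, vdW radii, reference SASA maxima,
# genetic code, IUPAC nucleotide classes.

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O"
)

AA1_TO_3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

AMINO_ACIDS <- unname(AA1_TO_3[order(names(AA1_TO_3))])
AA_ALPHABET <- sort(names(AA1_TO_3))

# van der Waals radii (Angstrom); C/N/O/S values are the classic Bondi-style
# set used by most SASA implementations.
VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  H = 1.20, P = 1.80, SE = 1.90, F = 1.47,
  CL = 1.75, BR = 1.85, I = 1.98
)

# Theoretical maximum residue SASA (Angstrom^2), Gly-X-Gly tripeptide scale
# (Tien et al. 2013, "theoretical" column). Used for relative accessibility.
MAX_SASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

# Standard genetic code, codon -> one-letter amino acid ("*" = stop).
GENETIC_CODE_TABLE <- {
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16), rep(rep(bases, each = 4), 4), rep(bases, 16))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  stats::setNames(aas, codons)
}

# IUPAC nucleotide ambiguity codes -> base sets (DNA).
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Side-chain charge model for the simplified Coulomb surface: full negative
# charge on Asp/Glu, full positive on Lys/Arg, fractional on His.
RESIDUE_CHARGES <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1, HIS = 0.1)

#' Look up a van der Waals radius by element symbol
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @param fallback Radius in Angstrom used for unknown elements, or `NULL`
#'   (the default) to raise an error on an unknown element.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element, fallback = NULL) {
  el <- toupper(trimws(element))
  r <- VDW_RADII[el]
  miss <- is.na(r)
  if (any(miss)) {
    if (is.null(fallback)) {
      stop("no van der Waals radius for element(s): ",
           paste(unique(el[miss]), collapse = ", "), call. = FALSE)
    }
    r[miss] <- fallback
  }
  unname(r)
}

three_to_one <- function(resnames, warn = TRUE) {
  out <- AA3_TO_1[toupper(resnames)]
  unknown <- is.na(out)
  if (any(unknown)) {
    if (warn) {
      warning("unknown residue code(s) mapped to 'X': ",
              paste(unique(toupper(resnames[unknown])), collapse = ", "),
              call. = FALSE)
    }
    out[unknown] <- "X"
  }
  unname(out)
}
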