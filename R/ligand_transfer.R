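# Homology-based ligand transplantation: superpose an apo target onto a holo
# reference, carry the ligand across in the reference-to-target transform,
# optionally truncate glutathione to gamma-glutamyl-cysteine by deleting the
# glycyl moiety, then measure site distances and steric clashes.

GLYCYL_ATOMS <- c("N3", "CA3", "C3", "O31", "O32")

#' Transplant a ligand from a holo reference into a target structure
#'
#' Applies a superposition transform (mapping the reference frame onto the
#' target frame, e.g. from `superpose_monomer(reference, ., target, .)`) to
#' the ligand's HETATM coordinates. Being rigid, the transplant preserves all
#' internal inter-atom distances.
#'
#' @param target,reference [structure_model()] objects.
#' @param ligand_resname HETATM residue name of the ligand (e.g. `"GSH"`).
#' @param superposition A `superposition_result` mapping reference onto
#'   target.
#' @param selector Optional list(chain =, resseq =) picking one copy when the
#'   reference holds several.
#' @return An object of class `transplanted_ligand`: `atoms` (ligand atoms in
#'   the target frame), `source_entry`, `transform`, `edits` (deleted atom
#'   names, initially empty).
#' @export
transplant_ligand <- function(target, reference, ligand_resname, superposition,
                              selector = NULL) {
  h <- reference$het
  lig <- h[h$resname == ligand_resname, , drop = FALSE]
  if (!nrow(lig)) {
    stop("ligand '", ligand_resname, "' not found in ", reference$id, call. = FALSE)
  }
  copies <- unique(paste(lig$chain, lig$resseq, lig$icode, sep = ":"))
  if (length(copies) > 1) {
    if (is.null(selector)) {
      stop("multiple '", ligand_resname, "' copies in ", reference$id,
           "; pass selector = list(chain=, resseq=). Candidates: ",
           paste(copies, collapse = ", "), call. = FALSE)
    }
    lig <- lig[lig$chain == selector$chain & lig$resseq == selector$resseq, ,
               drop = FALSE]
    if (!nrow(lig)) stop("selector matches no ligand copy", call. = FALSE)
  }
  xyz <- apply_transform(as.matrix(lig[, c("x", "y", "z")]),
                         superposition$rotation, superposition$translation)
  lig$x <- xyz[, 1]; lig$y <- xyz[, 2]; lig$z <- xyz[, 3]
  rownames(lig) <- NULL
  structure(
    list(atoms = lig, source_entry = reference$id,
         transform = list(rotation = superposition$rotation,
                          translation = superposition$translation),
         edits = character(0)),
    class = "transplanted_ligand"
  )
}

#' Truncate glutathione to gamma-glutamyl-cysteine
#'
#' Deletes the five glycyl-moiety heavy atoms (N3, CA3, C3, O31, O32) of a
#' GSH ligand following the chemical-component atom naming convention, as
#' halophilic archaea use gamma-Glu-Cys in place of glutathione. No atoms are
#' rebuilt or renamed; surviving coordinates are untouched.
#'
#' @param ligand A `transplanted_ligand` carrying GSH-convention atom names.
#' @return The ligand with glycyl atoms removed and the edit log updated.
#' @export
truncate_gsh_to_gec <- function(ligand) {
  stopifnot(inherits(ligand, "transplanted_ligand"))
  present <- GLYCYL_ATOMS %in% ligand$atoms$name
  if (!all(present)) {
    stop("expected glycyl atoms absent: ",
         paste(GLYCYL_ATOMS[!present], collapse = ", "), call. = FALSE)
  }
  ligand$atoms <- ligand$atoms[!ligand$atoms$name %in% GLYCYL_ATOMS, , drop = FALSE]
  rownames(ligand$atoms) <- NULL
  ligand$edits <- c(ligand$edits, GLYCYL_ATOMS)
  ligand
}

# ---- selection mini-language -------------------------------------------
# Grammar: conjunction of clauses joined by "and":
#   chain <id> | resi <int> | name <atom name> | ligand
# "ligand" selects the transplanted ligand's atoms (requires `ligand=`).

select_atoms <- function(struct, expr, ligand = NULL) {
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  pool <- rbind(struct$atom, struct$het)
  use_ligand <- FALSE
  clauses <- list()
  i <- 1
  while (i <= length(toks)) {
    tk <- tolower(toks[i])
    if (tk == "and") { i <- i + 1; next }
    if (tk == "ligand") { use_ligand <- TRUE; i <- i + 1; next }
    if (i + 1 > length(toks)) {
      stop("malformed selection '", expr, "': keyword '", toks[i],
           "' needs a value", call. = FALSE)
    }
    val <- toks[i + 1]
    clauses[[length(clauses) + 1]] <- list(key = tk, value = val)
    i <- i + 2
  }
  if (use_ligand) {
    if (is.null(ligand)) {
      stop("selection '", expr, "' uses 'ligand' but no ligand was supplied",
           call. = FALSE)
    }
    pool <- ligand$atoms
  }
  keep <- rep(TRUE, nrow(pool))
  for (cl in clauses) {
    keep <- keep & switch(
      cl$key,
      chain = pool$chain == cl$value,
      resi = pool$resseq == as.integer(cl$value),
      name = pool$name == toupper(cl$value),
      stop("unknown selection keyword '", cl$key, "' in '", expr, "'",
           call. = FALSE)
    )
  }
  sel <- pool[keep, , drop = FALSE]
  if (!nrow(sel)) stop("empty selection: '", expr, "'", call. = FALSE)
  sel
}

#' Measure a distance between two atom selections
#'
#' Selections use a small conjunctive grammar:
#' `"chain A and resi 57 and name SG"`, `"ligand and name SG2"` (the `ligand`
#' keyword addresses a supplied [transplant_ligand()] result).
#'
#' @param struct A [structure_model()].
#' @param group_a,group_b Selection expressions.
#' @param mode `"min"` (minimum pairwise distance) or `"centroid"`.
#' @param ligand Optional `transplanted_ligand` for `ligand` selections.
#' @return An object of class `distance_measurement` with the selections,
#'   mode and `value` in Angstrom.
#' @export
measure_distance <- function(struct, group_a, group_b,
                             mode = c("min", "centroid"), ligand = NULL) {
  mode <- match.arg(mode)
  a <- select_atoms(struct, group_a, ligand)
  b <- select_atoms(struct, group_b, ligand)
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  value <- if (mode == "centroid") {
    sqrt(sum((colMeans(xa) - colMeans(xb))^2))
  } else {
    min(sqrt(pmax(outer(rowSums(xa^2), rep(1, nrow(xb))) +
                    outer(rep(1, nrow(xa)), rowSums(xb^2)) -
                    2 * xa %*% t(xb), 0)))
  }
  structure(
    list(group_a = group_a, group_b = group_b, mode = mode,
         value = max(value, 0)),
    class = "distance_measurement"
  )
}

#' Detect steric clashes between a transplanted ligand and the protein
#'
#' A ligand-protein atom pair clashes when its distance is strictly below the
#' sum of van der Waals radii minus a tolerance.
#'
#' @param ligand A `transplanted_ligand`.
#' @param struct A [structure_model()].
#' @param tolerance Steric tolerance in Angstrom (default 0.4).
#' @param radius_fallback vdW radius for unknown elements, or `NULL` to error.
#' @return data.frame sorted by `vdw_overlap` descending: ligand_atom,
#'   chain, resseq, resname, protein_atom, distance, vdw_overlap.
#' @export
detect_clashes <- function(ligand, struct, tolerance = 0.4,
                           radius_fallback = NULL) {
  la <- ligand$atoms
  pa <- struct$atom
  rl <- vdw_radius(la$element, fallback = radius_fallback)
  rp <- vdw_radius(pa$element, fallback = radius_fallback)
  xl <- as.matrix(la[, c("x", "y", "z")])
  xp <- as.matrix(pa[, c("x", "y", "z")])
  d2 <- outer(rowSums(xl^2), rep(1, nrow(xp))) +
    outer(rep(1, nrow(xl)), rowSums(xp^2)) - 2 * xl %*% t(xp)
  d <- sqrt(pmax(d2, 0))  # pmax(matrix, 0): matrix first, or dim is dropped
  lim <- outer(rl, rp, "+") - tolerance
  hit <- which(d < lim, arr.ind = TRUE)
  out <- data.frame(
    ligand_atom = la$name[hit[, 1]],
    chain = pa$chain[hit[, 2]], resseq = pa$resseq[hit[, 2]],
    resname = pa$resname[hit[, 2]], protein_atom = pa$name[hit[, 2]],
    distance = d[hit], vdw_overlap = (lim - d)[hit],
    stringsAsFactors = FALSE
  )
  out[order(-out$vdw_overlap), , drop = FALSE]
}
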