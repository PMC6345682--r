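# Sequence-alignment-driven rigid-body superposition.
#
# Pipeline: global sequence alignment (BLOSUM62, affine gaps) -> residue
# pairing -> Kabsch least-squares fit on paired C-alpha atoms -> iterative
# rejection of pairs deviating more than reject_factor * RMSD, as done by
# "align"-style structure comparison tools.

#' Globally align two protein sequences and derive a residue pairing
#'
#' Needleman-Wunsch global alignment with affine gap penalties (delegated to
#' Biostrings). Identity is computed over aligned non-gap columns.
#'
#' @param seq_a,seq_b Protein sequences (strings).
#' @param matrix Substitution matrix name (a matrix shipped with Biostrings,
#'   default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return An object of class `residue_pairing`: list with `pairs` (two-column
#'   integer matrix of 1-based positions in `seq_a`/`seq_b`),
#'   `identity_percent`, and `score`.
#' @export
align_sequences <- function(seq_a, seq_b, matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("align_sequences requires two non-empty sequences", call. = FALSE)
  }
  submat <- get_substitution_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global"
  )
  arow <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  brow <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ai <- cumsum(arow != "-")
  bi <- cumsum(brow != "-")
  both <- arow != "-" & brow != "-"
  pairs <- cbind(a = ai[both], b = bi[both])
  ident <- 100 * sum(arow[both] == brow[both]) / sum(both)
  structure(
    list(pairs = pairs, identity_percent = ident,
         score = Biostrings::score(pa),
         aligned_a = paste(arow, collapse = ""),
         aligned_b = paste(brow, collapse = "")),
    class = "residue_pairing"
  )
}

get_substitution_matrix <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e)) {
    stop("unknown substitution matrix: ", name, call. = FALSE)
  }
  get(name, envir = e)
}

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `coords_a %*% t(R) + t` against `coords_b`. The reflection branch of the
#' SVD solution is corrected so `det(R) = +1`.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (Angstrom), N >= 3,
#'   rows paired.
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`, and
#'   logical `degenerate` (near-collinear input flagged).
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b)) {
    stop("kabsch: point sets must have equal size", call. = FALSE)
  }
  if (nrow(coords_a) < 3) stop("kabsch requires at least 3 points", call. = FALSE)
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- as.numeric(cb - R %*% ca)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  list(rotation = R, translation = t_vec, rmsd = rmsd, degenerate = degenerate)
}

apply_transform <- function(coords, rotation, translation) {
  sweep(as.matrix(coords) %*% t(rotation), 2, -translation)
}

# Iterative fit with outlier rejection on an initial paired coordinate set.
refine_fit <- function(xa, xb, cycles, reject_factor) {
  keep <- rep(TRUE, nrow(xa))
  fit <- kabsch(xa, xb)
  for (k in seq_len(cycles)) {
    dev <- sqrt(rowSums((apply_transform(xa[keep, , drop = FALSE],
                                         fit$rotation, fit$translation) -
                           xb[keep, , drop = FALSE])^2))
    cut <- reject_factor * fit$rmsd
    drop_now <- dev > cut
    if (!any(drop_now)) break
    if (sum(keep) - sum(drop_now) < 3) break
    keep[which(keep)[drop_now]] <- FALSE
    fit <- kabsch(xa[keep, , drop = FALSE], xb[keep, , drop = FALSE])
  }
  list(fit = fit, keep = keep)
}

superposition_result <- function(fit, n_aligned, n_rejected, identity_percent) {
  structure(
    list(rotation = fit$rotation, translation = fit$translation,
         rmsd = fit$rmsd, n_aligned = n_aligned, n_rejected = n_rejected,
         identity_percent = identity_percent, degenerate = fit$degenerate),
    class = "superposition_result"
  )
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.3f A over %d pairs (%d rejected), identity %.2f%%\n",
              x$rmsd, x$n_aligned, x$n_rejected, x$identity_percent))
  invisible(x)
}

ca_table <- function(struct, chain) {
  a <- struct$atom
  ca <- a[a$chain == chain & a$name == "CA", , drop = FALSE]
  if (!nrow(ca)) stop("chain ", chain, " of ", struct$id, " has no CA atoms",
                      call. = FALSE)
  ca <- ca[order(ca$resseq, ca$icode), , drop = FALSE]
  ca
}

# Alignment-derived paired CA coordinates for one chain-to-chain match.
paired_ca <- function(struct_a, chain_a, struct_b, chain_b, ...) {
  ca_a <- ca_table(struct_a, chain_a)
  ca_b <- ca_table(struct_b, chain_b)
  seq_a <- paste(three_to_one(ca_a$resname, warn = FALSE), collapse = "")
  seq_b <- paste(three_to_one(ca_b$resname, warn = FALSE), collapse = "")
  pr <- align_sequences(seq_a, seq_b, ...)
  xa <- as.matrix(ca_a[pr$pairs[, "a"], c("x", "y", "z")])
  xb <- as.matrix(ca_b[pr$pairs[, "b"], c("x", "y", "z")])
  list(xa = xa, xb = xb, pairing = pr,
       n_ident = round(pr$identity_percent / 100 * nrow(pr$pairs)),
       n_cols = nrow(pr$pairs))
}

#' Superpose two monomers
#'
#' Aligns the modeled sequences of the two chains, pairs residues modeled
#' with a C-alpha atom, performs a Kabsch fit and then `cycles` rounds of
#' rejection of pairs deviating more than `reject_factor` times the current
#' RMSD. The transform maps chain `chain_a` of `struct_a` onto `chain_b` of
#' `struct_b`.
#'
#' @param struct_a,struct_b [structure_model()] objects.
#' @param chain_a,chain_b Chain ids.
#' @param cycles Maximum rejection cycles (default 5).
#' @param reject_factor Rejection threshold as a multiple of the current RMSD
#'   (default 2).
#' @param ... Passed to [align_sequences()].
#' @return A `superposition_result`: rotation, translation, `rmsd` (Angstrom),
#'   `n_aligned` C-alpha pairs used in the final cycle, `n_rejected`, and
#'   sequence `identity_percent`.
#' @export
superpose_monomer <- function(struct_a, chain_a, struct_b, chain_b,
                              cycles = 5, reject_factor = 2, ...) {
  p <- paired_ca(struct_a, chain_a, struct_b, chain_b, ...)
  if (nrow(p$xa) < 3) stop("fewer than 3 alignable CA pairs", call. = FALSE)
  r <- refine_fit(p$xa, p$xb, cycles, reject_factor)
  superposition_result(r$fit, sum(r$keep), sum(!r$keep),
                       p$pairing$identity_percent)
}

#' Superpose two dimers
#'
#' Both chain-to-chain pairings (`AB` onto `A'B'` and `AB` onto `B'A'`) are
#' evaluated as single concatenated C-alpha point sets; the pairing with the
#' lower final RMSD is reported. Residue pairing stays within each chain pair
#' (no inter-chain pairing).
#'
#' @inheritParams superpose_monomer
#' @param chains_a,chains_b Character vectors of two chain ids per structure.
#' @return A `superposition_result` for the best chain pairing, with a
#'   `chain_mapping` field recording it.
#' @export
superpose_dimer <- function(struct_a, chains_a, struct_b, chains_b,
                            cycles = 5, reject_factor = 2, ...) {
  stopifnot(length(chains_a) == 2, length(chains_b) == 2)
  candidates <- list(chains_b, rev(chains_b))
  best <- NULL
  for (cb in candidates) {
    p1 <- paired_ca(struct_a, chains_a[1], struct_b, cb[1], ...)
    p2 <- paired_ca(struct_a, chains_a[2], struct_b, cb[2], ...)
    xa <- rbind(p1$xa, p2$xa); xb <- rbind(p1$xb, p2$xb)
    if (nrow(xa) < 3) next
    r <- refine_fit(xa, xb, cycles, reject_factor)
    ident <- 100 * (p1$n_ident + p2$n_ident) / (p1$n_cols + p2$n_cols)
    res <- superposition_result(r$fit, sum(r$keep), sum(!r$keep), ident)
    res$chain_mapping <- stats::setNames(cb, chains_a)
    if (is.null(best) || res$rmsd < best$rmsd) best <- res
  }
  if (is.null(best)) stop("fewer than 3 alignable CA pairs in both pairings",
                          call. = FALSE)
  best
}
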