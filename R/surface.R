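# Solvent accessibility (Shrake-Rupley), surface-residue classification, a
# permutation test for the spatial evenness of charged surface residues, and
# a simplified Coulomb surface score standing in for full Poisson-Boltzmann
# electrostatics.

# Deterministic quasi-uniform unit-sphere point set (golden-section spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sphere-point SASA: each atom's accessible fraction is estimated on
#' a fixed deterministic point set placed on its solvent-expanded sphere and
#' tested against neighbouring atoms. Deterministic given `n_points`.
#'
#' @param struct A [structure_model()].
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param n_points Sphere test points per atom (default 960).
#' @param include_het Include HETATM atoms (default `FALSE`).
#' @param radius_fallback vdW radius for unknown elements, or `NULL` to error.
#' @return An object of class `sasa_result`: `atom` (per-atom SASA, Angstrom^2,
#'   alongside atom identifiers) and `residue` (per-residue total and relative
#'   SASA; relative = residue SASA / residue-type theoretical maximum, capped
#'   at 1).
#' @export
shrake_rupley <- function(struct, probe_radius = 1.4, n_points = 960,
                          include_het = FALSE, radius_fallback = NULL) {
  atoms <- struct$atom
  if (include_het && nrow(struct$het)) atoms <- rbind(atoms, struct$het)
  if (!nrow(atoms)) stop("structure has no atoms", call. = FALSE)
  radii <- vdw_radius(atoms$element, fallback = radius_fallback)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  expanded <- radii + probe_radius

  # neighbour candidates: pairwise distance below sum of expanded radii
  d2 <- as.matrix(stats::dist(xyz))^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    cutoff <- (expanded[i] + expanded)^2
    nb <- which(d2[i, ] < cutoff)
    nb <- nb[nb != i]
    p <- sweep(pts * expanded[i], 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      dj2 <- (p[accessible, 1] - xyz[j, 1])^2 +
        (p[accessible, 2] - xyz[j, 2])^2 +
        (p[accessible, 3] - xyz[j, 3])^2
      accessible[accessible] <- dj2 >= expanded[j]^2
    }
    sasa[i] <- 4 * pi * expanded[i]^2 * mean(accessible)
  }

  atom_tab <- data.frame(
    chain = atoms$chain, resseq = atoms$resseq, icode = atoms$icode,
    resname = atoms$resname, name = atoms$name, sasa = sasa,
    stringsAsFactors = FALSE
  )
  key <- paste(atom_tab$chain, atom_tab$resseq, atom_tab$icode, sep = ":")
  agg <- stats::aggregate(sasa ~ key, data = cbind(atom_tab, key = key), sum)
  first <- !duplicated(key)
  res_tab <- data.frame(
    residue_id = key[first], chain = atom_tab$chain[first],
    resseq = atom_tab$resseq[first], icode = atom_tab$icode[first],
    resname = atom_tab$resname[first], stringsAsFactors = FALSE
  )
  res_tab$sasa <- agg$sasa[match(res_tab$residue_id, agg$key)]
  mx <- MAX_SASA[res_tab$resname]
  res_tab$rel_sasa <- pmin(1, res_tab$sasa / ifelse(is.na(mx), max(MAX_SASA), mx))
  structure(
    list(atom = atom_tab, residue = res_tab,
         probe_radius = probe_radius, n_points = n_points),
    class = "sasa_result"
  )
}

#' Surface residues by relative accessibility
#'
#' @param sasa A `sasa_result`.
#' @param rel_threshold Relative SASA threshold (default 0.25); residues with
#'   relative SASA greater than or equal to the threshold are classified as
#'   surface.
#' @return Character vector of residue ids (`"chain:resseq:icode"`).
#' @export
surface_residues <- function(sasa, rel_threshold = 0.25) {
  sasa$residue$residue_id[sasa$residue$rel_sasa >= rel_threshold]
}

# Side-chain centroid per residue; falls back to all atoms of the residue
# when no side-chain atoms exist (Gly, CA-only models).
residue_centroids <- function(struct, residue_ids) {
  a <- struct$atom
  key <- paste(a$chain, a$resseq, a$icode, sep = ":")
  backbone <- c("N", "CA", "C", "O", "OXT")
  t(vapply(residue_ids, function(id) {
    rows <- a[key == id, , drop = FALSE]
    sc <- rows[!rows$name %in% backbone, , drop = FALSE]
    if (!nrow(sc)) sc <- rows
    c(mean(sc$x), mean(sc$y), mean(sc$z))
  }, numeric(3)))
}

#' Permutation test for evenness of charged surface residues
#'
#' Quantifies whether charged residues are spread evenly over the protein
#' surface or spatially clustered. The statistic is the mean nearest-neighbour
#' distance among side-chain centroids of charged surface residues; the null
#' distribution reassigns the charged labels uniformly at random among all
#' surface residues. Small statistics indicate clustering, so `p_clustered`
#' is the fraction of null samples less than or equal to the observed value.
#'
#' @param struct A [structure_model()].
#' @param sasa A `sasa_result` for the same structure.
#' @param charged_set Residue types treated as charged
#'   (default `c("ASP", "GLU")`, the acidic surface of halophilic proteins).
#' @param n_perm Number of permutations (must be >= 1).
#' @param seed Integer seed; results are reproducible bit-exactly given
#'   (seed, n_perm).
#' @param rel_threshold Surface threshold passed to [surface_residues()].
#' @return An object of class `evenness_report`: `statistic` (Angstrom),
#'   `null_distribution`, `p_clustered`, `n_charged_surface`, `n_surface`.
#' @export
charge_evenness <- function(struct, sasa, charged_set = c("ASP", "GLU"),
                            n_perm = 999, seed = 1, rel_threshold = 0.25) {
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  surf <- surface_residues(sasa, rel_threshold)
  res <- sasa$residue[match(surf, sasa$residue$residue_id), ]
  charged <- res$resname %in% charged_set
  n_charged <- sum(charged)
  if (n_charged < 2) {
    stop("charge evenness is not computable: fewer than 2 charged surface residues",
         call. = FALSE)
  }
  cent <- residue_centroids(struct, surf)
  dmat <- as.matrix(stats::dist(cent))
  diag(dmat) <- Inf

  mean_nn <- function(idx) {
    sub <- dmat[idx, idx, drop = FALSE]
    mean(apply(sub, 1, min))
  }
  obs <- mean_nn(which(charged))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(k) {
    mean_nn(sample(length(surf), n_charged))
  }, numeric(1))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  structure(
    list(statistic = obs, null_distribution = null,
         p_clustered = mean(null <= obs),
         n_charged_surface = n_charged, n_surface = length(surf)),
    class = "evenness_report"
  )
}

#' @export
print.evenness_report <- function(x, ...) {
  cat(sprintf(
    "<evenness_report> mean NN distance %.2f A among %d/%d charged surface residues; p(clustered) = %.4f\n",
    x$statistic, x$n_charged_surface, x$n_surface, x$p_clustered))
  invisible(x)
}

#' Simplified Coulomb surface potential score
#'
#' Qualitative stand-in for a Poisson-Boltzmann surface: each surface
#' residue's score is the unscreened Coulomb sum `q_j / d_ij` over all other
#' charged residues (side-chain centroids, distances in Angstrom, capped at
#' 1 Angstrom minimum). Charges: -1 for Asp/Glu, +1 for Lys/Arg, +0.1 for
#' His. The score is linear in the charge assignment; only the sign pattern
#' is meaningful.
#'
#' @param struct A [structure_model()].
#' @param sasa A `sasa_result`.
#' @param rel_threshold Surface threshold (default 0.25).
#' @return data.frame per surface residue: residue_id, resname, charge,
#'   coulomb_score.
#' @export
coulomb_surface <- function(struct, sasa, rel_threshold = 0.25) {
  surf <- surface_residues(sasa, rel_threshold)
  res <- sasa$residue[match(surf, sasa$residue$residue_id), ]
  all_res <- sasa$residue
  q_all <- unname(RESIDUE_CHARGES[all_res$resname])
  q_all[is.na(q_all)] <- 0
  cent_all <- residue_centroids(struct, all_res$residue_id)
  cent_surf <- cent_all[match(surf, all_res$residue_id), , drop = FALSE]

  score <- vapply(seq_along(surf), function(i) {
    d <- sqrt(rowSums(sweep(cent_all, 2, cent_surf[i, ])^2))
    d <- pmax(d, 1)
    self <- all_res$residue_id == surf[i]
    sum(q_all[!self] / d[!self])
  }, numeric(1))

  data.frame(
    residue_id = surf, resname = res$resname,
    charge = unname(ifelse(is.na(RESIDUE_CHARGES[res$resname]), 0,
                           RESIDUE_CHARGES[res$resname])),
    coulomb_score = score, stringsAsFactors = FALSE
  )
}
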