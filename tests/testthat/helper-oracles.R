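# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: brute-force enumeration for global alignment,
# closed-form spherical-cap geometry for SASA, ape as an external NJ/newick
# reference, and direct pairwise summation for the Coulomb field.

# ---- global alignment: exhaustive enumeration (affine gaps) -------------
# Enumerates every global alignment of two short sequences and returns the
# optimal score under BLOSUM62 with gap cost open + k * extend per gap run.
brute_force_alignment_score <- function(seq_a, seq_b, submat,
                                        gap_open = 10, gap_extend = 0.5) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  best <- -Inf
  score_ops <- function(ops) {
    i <- 0; j <- 0; s <- 0
    run <- ""  # current gap state: "", "I" (gap in b), "D" (gap in a)
    for (op in ops) {
      if (op == "M") {
        i <- i + 1; j <- j + 1
        s <- s + submat[a[i], b[j]]
        run <- ""
      } else if (op == "I") {
        i <- i + 1
        s <- s - gap_extend - if (run == "I") 0 else gap_open
        run <- "I"
      } else {
        j <- j + 1
        s <- s - gap_extend - if (run == "D") 0 else gap_open
        run <- "D"
      }
    }
    s
  }
  recurse <- function(i, j, ops) {
    if (i == length(a) && j == length(b)) {
      sc <- score_ops(ops)
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i < length(a) && j < length(b)) recurse(i + 1, j + 1, c(ops, "M"))
    if (i < length(a)) recurse(i + 1, j, c(ops, "I"))
    if (j < length(b)) recurse(i, j + 1, c(ops, "D"))
  }
  recurse(0, 0, character(0))
  best
}

# ---- SASA: closed-form two-sphere overlap -------------------------------
# Exact accessible area of expanded sphere 1 (radius r1) partially buried by
# expanded sphere 2 (radius r2) at centre distance d: full area minus the
# spherical cap hidden inside sphere 2.
two_sphere_sasa <- function(r1, r2, d) {
  full <- 4 * pi * r1^2
  if (d >= r1 + r2) return(full)
  if (d + r1 <= r2) return(0)
  h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  full - 2 * pi * r1 * h
}

# ---- structure fixture builders ----------------------------------------
ca_structure <- function(xyz, resnames, chain = "A", id = "FIX",
                         element = "C") {
  n <- nrow(xyz)
  structure_model(
    id = id,
    atom = data.frame(
      serial = seq_len(n), name = "CA", altloc = "", resname = resnames,
      chain = chain, resseq = seq_len(n), icode = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, bfactor = 0, element = element,
      stringsAsFactors = FALSE
    ),
    seqres = stats::setNames(list(resnames), chain)
  )
}

# n residues as isolated CA atoms on a sphere (radius 20 A): every residue
# fully solvent exposed, ideal for the charge-evenness null calibration.
sphere_residue_structure <- function(n, resnames, radius = 20) {
  pts <- halogst:::sphere_points(n) * radius
  ca_structure(pts, resnames, id = "SPHERE")
}

# hemisphere-clustered charge fixture: charged residues confined to z > 0
hemisphere_charge_structure <- function(n = 60, n_charged = 12, radius = 20) {
  pts <- halogst:::sphere_points(n) * radius
  resnames <- rep("SER", n)
  top <- order(pts[, 3], decreasing = TRUE)[seq_len(n_charged)]
  resnames[top] <- "ASP"
  ca_structure(pts, resnames, id = "HEMI")
}

# ---- misc ---------------------------------------------------------------
coords_of <- function(struct, chain = NULL) {
  a <- struct$atom
  if (!is.null(chain)) a <- a[a$chain == chain, ]
  as.matrix(a[, c("x", "y", "z")])
}

rotation_angle_deg <- function(R1, R2) {
  # angle of the relative rotation between two rotation matrices
  tr <- sum(diag(R1 %*% t(R2)))
  acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
}

random_orf <- function(n_nt, seed) {
  stopifnot(n_nt %% 3 == 0)
  halogst:::with_seed(seed, {
    n_codons <- n_nt / 3 - 2  # minus start and stop
    sense <- names(halogst:::GENETIC_CODE_TABLE)
    sense <- sense[halogst:::GENETIC_CODE_TABLE != "*" & sense != "ATG"]
    paste0("ATG", paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
           "TAA")
  })
}

# random additive tree + its exact leaf-to-leaf distance matrix (ape oracle)
random_additive_tree <- function(n_taxa, seed) {
  halogst:::with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
    tr
  })
}

# path to optional real deposition data (never shipped: requires downloads)
real_data_path <- function(file) {
  file.path(system.file("extdata", package = "halogst"), "real", file)
}
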