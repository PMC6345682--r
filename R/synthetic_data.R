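# Synthetic fixtures with planted ground truth: ideal helical CA traces,
# rigid-transformed noisy copies, a GSH-like tripeptide ligand, and sequence
# families evolved on a known tree. Everything is byte-reproducible from
# (parameters, seed) and emitted in the same containers the analysis modules
# consume.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Ideal alpha-helical CA-trace structure
#'
#' Builds a single-chain structure of CA atoms on an ideal alpha helix
#' (rise 1.5 Angstrom per residue, 100 degrees per residue, radius 2.3
#' Angstrom), giving consecutive CA-CA distances of ~3.8 Angstrom. Residue
#' types are drawn uniformly from the 20 amino acids under the seed; SEQRES
#' is filled to match.
#'
#' @param n_res Number of residues (>= 4).
#' @param seed Integer seed.
#' @param chain Chain id (default "A").
#' @param rise,twist_deg,radius Helix parameters (Angstrom, degrees,
#'   Angstrom).
#' @return A [structure_model()].
#' @export
make_helix_structure <- function(n_res, seed = 1, chain = "A",
                                 rise = 1.5, twist_deg = 100, radius = 2.3) {
  if (n_res < 4) stop("n_res must be at least 4", call. = FALSE)
  resnames <- with_seed(seed, sample(AMINO_ACIDS, n_res, replace = TRUE))
  i <- seq_len(n_res)
  theta <- (i - 1) * twist_deg * pi / 180
  atom <- data.frame(
    serial = i, name = "CA", altloc = "", resname = resnames,
    chain = chain, resseq = i, icode = "",
    x = radius * cos(theta), y = radius * sin(theta), z = (i - 1) * rise,
    occupancy = 1, bfactor = 0, element = "C",
    stringsAsFactors = FALSE
  )
  structure_model(id = sprintf("SYN-HELIX-%d-%d", n_res, seed), atom = atom,
                  seqres = stats::setNames(list(resnames), chain))
}

rotation_matrix <- function(angle_deg, axis) {
  axis <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  c_ <- cos(a); s <- sin(a); C <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(
    x * x * C + c_, x * y * C - z * s, x * z * C + y * s,
    y * x * C + z * s, y * y * C + c_, y * z * C - x * s,
    z * x * C - y * s, z * y * C + x * s, z * z * C + c_
  ), 3, 3, byrow = TRUE)
}

#' Rigidly transformed, optionally noisy copy of a structure
#'
#' Applies a planted rotation (about the given axis through the origin) and
#' translation to every atom, then adds iid Gaussian noise per coordinate.
#' The planted transform is recorded in the `planted` attribute for
#' parameter-recovery tests.
#'
#' @param struct A [structure_model()].
#' @param rotation_deg Rotation angle in degrees.
#' @param axis Rotation axis (length-3 vector).
#' @param translation Translation vector (Angstrom).
#' @param noise_sigma Gaussian noise sd per coordinate (Angstrom).
#' @param seed Integer seed for the noise.
#' @return A [structure_model()] with attribute `planted` = list(rotation,
#'   translation, noise_sigma).
#' @export
make_transformed_copy <- function(struct, rotation_deg = 0, axis = c(0, 0, 1),
                                  translation = c(0, 0, 0), noise_sigma = 0,
                                  seed = 1) {
  R <- rotation_matrix(rotation_deg, axis)
  transform_one <- function(df) {
    if (!nrow(df)) return(df)
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    xyz <- sweep(xyz, 2, translation, "+")
    if (noise_sigma > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sigma), ncol = 3)
    }
    df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
    df
  }
  out <- with_seed(seed, {
    atom <- transform_one(struct$atom)
    het <- transform_one(struct$het)
    structure_model(id = paste0(struct$id, "-T"), atom = atom, het = het,
                    seqres = struct$seqres, cell = struct$cell,
                    space_group = struct$space_group)
  })
  attr(out, "planted") <- list(rotation = R, translation = translation,
                               noise_sigma = noise_sigma)
  out
}

#' Two-chain (homodimer-like) helical fixture
#'
#' Chain A is an ideal helix; chain B is a copy rotated 180 degrees about x
#' and shifted, mimicking a symmetric dimer interface. Useful for the dimer
#' superposition pairing search.
#'
#' @param n_res Residues per chain.
#' @param seed Integer seed.
#' @param distinct If `TRUE`, chain B gets an independent random sequence and
#'   a slightly different helical geometry (heterodimer-like, so the two
#'   chains are distinguishable both by sequence and by shape); otherwise B
#'   is an exact rigid copy of A (homodimer).
#' @return A [structure_model()] with chains A and B.
#' @export
make_dimer_structure <- function(n_res = 40, seed = 1, distinct = FALSE) {
  a <- make_helix_structure(n_res, seed = seed, chain = "A")
  if (distinct) {
    b <- make_helix_structure(n_res, seed = seed + 1000L, chain = "B",
                              twist_deg = 97, radius = 2.6)
  } else {
    b <- a
  }
  R <- rotation_matrix(180, c(1, 0, 0))
  xyz <- as.matrix(b$atom[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, c(8, 0, 0), "+")
  b_atom <- b$atom
  b_atom$chain <- "B"
  b_atom$serial <- b_atom$serial + n_res
  b_atom$x <- xyz[, 1]; b_atom$y <- xyz[, 2]; b_atom$z <- xyz[, 3]
  structure_model(
    id = sprintf("SYN-DIMER-%d-%d", n_res, seed),
    atom = rbind(a$atom, b_atom),
    seqres = list(A = a$seqres[["A"]], B = b_atom$resname)
  )
}

# GSH heavy-atom topology (chemical-component naming): each atom placed at a
# plausible bond length (1.2-1.8 A) from its parent along the tripeptide
# graph. gamma-glutamyl: N1-CA1(-C1(-O11,O12))-CB1-CG1-CD1(-OE1);
# cysteinyl: N2-CA2(-C2(-O2))-CB2-SG2; glycyl: N3-CA3-C3(-O31,O32).
GSH_TOPOLOGY <- list(
  N1  = list(parent = NA,    pos = c(0, 0, 0)),
  CA1 = list(parent = "N1",  bond = 1.47),
  C1  = list(parent = "CA1", bond = 1.52, branch = c(0, 1.2, 0.6)),
  O11 = list(parent = "C1",  bond = 1.25, branch = c(0.3, 1.0, -0.4)),
  O12 = list(parent = "C1",  bond = 1.25, branch = c(-0.3, 1.0, 0.7)),
  CB1 = list(parent = "CA1", bond = 1.53, branch = c(0.2, -1.0, 0.5)),
  CG1 = list(parent = "CB1", bond = 1.53),
  CD1 = list(parent = "CG1", bond = 1.52),
  OE1 = list(parent = "CD1", bond = 1.23, branch = c(0, 1.1, -0.5)),
  N2  = list(parent = "CD1", bond = 1.33),
  CA2 = list(parent = "N2",  bond = 1.46),
  C2  = list(parent = "CA2", bond = 1.52),
  O2  = list(parent = "C2",  bond = 1.23, branch = c(0, 1.0, 0.6)),
  CB2 = list(parent = "CA2", bond = 1.53, branch = c(0.1, -1.1, -0.5)),
  SG2 = list(parent = "CB2", bond = 1.81, branch = c(0.4, -0.9, 0.8)),
  N3  = list(parent = "C2",  bond = 1.33),
  CA3 = list(parent = "N3",  bond = 1.46),
  C3  = list(parent = "CA3", bond = 1.52),
  O31 = list(parent = "C3",  bond = 1.25, branch = c(0.3, 1.0, -0.3)),
  O32 = list(parent = "C3",  bond = 1.25, branch = c(-0.2, 1.0, 0.6))
)

#' GSH-like tripeptide ligand fixture
#'
#' Builds the 20 heavy atoms of glutathione with chemical-component atom
#' names and chemically plausible bond lengths along the tripeptide graph,
#' plus a small seeded coordinate jitter. Drop-in input for
#' [truncate_gsh_to_gec()] and [detect_clashes()] tests.
#'
#' @param seed Integer seed for the jitter.
#' @param resname Ligand residue name (default "GSH").
#' @return HETATM-style data.frame of 20 atoms (chain "X", resseq 1).
#' @export
make_gsh_like_ligand <- function(seed = 1, resname = "GSH") {
  names_v <- names(GSH_TOPOLOGY)
  coords <- matrix(NA_real_, length(names_v), 3,
                   dimnames = list(names_v, NULL))
  main_dir <- c(1, 0.25, -0.15)
  main_dir <- main_dir / sqrt(sum(main_dir^2))
  flip <- 1
  for (nm in names_v) {
    spec <- GSH_TOPOLOGY[[nm]]
    if (is.na(spec$parent[1])) {
      coords[nm, ] <- spec$pos
      next
    }
    p <- coords[spec$parent, ]
    if (!is.null(spec$branch)) {
      dir <- spec$branch / sqrt(sum(spec$branch^2))
    } else {
      # zig-zag the main chain to avoid collinearity
      dir <- main_dir + flip * c(0, 0.45, 0.3)
      dir <- dir / sqrt(sum(dir^2))
      flip <- -flip
    }
    coords[nm, ] <- p + spec$bond * dir
  }
  jitter <- with_seed(seed, matrix(stats::rnorm(length(coords), 0, 0.01),
                                   ncol = 3))
  coords <- coords + jitter
  data.frame(
    serial = seq_along(names_v), name = names_v, altloc = "",
    resname = resname, chain = "X", resseq = 1L, icode = "",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1, bfactor = 0,
    element = substr(names_v, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Evolve a sequence family on a known tree
#'
#' A random root protein sequence is evolved along each branch of the given
#' tree: per column, a substitution to a uniformly chosen different residue
#' occurs with probability `min(subst_rate * branch_length, 0.75)`. Columns
#' evolve independently. The generating tree is returned with the alignment
#' so tree-recovery tests have their ground truth.
#'
#' @param tree An ape `phylo` object or newick string (>= 4 taxa, branch
#'   lengths required).
#' @param n_columns Alignment length.
#' @param subst_rate Substitution rate per unit branch length, in (0, 0.75].
#' @param seed Integer seed.
#' @return List with `msa` (named character vector, gap-free and aligned by
#'   construction) and `tree` (the generating `phylo`).
#' @export
make_sequence_family <- function(tree, n_columns, subst_rate, seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (length(tree$tip.label) < 4) stop("at least 4 taxa required", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths", call. = FALSE)
  if (subst_rate <= 0 || subst_rate > 0.75) {
    stop("subst_rate must be in (0, 0.75]", call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  with_seed(seed, {
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[root]] <- sample(AA_ALPHABET, n_columns, replace = TRUE)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      p_sub <- min(subst_rate * ord$edge.length[e], 0.75)
      s <- seqs[[parent]]
      mut <- stats::runif(n_columns) < p_sub
      if (any(mut)) {
        s[mut] <- vapply(s[mut], function(old) {
          sample(setdiff(AA_ALPHABET, old), 1)
        }, "")
      }
      seqs[[child]] <- s
    }
    msa <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""), "")
    names(msa) <- tree$tip.label
    list(msa = msa, tree = tree)
  })
}

#' Write a fixture bundle to disk
#'
#' Emits standard PDB/FASTA files plus a JSON-like metadata sidecar recording
#' the planted truth, so fixtures can be consumed unchanged by the other
#' modules and by external tools.
#'
#' @param kind One of "structure", "dimer", "ligand", "sequence_family".
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param ... Parameters forwarded to the matching generator.
#' @return Character vector of files written, invisibly.
#' @export
make_fixture <- function(kind = c("structure", "dimer", "ligand",
                                  "sequence_family"),
                         out_dir, seed = 1, ...) {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  meta <- list(kind = kind, seed = seed)
  if (kind == "structure") {
    s <- make_helix_structure(seed = seed, ...)
    f <- file.path(out_dir, paste0(tolower(s$id), ".pdb"))
    write_structure(s, f); files <- c(files, f)
  } else if (kind == "dimer") {
    s <- make_dimer_structure(seed = seed, ...)
    f <- file.path(out_dir, paste0(tolower(s$id), ".pdb"))
    write_structure(s, f); files <- c(files, f)
  } else if (kind == "ligand") {
    lig <- make_gsh_like_ligand(seed = seed, ...)
    s <- structure_model(id = "SYN-GSH", atom = empty_atom_frame(), het = lig)
    f <- file.path(out_dir, "syn-gsh.pdb")
    write_structure(s, f); files <- c(files, f)
  } else {
    fam <- make_sequence_family(seed = seed, ...)
    f1 <- file.path(out_dir, "family.fasta")
    write_fasta(fam$msa, f1)
    f2 <- file.path(out_dir, "family.nwk")
    writeLines(write_newick(fam$tree), f2)
    files <- c(files, f1, f2)
  }
  meta_file <- file.path(out_dir, paste0(kind, "-meta.txt"))
  writeLines(c(paste0("kind=", kind), paste0("seed=", seed)), meta_file)
  invisible(c(files, meta_file))
}
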