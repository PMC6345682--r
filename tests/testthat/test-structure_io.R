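# PDB model: parsing, writing, altloc resolution, SEQRES bookkeeping.

pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     altloc = " ", icode = " ", occ = 1, b = 0, el = " C",
                     record = "ATOM  ") {
  sprintf("%-6s%5d  %-3s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resseq, icode,
          x, y, z, occ, b, el)
}

test_that("negative residue numbers, altloc resolution and CRYST1 parse correctly", {
  txt <- paste(
    "CRYST1   58.200   62.300  107.700  90.00  90.00  95.60 P 1 21 1",
    pdb_line(1, "CA", "MET", "A", -6, 1, 2, 3),
    pdb_line(2, "CA", "ALA", "A", 1, 4, 5, 6, altloc = "B", occ = 0.4),
    pdb_line(3, "CA", "ALA", "A", 1, 4.5, 5, 6, altloc = "A", occ = 0.6),
    pdb_line(4, "CA", "GLY", "A", 2, 7, 8, 9),
    sep = "\n"
  )
  s <- read_structure(txt, id = "TEST")
  expect_equal(s$cell[["a"]], 58.2)
  expect_equal(s$cell[["gamma"]], 95.6)
  expect_equal(s$space_group, "P 1 21 1")
  res <- modeled_residues(s, "A")
  expect_equal(res$resseq, c(-6L, 1L, 2L))
  # altloc: highest occupancy wins
  ala <- s$atom[s$atom$resseq == 1, ]
  expect_equal(nrow(ala), 1)
  expect_equal(ala$altloc, "A")
  expect_equal(ala$x, 4.5)
})

test_that("altloc occupancy ties break to the lexicographically smallest id", {
  txt <- paste(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, altloc = "C", occ = 0.5),
    pdb_line(2, "CA", "ALA", "A", 1, 1, 0, 0, altloc = "B", occ = 0.5),
    pdb_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_line(4, "CA", "GLY", "A", 3, 7.6, 0, 0),
    sep = "\n"
  )
  s <- read_structure(txt)
  expect_equal(s$atom$altloc[s$atom$resseq == 1], "B")
})

test_that("write/read round trip preserves coordinates, numbering and cell", {
  s <- make_helix_structure(25, seed = 7)
  s$cell <- c(a = 58.2, b = 62.3, c = 107.7, alpha = 90, beta = 90, gamma = 95.6)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  s2 <- read_structure(path)
  expect_equal(s2$atom$resseq, s$atom$resseq)
  expect_equal(s2$atom$name, s$atom$name)
  expect_equal(s2$atom$x, round(s$atom$x, 3))
  expect_equal(s2$atom$y, round(s$atom$y, 3))
  expect_equal(s2$atom$z, round(s$atom$z, 3))
  expect_equal(s2$atom$occupancy, s$atom$occupancy)
  expect_equal(s2$atom$bfactor, s$atom$bfactor)
  expect_equal(s2$cell, s$cell)
  expect_equal(s2$seqres, s$seqres)
  # second round trip is byte-identical
  expect_identical(write_structure(s2), write_structure(read_structure(write_structure(s2))))
})

test_that("parse errors name the offending line; empty structures error", {
  bad <- paste(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    "ATOM      2  CA  ALA A   2      xxx.000   0.000   0.000  1.00  0.00           C",
    sep = "\n"
  )
  expect_error(read_structure(bad), "line 2")
  expect_error(read_structure("HEADER  NOTHING"), "empty structure")
  # occupancy outside [0,1]
  expect_error(read_structure(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 1.5)),
               "occupancy")
})

test_that("missing_residues reports maximal gaps with location tags", {
  # SEQRES of 12; model residues 1-3 and 7-9 -> N-terminal? no: modeled start
  # at seqres position 1.. build: missing 4-6 (internal) and 10-12 (C-terminal)
  resnames <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY",
                "HIS", "ILE", "LYS", "LEU", "MET", "ASN")
  keep <- c(1:3, 7:9)
  xyz <- cbind(seq_along(keep) * 3.8, 0, 0)
  s <- ca_structure(xyz, resnames[keep])
  s$atom$resseq <- keep
  s$seqres <- list(A = resnames)
  gaps <- missing_residues(s, "A")
  expect_equal(gaps$start, c(4L, 10L))
  expect_equal(gaps$end, c(6L, 12L))
  expect_equal(gaps$location, c("internal", "C-terminal"))
  expect_equal(sum(gaps$length), length(resnames) - length(keep))

  # N-terminal gap
  keep2 <- 4:12
  s2 <- ca_structure(cbind(seq_along(keep2) * 3.8, 0, 0), resnames[keep2])
  s2$seqres <- list(A = resnames)
  gaps2 <- missing_residues(s2, "A")
  expect_equal(gaps2$location, "N-terminal")

  # fully modeled chain -> empty
  s3 <- ca_structure(cbind(seq_along(resnames) * 3.8, 0, 0), resnames)
  s3$seqres <- list(A = resnames)
  expect_equal(nrow(missing_residues(s3, "A")), 0)

  # no seqres -> not computable
  s4 <- s3; s4$seqres <- list()
  expect_error(missing_residues(s4, "A"), "SEQRES")
})

test_that("missing-residue lengths always sum to seqres minus modeled count", {
  for (seed in 1:5) {
    s <- make_helix_structure(30, seed = seed)
    drop <- halogst:::with_seed(seed, sample(30, 8))
    s$atom <- s$atom[!s$atom$resseq %in% drop, ]
    gaps <- missing_residues(s, "A")
    expect_equal(sum(gaps$length),
                 length(s$seqres$A) - nrow(modeled_residues(s, "A")))
  }
})

test_that("chain_sequence maps 3-letter codes with X fallback and cross-checks gaps", {
  s <- ca_structure(cbind(1:3 * 3.8, 0, 0), c("MET", "ALA", "CYS"))
  expect_equal(chain_sequence(s, "A", "seqres"), "MAC")
  s$atom$resname[2] <- "XYZ"
  s$seqres <- list(A = c("MET", "XYZ", "CYS"))
  expect_warning(got <- chain_sequence(s, "A", "modeled"), "unknown residue")
  expect_equal(got, "MXC")
  # seqres length - modeled length = missing count
  h <- make_helix_structure(20, seed = 2)
  h$atom <- h$atom[h$atom$resseq <= 15, ]
  expect_equal(nchar(chain_sequence(h, "A", "seqres")) -
                 nchar(chain_sequence(h, "A", "modeled")),
               sum(missing_residues(h, "A")$length))
})

test_that("parsing ignores trailing whitespace and record order within a chain", {
  l1 <- pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0)
  l2 <- pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0)
  l3 <- pdb_line(3, "CA", "SER", "A", 3, 7.6, 0, 0)
  a <- read_structure(paste(l1, l2, l3, sep = "\n"))
  b <- read_structure(paste(paste0(l3, "   "), l1, paste0(l2, "\t"), sep = "\n"))
  expect_equal(modeled_residues(a, "A"), modeled_residues(b, "A"))
})

test_that("entry codes normalize case and letter-O typography", {
  expect_message(got <- normalize_entry_code("4GOI"), "4G0I")
  expect_equal(got, "4G0I")
  expect_silent(expect_equal(normalize_entry_code("6gzf"), "6GZF"))
})

test_that("HETATM records are kept apart from the polymer", {
  txt <- paste(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_line(3, "CA", "SER", "A", 3, 7.6, 0, 0),
    pdb_line(4, "O", "HOH", "A", 101, 20, 0, 0, el = " O", record = "HETATM"),
    sep = "\n"
  )
  s <- read_structure(txt)
  expect_equal(nrow(s$atom), 3)
  expect_equal(nrow(s$het), 1)
  expect_equal(chain_sequence(s, "A", "modeled"), "AGS")
})
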