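# Ligand transplantation, glycyl truncation, distance measurement, clashes.

# holo reference: helix + GSH-like ligand parked near residue 10
make_holo_reference <- function(seed = 1) {
  ref <- make_helix_structure(30, seed = seed)
  lig <- make_gsh_like_ligand(seed = seed)
  anchor <- as.numeric(ref$atom[10, c("x", "y", "z")])
  lig$x <- lig$x + anchor[1] + 4
  lig$y <- lig$y + anchor[2]
  lig$z <- lig$z + anchor[3]
  ref$het <- lig
  ref
}

identity_superposition <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0), rmsd = 0,
                 n_aligned = 0, n_rejected = 0, identity_percent = 100,
                 degenerate = FALSE),
            class = "superposition_result")
}

test_that("identity transplant leaves coordinates unchanged; provenance recorded", {
  ref <- make_holo_reference()
  target <- make_helix_structure(30, seed = 1)
  tl <- transplant_ligand(target, ref, "GSH", identity_superposition())
  expect_equal(tl$atoms$x, ref$het$x)
  expect_equal(tl$source_entry, ref$id)
  expect_equal(tl$edits, character(0))
  expect_error(transplant_ligand(target, ref, "NAD", identity_superposition()),
               "not found")
})

test_that("rigid transplant preserves internal distances; inverse restores source", {
  ref <- make_holo_reference(seed = 2)
  target <- make_transformed_copy(make_helix_structure(30, seed = 2),
                                  rotation_deg = 50, axis = c(1, 0, 1),
                                  translation = c(4, 4, -2), seed = 3)
  sup <- superpose_monomer(ref, "A", target, "A")
  tl <- transplant_ligand(target, ref, "GSH", sup)

  d0 <- dist(ref$het[, c("x", "y", "z")])
  d1 <- dist(tl$atoms[, c("x", "y", "z")])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)

  # inverse transform restores source coordinates
  back <- sweep(as.matrix(tl$atoms[, c("x", "y", "z")]), 2, sup$translation) %*%
    sup$rotation
  expect_equal(back, as.matrix(ref$het[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("multiple ligand copies require a selector", {
  ref <- make_holo_reference()
  second <- ref$het
  second$resseq <- 2L
  second$x <- second$x + 25
  ref$het <- rbind(ref$het, second)
  expect_error(transplant_ligand(make_helix_structure(30), ref, "GSH",
                                 identity_superposition()),
               "Candidates: X:1:, X:2:")
  tl <- transplant_ligand(make_helix_structure(30), ref, "GSH",
                          identity_superposition(),
                          selector = list(chain = "X", resseq = 2))
  expect_equal(unique(tl$atoms$resseq), 2L)
})

test_that("glycyl truncation removes exactly the five glycyl atoms, once", {
  ref <- make_holo_reference()
  tl <- transplant_ligand(make_helix_structure(30), ref, "GSH",
                          identity_superposition())
  before <- tl$atoms
  gec <- truncate_gsh_to_gec(tl)
  expect_equal(nrow(gec$atoms), 15)
  expect_setequal(gec$edits, c("N3", "CA3", "C3", "O31", "O32"))
  expect_true(all(c("SG2", "N1") %in% gec$atoms$name))
  # surviving coordinates untouched
  kept <- before[!before$name %in% gec$edits, c("x", "y", "z")]
  expect_equal(gec$atoms[, c("x", "y", "z")], kept, ignore_attr = TRUE)
  # applying twice errors instead of silently no-opping
  expect_error(truncate_gsh_to_gec(gec), "glycyl atoms absent")
})

test_that("measure_distance handles selections, modes, and rigid invariance", {
  txt_atoms <- data.frame(
    serial = 1:2, name = c("SG", "SG"), altloc = "", resname = "CYS",
    chain = "A", resseq = c(57L, 58L), icode = "",
    x = c(0, 3), y = c(0, 4), z = c(0, 0),
    occupancy = 1, bfactor = 0, element = "S", stringsAsFactors = FALSE
  )
  s <- structure_model("D", txt_atoms)
  m <- measure_distance(s, "chain A and resi 57 and name SG",
                        "chain A and resi 58 and name SG")
  expect_equal(m$value, 5)
  same <- measure_distance(s, "resi 57", "resi 57")
  expect_equal(same$value, 0)
  expect_error(measure_distance(s, "resi 99", "resi 57"), "resi 99")

  # centroid mode and ligand keyword
  ref <- make_holo_reference()
  tl <- transplant_ligand(make_helix_structure(30), ref, "GSH",
                          identity_superposition())
  d_min <- measure_distance(ref, "ligand and name SG2", "chain A and resi 10",
                            mode = "min", ligand = tl)
  expect_gte(d_min$value, 0)
  expect_error(measure_distance(ref, "ligand and name SG2", "resi 10"),
               "no ligand was supplied")

  # invariance under joint rigid motion
  h <- make_helix_structure(12, seed = 5)
  base <- measure_distance(h, "resi 1", "resi 12")$value
  moved <- make_transformed_copy(h, 80, axis = c(2, 1, 1),
                                 translation = c(5, 6, 7), seed = 6)
  expect_equal(measure_distance(moved, "resi 1", "resi 12")$value, base,
               tolerance = 1e-9)
})

test_that("clash detection honours the strict vdW criterion and sorts by overlap", {
  target <- make_helix_structure(30, seed = 4)
  far <- transplant_ligand(make_helix_structure(30), make_holo_reference(4),
                           "GSH", identity_superposition())
  far$atoms$x <- far$atoms$x + 100
  expect_equal(nrow(detect_clashes(far, target)), 0)

  # plant a ligand nitrogen 1.4 A from a protein carbon: N+C vdW = 3.25 A
  lig_atoms <- make_gsh_like_ligand(4)
  ca1 <- as.numeric(target$atom[5, c("x", "y", "z")])
  shift <- ca1 + c(1.4, 0, 0) - as.numeric(lig_atoms[lig_atoms$name == "N1",
                                                     c("x", "y", "z")])
  lig_atoms$x <- lig_atoms$x + shift[1]
  lig_atoms$y <- lig_atoms$y + shift[2]
  lig_atoms$z <- lig_atoms$z + shift[3]
  near <- structure(list(atoms = lig_atoms, source_entry = "SYN",
                         transform = NULL, edits = character(0)),
                    class = "transplanted_ligand")
  clashes <- detect_clashes(near, target, tolerance = 0.4)
  expect_gt(nrow(clashes), 0)
  n1 <- clashes[clashes$ligand_atom == "N1" & clashes$resseq == 5, ]
  expect_equal(nrow(n1), 1)
  expect_equal(n1$distance, 1.4, tolerance = 1e-6)
  expect_true(all(diff(clashes$vdw_overlap) <= 1e-12))

  # boundary: pair exactly at r_a + r_b - tolerance is NOT a clash
  one_c <- ca_structure(matrix(0, 1, 3), "ALA")
  probe <- structure(list(atoms = data.frame(
    serial = 1L, name = "N1", altloc = "", resname = "GSH", chain = "X",
    resseq = 1L, icode = "", x = 1.7 + 1.55 - 0.4, y = 0, z = 0,
    occupancy = 1, bfactor = 0, element = "N", stringsAsFactors = FALSE
  ), source_entry = "SYN", transform = NULL, edits = character(0)),
  class = "transplanted_ligand")
  expect_equal(nrow(detect_clashes(probe, one_c, tolerance = 0.4)), 0)
})
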