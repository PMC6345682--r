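Package: halogst
Title: Structural and Sequence Analysis of Halophilic Xi-Class Glutathione Transferases
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for comparative characterization of halophilic
    Xi-class glutathionyl-hydroquinone reductases: PDB structure parsing with
    His-tag negative residue numbering and SEQRES bookkeeping, alignment-driven
    Kabsch superposition of monomers and dimers with iterative outlier
    rejection, amino-acid composition deltas for halophilic adaptation
    analysis, Shrake-Rupley solvent accessibility with a permutation test for
    surface charge evenness and a simplified Coulomb surface score,
    homology-based transplantation of glutathione into an apo structure with
    glycyl truncation to gamma-glutamyl-cysteine and clash detection,
    motif/restriction-site scanning and ORF translation, neighbor-joining
    phylogenies with bootstrap support, and a synthetic-data generator with
    planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
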