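# p-distances, neighbor joining, bootstrap support, newick output.

test_that("p-distances use pairwise deletion and validate input", {
  msa <- c(a = "ACDE", b = "ACDF", c = "AC-E")
  d <- p_distance_matrix(msa)
  expect_equal(d["a", "b"], 0.25)     # 1 mismatch / 4 columns
  expect_equal(d["a", "c"], 0)        # gapped column dropped, denominator 3
  expect_equal(d["b", "c"], 1 / 3)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_equal(p_distance_matrix(c(a = "AAA", b = "AAA", c = "AAA"))["a", "b"], 0)
  expect_error(p_distance_matrix(msa[1:2]), "at least 3")
  expect_error(p_distance_matrix(c(a = "A-", b = "-A", c = "AA")), "no comparable")
})

test_that("3-taxon NJ solves the closed form", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  st <- nj_tree(d)
  expect_equal(write_newick(st), "(A:0.500000,B:1.500000,C:2.500000);")
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ reconstructs additive trees exactly (topology and path lengths)", {
  for (seed in 1:10) {
    n_taxa <- 5 + (seed %% 4)
    true_tree <- random_additive_tree(n_taxa, seed)
    dmat <- ape::cophenetic.phylo(true_tree)
    dmat <- dmat[sort(rownames(dmat)), sort(colnames(dmat))]
    st <- nj_tree(dmat)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true_tree), st$tree)), 0,
                 label = paste("RF distance, seed", seed))
    # path lengths between leaves reproduce the matrix entries
    recovered <- ape::cophenetic.phylo(st$tree)
    recovered <- recovered[rownames(dmat), colnames(dmat)]
    expect_equal(recovered, dmat, tolerance = 1e-8)
  }
})

test_that("NJ agrees with the independent ape implementation on random matrices", {
  for (seed in 1:10) {
    dmat <- halogst:::with_seed(seed, {
      base <- ape::cophenetic.phylo(random_additive_tree(6, seed))
      noise <- matrix(stats::runif(36, 0, 0.05), 6, 6)
      noise <- (noise + t(noise)) / 2
      diag(noise) <- 0
      base + noise
    })
    mine <- nj_tree(dmat)$tree
    theirs <- ape::nj(as.dist(dmat))
    expect_equal(as.numeric(ape::dist.topo(mine, theirs)), 0,
                 label = paste("vs ape::nj, seed", seed))
  }
})

test_that("4-taxon NJ picks the least-squares-best topology on near-additive input", {
  # brute force: evaluate all 3 unrooted 4-taxon topologies by OLS fit
  ls_best_topology <- function(d) {
    taxa <- rownames(d)
    splits <- list(c(1, 2), c(1, 3), c(1, 4))
    fits <- vapply(splits, function(pair) {
      others <- setdiff(1:4, pair)
      i <- pair[1]; j <- pair[2]; k <- others[1]; l <- others[2]
      # OLS branch lengths for topology ij|kl have closed form via the
      # four-point decomposition; residual = (d_ik + d_jl - d_il - d_jk)^2/4
      # under the constraint only the internal branch differs
      ((d[i, k] + d[j, l]) - (d[i, l] + d[j, k]))^2 / 4
    }, numeric(1))
    paste(sort(taxa[splits[[which.min(fits)]]]), collapse = "")
  }
  agree <- 0
  for (seed in 1:100) {
    true_tree <- random_additive_tree(4, seed)
    d <- ape::cophenetic.phylo(true_tree)
    noise <- halogst:::with_seed(seed + 500, {
      m <- matrix(stats::runif(16, 0, 0.02), 4, 4); (m + t(m)) / 2
    })
    diag(noise) <- 0
    d <- d + noise
    st <- nj_tree(d)
    # recover the split of the NJ tree
    keys <- halogst:::bipartition_keys(st$tree, sort(rownames(d)))
    nj_split <- if (length(keys$keys)) {
      side <- strsplit(keys$keys[1], "\\|")[[1]]
      paste(sort(setdiff(rownames(d), side)), collapse = "")
    } else NA
    other_side <- paste(sort(strsplit(keys$keys[1], "\\|")[[1]]), collapse = "")
    ls <- ls_best_topology(d)
    if (identical(nj_split, ls) || identical(other_side, ls)) agree <- agree + 1
  }
  expect_equal(agree, 100)
})

test_that("negative branch lengths are clamped with the deficit transferred", {
  # a matrix engineered to produce a negative NJ branch estimate
  d <- matrix(c(
    0, 0.1, 1.0, 1.05,
    0.1, 0, 1.02, 1.0,
    1.0, 1.02, 0, 0.3,
    1.05, 1.0, 0.3, 0
  ), 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  st <- nj_tree(d)
  expect_true(all(st$tree$edge.length >= 0))
})

test_that("bootstrap is deterministic, supports planted splits, masks below threshold", {
  fam <- make_sequence_family(
    "((a:0.05,b:0.05):0.45,(c:0.05,d:0.05):0.45,(e:0.05,f:0.05):0.45);",
    n_columns = 500, subst_rate = 1 / 2, seed = 31
  )
  b1 <- bootstrap_support(fam$msa, n_reps = 100, seed = 9)
  b2 <- bootstrap_support(fam$msa, n_reps = 100, seed = 9)
  expect_identical(b1$support, b2$support)
  # two deeply separated clades: the separating branches get >= 99% support
  expect_true(all(b1$support[!is.na(b1$support)] >= 99))
  expect_error(bootstrap_support(fam$msa, n_reps = 0), "at least 1")

  # masking: 39 masked at threshold 40, 41 kept; data retained either way
  st <- nj_tree(p_distance_matrix(fam$msa[1:5]))
  st$support <- c(NA, 39, 41)[seq_len(st$tree$Nnode)]
  st$display_threshold <- 40
  nwk <- write_newick(st)
  expect_false(grepl("39", nwk))
  expect_true(grepl("41", nwk))
  expect_equal(st$support[2], 39)
})

test_that("bootstrap supports are invariant to taxon input order", {
  fam <- make_sequence_family("((a:0.1,b:0.1):0.3,(c:0.1,d:0.1):0.3,(e:0.1,f:0.1):0.3);",
                              n_columns = 300, subst_rate = 0.5, seed = 13)
  b1 <- bootstrap_support(fam$msa, n_reps = 50, seed = 3)
  b2 <- bootstrap_support(rev(fam$msa), n_reps = 50, seed = 3)
  key_support <- function(b) {
    k <- halogst:::bipartition_keys(b$tree, sort(b$tree$tip.label))
    stats::setNames(b$support[k$nodes - length(b$tree$tip.label)], k$keys)
  }
  s1 <- key_support(b1); s2 <- key_support(b2)
  common <- intersect(names(s1), names(s2))
  expect_setequal(names(s1), names(s2))
  # same splits found; supports within resampling noise of each other
  expect_true(all(abs(s1[common] - s2[common]) <= 10))
})

test_that("newick output round-trips through an independent parser", {
  fam <- make_sequence_family("((a:0.1,b:0.1):0.2,(c:0.1,'d d':0.1):0.2);",
                              n_columns = 100, subst_rate = 0.5, seed = 17)
  st <- bootstrap_support(fam$msa, n_reps = 20, seed = 5, threshold = 0)
  nwk <- write_newick(st)
  parsed <- ape::read.tree(text = nwk)
  expect_setequal(parsed$tip.label, st$tree$tip.label)
  expect_equal(as.numeric(ape::dist.topo(parsed, st$tree)), 0)
  expect_equal(sort(parsed$edge.length), sort(round(st$tree$edge.length, 6)),
               tolerance = 1e-9)
  # labels containing spaces are quoted
  expect_true(grepl("'d d'", nwk))
})
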