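# Distance-based phylogeny: p-distances with pairwise gap deletion,
# neighbor-joining (Saitou-Nei) with deterministic tie-breaking and negative
# branch clamping, bootstrap support by column resampling, newick output.
# Trees are carried as ape "phylo" objects.

#' p-distance matrix from an alignment
#'
#' Proportion of mismatching columns per sequence pair, with pairwise
#' deletion: columns holding a gap (`-` or `.`) in either sequence of the
#' pair are excluded from that pair's denominator.
#'
#' @param msa Named character vector of equal-length aligned sequences
#'   (at least 3).
#' @return Symmetric distance matrix with zero diagonal, taxa as dimnames.
#' @export
p_distance_matrix <- function(msa) {
  if (length(msa) < 3) stop("at least 3 sequences required", call. = FALSE)
  if (length(unique(nchar(msa))) != 1) {
    stop("aligned sequences must have equal lengths", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(unlist(msa)), ""))
  rownames(m) <- names(msa)
  gap <- m == "-" | m == "."
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        stop("no comparable columns between ", names(msa)[i], " and ",
             names(msa)[j], call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  d
}

# internal recursive node used during agglomeration
nj_leaf <- function(label) list(label = label, children = NULL, lengths = NULL)
nj_join <- function(a, b, la, lb) {
  list(label = NULL, children = list(a, b), lengths = c(la, lb))
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on a distance matrix. Ties in the
#' Q-matrix are broken by the lowest (i, j) index pair for deterministic
#' output. A negative branch length at a join is clamped to zero with the
#' deficit transferred to its sister branch, preserving the pair's summed
#' length.
#'
#' @param d Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return An object of class `supported_tree`: list with `tree` (an unrooted
#'   ape `phylo`), `support` (NULL until [bootstrap_support()] fills it) and
#'   `display_threshold`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining requires at least 3 taxa", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- lapply(labels, nj_leaf)

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }

  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest (i, j), i < j, among minima (row-major on the upper triangle)
    idx <- which(upper.tri(q) & q == min(q[upper.tri(q)]), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    ll <- clamp_pair(li, lj)
    new_node <- nj_join(nodes[[i]], nodes[[j]], ll[1], ll[2])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    dk <- pmax(dk[-c(i, j)], 0)
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, dk), c(dk, 0))
    nodes <- c(nodes[-c(i, j)], list(new_node))
  }

  # final three nodes joined in a star
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  lens <- pmax(c(la, lb, lc), 0)
  root <- list(label = NULL, children = nodes, lengths = lens)

  tree <- nested_to_phylo(root)
  structure(list(tree = tree, support = NULL, display_threshold = NULL),
            class = "supported_tree")
}

# Convert the recursive node representation into an ape phylo object.
nested_to_phylo <- function(root) {
  tips <- character(0)
  collect_tips <- function(nd) {
    if (is.null(nd$children)) tips <<- c(tips, nd$label)
    else for (ch in nd$children) collect_tips(ch)
  }
  collect_tips(root)
  n_tip <- length(tips)
  count_internal <- function(nd) {
    if (is.null(nd$children)) return(0L)
    1L + sum(vapply(nd$children, count_internal, integer(1)))
  }
  n_node <- count_internal(root)

  edge <- matrix(0L, 0, 2)
  edge_len <- numeric(0)
  tip_no <- stats::setNames(seq_len(n_tip), tips)
  next_internal <- n_tip + 1L

  assign_num <- function(nd) {
    if (is.null(nd$children)) return(tip_no[[nd$label]])
    my <- next_internal
    next_internal <<- next_internal + 1L
    for (k in seq_along(nd$children)) {
      child_num <- assign_num(nd$children[[k]])
      edge <<- rbind(edge, c(my, child_num))
      edge_len <<- c(edge_len, nd$lengths[k])
    }
    my
  }
  assign_num(root)

  tr <- list(edge = edge, edge.length = edge_len, tip.label = tips,
             Nnode = n_node)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat("<supported_tree> ", length(x$tree$tip.label), " taxa")
  if (!is.null(x$support)) {
    thr <- if (is.null(x$display_threshold)) 0 else x$display_threshold
    shown <- x$support[!is.na(x$support) & x$support > thr]
    cat(sprintf(", %d internal branches with support > %s%%",
                length(shown), format(thr)))
  }
  cat("\n", write_newick(x), "\n", sep = "")
  invisible(x)
}

# Bipartition keys of a phylo tree: for every internal edge, the tip set on
# the child side, canonicalized to the side not containing the first taxon
# of `taxa`.
bipartition_keys <- function(tree, taxa) {
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  tips_below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(tree$edge[children[[as.character(node)]], 2], tips_below))
  }
  keys <- character(0)
  nodes <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n_tip) next
    side <- tips_below(child)
    if (length(side) < 2 || length(side) > n_tip - 2) next
    if (taxa[1] %in% side) side <- setdiff(taxa, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, child)
  }
  list(keys = keys, nodes = nodes)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the NJ tree on the full alignment, then resamples alignment columns
#' with replacement `n_reps` times, rebuilds a tree per replicate, and scores
#' each internal branch of the original tree by the percentage of replicates
#' containing its bipartition. Supports below `threshold` are masked in
#' display output (newick, print) but retained in the data.
#'
#' @param msa Named character vector of aligned sequences.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; identical (msa, n_reps, seed) give bit-identical
#'   supports.
#' @param threshold Display threshold in percent (default 40).
#' @return A `supported_tree` with `support` set (one value per internal
#'   node, NA for the root) and `display_threshold`.
#' @export
bootstrap_support <- function(msa, n_reps, seed = 1, threshold = 40) {
  if (n_reps < 1) stop("n_reps must be at least 1", call. = FALSE)
  st <- nj_tree(p_distance_matrix(msa))
  tree <- st$tree
  taxa <- sort(tree$tip.label)
  orig <- bipartition_keys(tree, taxa)
  counts <- stats::setNames(numeric(length(orig$keys)), orig$keys)

  chars <- do.call(rbind, strsplit(unlist(msa), ""))
  rownames(chars) <- names(msa)
  n_col <- ncol(chars)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  for (rep_i in seq_len(n_reps)) {
    cols <- sample.int(n_col, n_col, replace = TRUE)
    rep_msa <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
    rep_tree <- tryCatch(nj_tree(p_distance_matrix(rep_msa))$tree,
                         error = function(e) NULL)
    if (is.null(rep_tree)) next
    rep_keys <- bipartition_keys(rep_tree, taxa)$keys
    hit <- orig$keys %in% rep_keys
    counts[hit] <- counts[hit] + 1
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  support <- rep(NA_real_, tree$Nnode)
  support[orig$nodes - length(tree$tip.label)] <- 100 * counts / n_reps
  st$support <- support
  st$display_threshold <- threshold
  st
}

#' Write a tree as a newick string
#'
#' Branch lengths to 6 decimals; bootstrap supports (when present and above
#' the display threshold) as internal node labels; labels containing spaces
#' or newick metacharacters are single-quoted.
#'
#' @param x A `supported_tree` or ape `phylo`.
#' @param digits Branch-length decimals (default 6).
#' @return Newick string (with trailing semicolon).
#' @export
write_newick <- function(x, digits = 6) {
  if (inherits(x, "supported_tree")) {
    tree <- x$tree; support <- x$support
    thr <- if (is.null(x$display_threshold)) 0 else x$display_threshold
  } else {
    tree <- x; support <- NULL; thr <- 0
  }
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  quote_label <- function(lab) {
    if (grepl("[ ():,;\\[\\]']", lab)) {
      paste0("'", gsub("'", "''", lab), "'")
    } else lab
  }
  fmt_len <- function(len) sprintf(paste0("%.", digits, "f"), len)
  render <- function(node) {
    if (node <= n_tip) return(quote_label(tree$tip.label[node]))
    kid_edges <- children[[as.character(node)]]
    inner <- paste(vapply(kid_edges, function(e) {
      paste0(render(tree$edge[e, 2]), ":", fmt_len(tree$edge.length[e]))
    }, ""), collapse = ",")
    lab <- ""
    if (!is.null(support)) {
      s <- support[node - n_tip]
      if (!is.na(s) && s > thr) lab <- format(round(s), trim = TRUE)
    }
    paste0("(", inner, ")", lab)
  }
  root <- n_tip + 1L
  paste0(render(root), ";")
}
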