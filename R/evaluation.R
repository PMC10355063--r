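#' Non-trivial bipartitions of an unrooted tree
#'
#' Every internal edge of the unrooted tree splits the leaf set in two;
#' the set of these bipartitions determines the unrooted topology.
#' Bipartitions are canonicalized as the sorted side *not* containing the
#' reference taxon (the lexicographically smallest label), so the encoding
#' is independent of root placement and tip order. Trivial bipartitions
#' (leaf-incident edges) are excluded.
#'
#' @param tree a `phylo` (polytomies allowed; degree-2 root suppressed).
#' @return character vector (one encoded split per internal edge) with
#'   attributes `"n"` (leaf count) and `"labels"`.
#' @examples
#' length(bipartitions(ape::read.tree(text = "((a,b),(c,d));")))  # 1
#' @export
bipartitions <- function(tree) {
  ut <- as_utree(tree)
  n <- ut$n_leaf
  labels <- ut$labels
  ref <- labels[order(labels)[1]]
  splits <- character(0)
  int_rows <- which(!ut$leaf_edge)
  for (e in int_rows) {
    side <- side_of(ut$edge, e, ut$edge[e, 1])
    side <- side[side <= n]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% labels[side]) side <- setdiff(seq_len(n), side)
    splits <- c(splits, paste(sort(labels[side]), collapse = "\r"))
  }
  splits <- unique(splits)
  attr(splits, "n") <- n
  attr(splits, "labels") <- labels
  splits
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the non-trivial bipartition
#' sets of two trees on the same leaf set.
#'
#' @param t1,t2 `phylo` trees over identical leaf sets.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  l1 <- t1$tip.label; l2 <- t2$tip.label
  if (!setequal(l1, l2)) {
    stop("leaf sets differ; only in first: {",
         paste(setdiff(l1, l2), collapse = ","), "}, only in second: {",
         paste(setdiff(l2, l1), collapse = ","), "}")
  }
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Normalized Robinson-Foulds distance
#'
#' For two binary trees the RF distance is divided by `2n - 6`, the
#' number of non-trivial bipartitions in the pair; in general it is
#' divided by the total number of non-trivial bipartitions in the two
#' trees. The result lies in `[0, 1]`, and for binary pairs equals the
#' missing-branch rate. Two trees with no non-trivial bipartitions at all
#' (stars) are at distance 0.
#'
#' @inheritParams rf_distance
#' @return a value in `[0, 1]`.
#' @export
nrf <- function(t1, t2) {
  n <- length(t1$tip.label)
  if (n < 4) stop("nRF requires at least 4 leaves")
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  denom <- length(b1) + length(b2)
  if (denom == 0) return(0)
  (length(setdiff(b1, b2)) + length(setdiff(b2, b1))) / denom
}

restrict_pair <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4)
    stop("fewer than 4 shared taxa between trees")
  drop1 <- setdiff(t1$tip.label, shared)
  drop2 <- setdiff(t2$tip.label, shared)
  if (length(drop1)) t1 <- ape::drop.tip(t1, drop1)
  if (length(drop2)) t2 <- ape::drop.tip(t2, drop2)
  list(t1, t2)
}

#' Gene tree estimation error (GTEE)
#'
#' Mean normalized RF distance between paired lists of true and estimated
#' gene trees. When a pair's leaf sets differ, both trees are restricted
#' to the shared taxa first (an extension needed for incomplete gene
#' trees).
#'
#' @param true_trees,est_trees lists of `phylo` of equal length.
#' @return mean per-pair nRF.
#' @export
gtee <- function(true_trees, est_trees) {
  if (!length(true_trees) || length(true_trees) != length(est_trees))
    stop("need two non-empty paired lists of trees")
  vals <- mapply(function(a, b) {
    p <- restrict_pair(a, b)
    nrf(p[[1]], p[[2]])
  }, true_trees, est_trees)
  mean(vals)
}

#' Average discordance (AD)
#'
#' Mean normalized RF distance between a species tree and a set of gene
#' trees; the standard proxy for the level of incomplete lineage sorting
#' in a dataset. Gene trees missing taxa are compared on the shared leaf
#' set.
#'
#' @param species_tree a `phylo`.
#' @param gene_trees list of `phylo`.
#' @return mean nRF in `[0, 1]`.
#' @export
average_discordance <- function(species_tree, gene_trees) {
  if (!length(gene_trees)) stop("empty gene tree list")
  vals <- vapply(gene_trees, function(g) {
    p <- restrict_pair(species_tree, g)
    nrf(p[[1]], p[[2]])
  }, numeric(1))
  mean(vals)
}

#' ILS level category from average discordance
#'
#' Classifies a dataset's ILS level by its AD value: below 25% low (`L`),
#' up to 39% medium (`M`), 40-59% high (`H`), above that very high
#' (`VH`). Values in the unstated 25-26% gap fall in `M`.
#'
#' @param ad average discordance in `[0, 1]`.
#' @return one of `"L"`, `"M"`, `"H"`, `"VH"`.
#' @export
ils_band <- function(ad) {
  stopifnot(ad >= 0, ad <= 1)
  if (ad < 0.25) "L" else if (ad < 0.40) "M" else if (ad < 0.60) "H" else "VH"
}
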