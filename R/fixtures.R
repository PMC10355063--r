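# Synthetic data: species trees, multispecies-coalescent gene trees,
# gene-tree error with support annotation, and missing-data models.

# rooted edge list (parent, child) -> cladewise phylo
rooted_edges_to_phylo <- function(edge, n, root, lengths = NULL) {
  max_id <- max(edge)
  kids <- vector("list", max_id)
  krow <- vector("list", max_id)
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]
    kids[[p]] <- c(kids[[p]], edge[i, 2])
    krow[[p]] <- c(krow[[p]], i)
  }
  new_id <- integer(max_id)
  new_id[seq_len(n)] <- seq_len(n)
  next_int <- n
  ord_rows <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (v > n) { next_int <- next_int + 1L; new_id[v] <- next_int }
    if (!is.null(krow[[v]])) {
      ord_rows <- c(ord_rows, krow[[v]])
      stack <- c(stack, rev(kids[[v]]))
    }
  }
  out <- cbind(new_id[edge[ord_rows, 1]], new_id[edge[ord_rows, 2]])
  phy <- structure(list(edge = out, tip.label = paste0("t", seq_len(n)),
                        Nnode = next_int - n), class = "phylo")
  if (!is.null(lengths)) phy$edge.length <- lengths[ord_rows]
  phy
}

#' Random rooted species tree
#'
#' Uniform random rooted binary topology by sequential attachment: taxon
#' `t + 1` subdivides one of the `2t - 2` existing edges or starts a new
#' stem above the root, each with equal probability, which makes every
#' rooted topology equally likely (and every unrooted topology equally
#' likely after unrooting). Branch lengths, in coalescent units, are drawn
#' from `length_law`.
#'
#' @param n number of taxa (at least 4).
#' @param seed optional RNG seed.
#' @param length_law function of one integer argument returning that many
#'   positive branch lengths; default uniform on `[0.5, 2]` coalescent
#'   units (moderate ILS).
#' @return a rooted binary `phylo` with tip labels `t1..tn`.
#' @export
random_species_tree <- function(n, seed = NULL,
                                length_law = function(m) stats::runif(m, 0.5, 2)) {
  stopifnot(n >= 4)
  if (!is.null(seed)) set.seed(seed)
  next_int <- n + 1L
  root <- next_int
  edge <- rbind(c(root, 1L), c(root, 2L))
  for (t in 3:n) {
    pick <- sample.int(nrow(edge) + 1L, 1L)
    next_int <- next_int + 1L
    v <- next_int
    if (pick > nrow(edge)) {          # new stem above the root
      edge <- rbind(edge, c(v, root), c(v, t))
      root <- v
    } else {
      child <- edge[pick, 2]
      edge[pick, 2] <- v
      edge <- rbind(edge, c(v, child), c(v, t))
    }
  }
  lens <- length_law(nrow(edge))
  if (any(lens <= 0)) stop("length_law produced non-positive lengths")
  rooted_edges_to_phylo(edge, n, root, lens)
}

#' Simulate gene trees under the multispecies coalescent
#'
#' For each gene, one lineage enters at every species-tree tip; within a
#' species-tree branch of duration `t` (coalescent units) the lineages
#' follow a Kingman coalescent — with `j` lineages the waiting time to the
#' next merger is exponential with rate `j (j - 1) / 2` and the merging
#' pair is uniform — and surviving lineages are passed to the parent
#' branch. Remaining lineages coalesce in the root's infinite branch. Gene
#' trees are returned with coalescent-unit branch lengths; they are stored
#' rooted but interpreted as unrooted downstream.
#'
#' @param species_tree rooted binary `phylo` with coalescent-unit branch
#'   lengths.
#' @param k number of gene trees.
#' @param seed optional RNG seed.
#' @return a `multiPhylo` of `k` gene trees with attribute `"registry"`.
#' @export
msc_simulate <- function(species_tree, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- species_tree
  n <- length(sp$tip.label)
  root <- n + 1L
  # postorder over internal nodes: deeper nodes (children) first
  depth <- node_depths(sp)
  internals <- order(depth[(n + 1):(n + sp$Nnode)], decreasing = TRUE) + n
  kids <- split(sp$edge[, 2], sp$edge[, 1])
  blen <- numeric(n + sp$Nnode)
  blen[sp$edge[, 2]] <- sp$edge.length
  blen[root] <- Inf

  nwk <- character(k)
  for (g in seq_len(k)) {
    frags <- vector("list", n + sp$Nnode)
    pend <- vector("list", n + sp$Nnode)
    for (tip in seq_len(n)) {
      res <- coalesce_branch(sp$tip.label[tip], 0, blen[tip])
      frags[[tip]] <- res$f; pend[[tip]] <- res$p
    }
    for (v in internals) {
      ch <- kids[[as.character(v)]]
      f <- unlist(lapply(ch, function(c) frags[[c]]))
      p <- unlist(lapply(ch, function(c) pend[[c]]))
      res <- coalesce_branch(f, p, blen[v])
      frags[[v]] <- res$f; pend[[v]] <- res$p
    }
    nwk[g] <- paste0(frags[[root]][1], ";")
  }
  trees <- ape::read.tree(text = paste(nwk, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  attr(trees, "registry") <- sp$tip.label
  trees
}

# Kingman coalescent within one branch of duration t; `f` newick
# fragments, `p` pending branch lengths grown since each fragment's root.
coalesce_branch <- function(f, p, t) {
  j <- length(f)
  left <- t
  while (j >= 2) {
    w <- stats::rexp(1, j * (j - 1) / 2)
    if (w > left) break
    p <- p + w
    left <- left - w
    pair <- sample.int(j, 2)
    i1 <- pair[1]; i2 <- pair[2]
    merged <- paste0("(", f[i1], ":", p[i1], ",", f[i2], ":", p[i2], ")")
    f <- c(f[-pair], merged)
    p <- c(p[-pair], 0)
    j <- j - 1L
  }
  if (is.finite(left)) p <- p + left
  list(f = f, p = p)
}

node_depths <- function(phy) {
  n <- length(phy$tip.label)
  depth <- integer(n + phy$Nnode)
  for (i in seq_len(nrow(phy$edge)))  # edge matrix is cladewise: parents first
    depth[phy$edge[i, 2]] <- depth[phy$edge[i, 1]] + 1L
  depth
}

#' Perturb gene trees and annotate supports
#'
#' Emulates gene-tree estimation error: applies `count` random NNI moves
#' to each tree, then annotates every internal edge with a branch support
#' drawn from `law_correct` when the edge's bipartition occurs in the
#' original (true) tree and from `law_wrong` otherwise, so that supports
#' are correlated with correctness. Branch lengths, when present, are
#' perturbed multiplicatively (log-normal).
#'
#' @param gene_trees `multiPhylo` or list of `phylo`.
#' @param count number of random NNI moves per tree.
#' @param seed optional RNG seed.
#' @param law_correct,law_wrong functions of one integer argument drawing
#'   supports in `[0, 1]` for correct / erroneous edges.
#' @param length_sd standard deviation of the log-normal length jitter
#'   (0 disables).
#' @return list of perturbed `phylo` trees with numeric node-label
#'   supports (raw01 scale).
#' @export
inject_error <- function(gene_trees, count, seed = NULL,
                         law_correct = function(m) 0.6 + 0.4 * stats::rbeta(m, 5, 1),
                         law_wrong = function(m) 0.7 * stats::rbeta(m, 2, 5),
                         length_sd = 0.25) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(gene_trees, function(tr) {
    true_splits <- bipartitions(tr)
    ut <- as_utree(tr)
    n <- ut$n_leaf
    edge <- ut$edge
    int_rows <- which(edge[, 1] > n & edge[, 2] > n)
    if (count > 0 && length(int_rows)) {
      for (i in seq_len(count)) {
        e <- int_rows[sample.int(length(int_rows), 1)]
        a <- edge[e, 1]; b <- edge[e, 2]
        ia <- setdiff(incident_rows(edge, a), e)
        ib <- setdiff(incident_rows(edge, b), e)
        rb <- ib[sample.int(length(ib), 1)]
        edge <- swap_endpoint(edge, ia[2], a, b)
        edge <- swap_endpoint(edge, rb, b, a)
      }
    }
    ut$edge <- edge
    # supports correlated with correctness
    ref <- ut$labels[order(ut$labels)[1]]
    sup <- rep(NA_real_, nrow(edge))
    for (e in which(!ut$leaf_edge)) {
      side <- side_of(edge, e, edge[e, 1])
      side <- side[side <= n]
      if (ref %in% ut$labels[side]) side <- setdiff(seq_len(n), side)
      key <- paste(sort(ut$labels[side]), collapse = "\r")
      sup[e] <- if (key %in% true_splits) law_correct(1) else law_wrong(1)
    }
    ut$support <- sup
    if (!all(is.na(ut$length)) && length_sd > 0)
      ut$length <- ut$length * exp(stats::rnorm(length(ut$length), 0, length_sd))
    utree_to_phylo(ut, use_lengths = !all(is.na(ut$length)), use_supports = TRUE)
  })
  class(out) <- "multiPhylo"
  attr(out, "registry") <- unique(unlist(lapply(out, `[[`, "tip.label")))
  out
}

#' Delete a fixed number of taxa from each gene tree at random
#'
#' Per gene, a uniformly random subset of `m` taxa is pruned (degree-2
#' nodes are suppressed, lengths summed), so every output tree has exactly
#' `n - m` leaves.
#'
#' @param gene_trees `multiPhylo` of complete gene trees.
#' @param m number of taxa to delete per gene; at least 4 must remain.
#' @param seed optional RNG seed.
#' @return `multiPhylo` of pruned trees.
#' @export
delete_iid <- function(gene_trees, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- attr(gene_trees, "registry")
  if (is.null(taxa)) taxa <- unique(unlist(lapply(gene_trees, `[[`, "tip.label")))
  n <- length(taxa)
  if (m <= 0 || n - m < 4)
    stop("m must satisfy 0 < m and n - m >= 4")
  out <- lapply(gene_trees, function(tr) {
    drop <- sample(taxa, m)
    ape::drop.tip(tr, intersect(drop, tr$tip.label))
  })
  class(out) <- "multiPhylo"
  attr(out, "registry") <- taxa
  out
}

#' Clade-based missing data
#'
#' Per gene, one clade of the rooted species tree with at least
#' `ceiling(x * n)` taxa is sampled uniformly, and the gene tree is pruned
#' to that clade's taxa. The root clade always qualifies, so larger `x`
#' means less deletion on average.
#'
#' @param gene_trees `multiPhylo` of gene trees.
#' @param species_tree rooted `phylo` defining the clades.
#' @param x minimum clade size as a fraction of `n`, in `(0, 1]`.
#' @param seed optional RNG seed.
#' @return `multiPhylo` of pruned trees.
#' @export
delete_m_clade <- function(gene_trees, species_tree, x, seed = NULL) {
  stopifnot(x > 0, x <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(species_tree$tip.label)
  clades <- ape::prop.part(species_tree)
  clade_tips <- lapply(clades, function(i) species_tree$tip.label[i])
  sizes <- lengths(clade_tips)
  ok <- which(sizes >= ceiling(x * n))
  if (!length(ok)) stop("no clade of size >= ceiling(x*n)")  # unreachable: root qualifies
  out <- lapply(gene_trees, function(tr) {
    keep <- clade_tips[[ok[sample.int(length(ok), 1)]]]
    drop <- setdiff(tr$tip.label, keep)
    if (length(drop)) ape::drop.tip(tr, drop) else tr
  })
  class(out) <- "multiPhylo"
  attr(out, "registry") <- species_tree$tip.label
  out
}
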