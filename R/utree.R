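# Internal unrooted-tree representation.
#
# Trees are stored rooted (ape "phylo") but all semantics here are
# unrooted: a degree-2 root is suppressed before any path computation, so
# no result can depend on root placement. A "utree" is a plain list:
#   edge      m x 2 integer matrix of undirected edges; leaves keep their
#             phylo tip numbers 1..n, internal ids are > n (gaps allowed)
#   length    numeric per-edge branch length (NA if absent)
#   support   numeric per-edge raw/normalized support (NA if absent;
#             always NA on leaf-incident edges, whose support is
#             implicitly 1)
#   leaf_edge logical, edge incident to a leaf
#   n_leaf    number of leaves
#   labels    tip labels, index = leaf id

as_utree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' tree")
  n <- length(phy$tip.label)
  edge <- phy$edge
  len <- if (is.null(phy$edge.length)) rep(NA_real_, nrow(edge)) else phy$edge.length

  # per-edge support: node label of the child when the child is internal
  sup <- rep(NA_real_, nrow(edge))
  if (!is.null(phy$node.label)) {
    lab <- phy$node.label
    child <- edge[, 2]
    int <- child > n
    idx <- child[int] - n
    raw <- suppressWarnings(as.numeric(lab[idx]))
    sup[int] <- raw
  }

  root <- n + 1L
  root_rows <- which(edge[, 1] == root)
  if (length(root_rows) == 2L) {
    # suppress the degree-2 root: concatenate its two edges
    r1 <- root_rows[1]; r2 <- root_rows[2]
    a <- edge[r1, 2]; b <- edge[r2, 2]
    l12 <- if (is.na(len[r1]) && is.na(len[r2])) NA_real_ else
      sum(len[root_rows], na.rm = TRUE)
    # the two root edges carry the same unrooted bipartition, so their
    # annotations describe one edge: take the defined one, or their mean
    s1 <- sup[r1]; s2 <- sup[r2]
    s12 <- if (is.na(s1)) s2 else if (is.na(s2)) s1 else (s1 + s2) / 2
    keep <- setdiff(seq_len(nrow(edge)), root_rows)
    edge <- rbind(edge[keep, , drop = FALSE], c(a, b))
    len <- c(len[keep], l12)
    sup <- c(sup[keep], s12)
  }

  leaf_edge <- edge[, 1] <= n | edge[, 2] <= n
  sup[leaf_edge] <- NA_real_
  list(edge = edge, length = len, support = sup, leaf_edge = leaf_edge,
       n_leaf = n, labels = phy$tip.label)
}

# All-pairs leaf path sums for arbitrary per-edge weights.
utree_path_sums <- function(ut, w) {
  max_id <- max(ut$edge)
  leaf_map <- integer(max_id)
  leaf_map[seq_len(ut$n_leaf)] <- seq_len(ut$n_leaf)
  d <- leaf_path_sums_cpp(ut$edge, w, leaf_map, ut$n_leaf)
  dimnames(d) <- list(ut$labels, ut$labels)
  d
}

# Single-source weighted distances from node `from` to every node,
# iterative BFS order (tree, so one pass suffices). Used by the two-sweep
# diameter search.
utree_sssp <- function(ut, w, from) {
  max_id <- max(ut$edge)
  adj_n <- vector("list", max_id)
  adj_w <- vector("list", max_id)
  for (i in seq_len(nrow(ut$edge))) {
    a <- ut$edge[i, 1]; b <- ut$edge[i, 2]
    adj_n[[a]] <- c(adj_n[[a]], b); adj_w[[a]] <- c(adj_w[[a]], w[i])
    adj_n[[b]] <- c(adj_n[[b]], a); adj_w[[b]] <- c(adj_w[[b]], w[i])
  }
  dist <- rep(NA_real_, max_id)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- adj_n[[v]]
    new <- nb[is.na(dist[nb])]
    dist[new] <- dist[v] + adj_w[[v]][match(new, nb)]
    queue <- c(queue, new)
  }
  dist
}

# Rebuild a valid cladewise "phylo" from a utree, rooted at an internal
# node (basal multifurcation), optionally attaching per-edge lengths and
# supports (supports become node labels of the child internal node).
utree_to_phylo <- function(ut, use_lengths = TRUE, use_supports = FALSE) {
  n <- ut$n_leaf
  edge <- ut$edge
  m <- nrow(edge)
  max_id <- max(edge)
  adj_n <- vector("list", max_id)
  adj_e <- vector("list", max_id)
  for (i in seq_len(m)) {
    a <- edge[i, 1]; b <- edge[i, 2]
    adj_n[[a]] <- c(adj_n[[a]], b); adj_e[[a]] <- c(adj_e[[a]], i)
    adj_n[[b]] <- c(adj_n[[b]], a); adj_e[[b]] <- c(adj_e[[b]], i)
  }
  internals <- sort(unique(edge[edge > n]))
  if (!length(internals)) {  # two-leaf tree
    phy <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2),
                          tip.label = ut$labels, Nnode = 1L),
                     class = "phylo")
    if (use_lengths) phy$edge.length <- c(ut$length[1] / 2, ut$length[1] / 2)
    return(phy)
  }
  root <- internals[1]

  # preorder DFS assigning new internal ids n+1, n+2, ...
  new_id <- integer(max_id)
  new_id[seq_len(n)] <- seq_len(n)
  next_int <- n
  parent <- integer(max_id)
  stack <- root
  parent[root] <- root
  ord <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    if (v > n) { next_int <- next_int + 1L; new_id[v] <- next_int }
    kids <- adj_n[[v]][parent[adj_n[[v]]] == 0L]
    kids <- setdiff(kids, root)
    if (length(kids)) {
      parent[kids] <- v
      stack <- c(stack, rev(kids))
    }
  }

  rows <- ord[ord != root]
  out_edge <- cbind(new_id[parent[rows]], new_id[rows])
  eidx <- vapply(rows, function(v) adj_e[[v]][match(parent[v], adj_n[[v]])],
                 integer(1))
  phy <- structure(list(edge = out_edge, tip.label = ut$labels,
                        Nnode = next_int - n), class = "phylo")
  if (use_lengths && !all(is.na(ut$length)))
    phy$edge.length <- ut$length[eidx]
  if (use_supports) {
    nl <- rep("", next_int - n)
    int_rows <- which(out_edge[, 2] > n)
    s <- ut$support[eidx[int_rows]]
    nl[out_edge[int_rows, 2] - n] <- ifelse(is.na(s), "", format(s, digits = 10))
    phy$node.label <- nl
  }
  phy
}
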