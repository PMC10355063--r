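# Independent oracles used across the suite. These deliberately avoid the
# package's own path machinery: distances go through igraph's shortest
# paths on an explicitly built graph, splits through per-edge component
# enumeration, and tree spaces through exhaustive insertion.

# weighted leaf-to-leaf distances by graph search (igraph), with the same
# unrooted semantics: a degree-2 root's two edges act as one edge
oracle_dists <- function(phy, mode = "internode", missing_support = 1,
                         normalization = "none") {
  n <- length(phy$tip.label)
  edge <- phy$edge
  w <- switch(mode,
    internode = rep(1, nrow(edge)),
    support = {
      s <- rep(1, nrow(edge))
      lab <- suppressWarnings(as.numeric(phy$node.label))
      int <- edge[, 2] > n
      s[int] <- lab[edge[int, 2] - n]
      s[is.na(s)] <- missing_support
      s
    },
    length = phy$edge.length)
  root <- n + 1L
  rr <- which(edge[, 1] == root)
  if (length(rr) == 2L) {
    mw <- switch(mode,
      internode = 1,
      support = {
        if (any(edge[rr, 2] <= n)) 1 else {  # leaf-incident merged edge
          both <- w[rr]
          lab <- suppressWarnings(as.numeric(phy$node.label))
          defined <- !is.na(lab[edge[rr, 2] - n])
          if (any(defined)) mean(both[defined]) else missing_support
        }
      },
      length = sum(w[rr]))
    edge <- rbind(edge[-rr, , drop = FALSE], edge[rr, 2])
    w <- c(w[-rr], mw)
  }
  if (mode == "length" && normalization == "max_path") {
    gl <- igraph::graph_from_edgelist(edge, directed = FALSE)
    dl <- igraph::distances(gl, v = seq_len(n), to = seq_len(n), weights = w)
    w <- w / max(dl)  # brute-force diameter over all leaf pairs
  }
  g <- igraph::graph_from_edgelist(edge, directed = FALSE)
  d <- igraph::distances(g, v = seq_len(n), to = seq_len(n), weights = w)
  dimnames(d) <- list(phy$tip.label, phy$tip.label)
  d
}

# non-trivial splits by deleting each edge and reading the components
oracle_splits <- function(phy) {
  n <- length(phy$tip.label)
  edge <- phy$edge
  root <- n + 1L
  rr <- which(edge[, 1] == root)
  if (length(rr) == 2L) {
    edge <- rbind(edge[-rr, , drop = FALSE], edge[rr, 2])
  }
  ref <- sort(phy$tip.label)[1]
  nv <- max(edge)
  out <- character(0)
  for (e in seq_len(nrow(edge))) {
    g <- igraph::make_undirected_graph(t(edge[-e, , drop = FALSE]), n = nv)
    comp <- igraph::components(g)$membership
    side <- which(comp == comp[edge[e, 1]])
    side <- side[side <= n]
    if (length(side) < 2 || length(side) > n - 2) next
    labs <- phy$tip.label[side]
    if (ref %in% labs) labs <- setdiff(phy$tip.label, labs)
    out <- c(out, paste(sort(labs), collapse = "\r"))
  }
  unique(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# all unrooted binary topologies on taxa 1..n as edge matrices
# (internal ids > n), built by exhaustive sequential insertion
enumerate_topologies <- function(n) {
  stopifnot(n >= 3, n <= 8)
  trees <- list(cbind(n + 1L, 1:3))
  next_int <- n + 1L
  for (x in seq_len(n)[-(1:3)]) {
    next_int <- next_int + 1L
    trees <- unlist(lapply(trees, function(edge) {
      lapply(seq_len(nrow(edge)), function(e) {
        cand <- rbind(edge, c(next_int, edge[e, 2]), c(next_int, x))
        cand[e, 2] <- next_int
        cand
      })
    }), recursive = FALSE)
  }
  trees
}

# random gene tree with supports in [0,1] as node labels, optional
# polytomies (by collapsing short edges), positive lengths
rand_gene_tree <- function(n, polytomies = FALSE) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  if (polytomies) {
    short <- tr$edge.length < 0.25 & tr$edge[, 2] > n
    tr$edge.length[short] <- 0
    tr <- ape::di2multi(tr, tol = 1e-12)
    tr$edge.length <- pmax(tr$edge.length, 0.05)
  }
  tr$node.label <- formatC(stats::runif(tr$Nnode), digits = 6, format = "f")
  tr
}

# symmetric positive "random distance" matrix, zero diagonal
rand_sym_matrix <- function(n, lo = 0.5, hi = 2) {
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2, lo, hi)
  D <- D + t(D)
  dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
  D
}

# additive matrix of a tree, with its minimum branch length
additive_instance <- function(n, seed = NULL) {
  sp <- random_species_tree(n, seed = seed)
  D <- ape::cophenetic.phylo(sp)
  list(tree = sp, D = D[sp$tip.label, sp$tip.label],
       min_bl = min(sp$edge.length))
}

# symmetric entrywise noise with max-norm below `eps`
perturb <- function(D, eps) {
  n <- nrow(D)
  E <- matrix(0, n, n)
  E[upper.tri(E)] <- stats::runif(n * (n - 1) / 2, -eps, eps)
  E <- E + t(E)
  D + E
}

# a uniformly random binary topology over the given labels
rand_topology <- function(labels) {
  ape::rtree(length(labels), tip.label = sample(labels))
}
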