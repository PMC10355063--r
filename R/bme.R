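# Balanced minimum evolution search.
#
# Search trees are unrooted binary trees held as plain m x 2 integer edge
# matrices: leaves are rows/cols of the distance matrix (1..n), internal
# ids are > n. The Pauplin (balanced) length of a topology given a
# distance matrix D is
#
#     L(T) = sum_{u<v} 2^(1 - p_uv) D[u, v]
#
# with p_uv the number of edges between leaves u and v. On an additive
# matrix L(T) equals the total branch length of the generating tree, and
# every accepted NNI/SPR move strictly decreases L.

bme_score <- function(edge, D, present = NULL) {
  nl <- nrow(D)
  lm <- integer(max(edge))
  lm[seq_len(nl)] <- seq_len(nl)
  p <- leaf_path_sums_cpp(edge, rep(1, nrow(edge)), lm, nl)
  if (!is.null(present)) {
    p <- p[present, present, drop = FALSE]
    D <- D[present, present, drop = FALSE]
  }
  ut <- upper.tri(p)
  sum(2^(1 - p[ut]) * D[ut])
}

# phylo (binary, unrooted semantics) -> search edge matrix in the index
# space of `labels`
phylo_to_search <- function(tree, labels) {
  ut <- as_utree(tree)
  if (!setequal(ut$labels, labels))
    stop("tree leaf set does not match the distance matrix")
  n <- ut$n_leaf
  perm <- match(ut$labels, labels)
  edge <- ut$edge
  leaf <- edge <= n
  edge[leaf] <- perm[edge[leaf]]
  edge
}

search_to_phylo <- function(edge, labels) {
  n <- length(labels)
  ut <- list(edge = edge, length = rep(NA_real_, nrow(edge)),
             support = rep(NA_real_, nrow(edge)),
             leaf_edge = edge[, 1] <= n | edge[, 2] <= n,
             n_leaf = n, labels = labels)
  utree_to_phylo(ut, use_lengths = FALSE)
}

#' Pauplin (balanced) length of a tree
#'
#' Evaluates the balanced minimum evolution objective
#' `sum over u < v of 2^(1 - p_uv) * D[u, v]`, where `p_uv` counts the
#' edges between leaves `u` and `v` in the unrooted tree. By Pauplin's
#' theorem this equals the total branch length when `D` is the additive
#' matrix of the tree.
#'
#' @param tree a binary `phylo` tree over the row labels of `D` (a
#'   degree-2 root is suppressed).
#' @param D complete symmetric distance matrix with dimnames.
#' @return the balanced length (scalar).
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):0);")
#' D <- ape::cophenetic.phylo(tr)
#' pauplin_length(tr, D[tr$tip.label, tr$tip.label])
#' @export
pauplin_length <- function(tree, D) {
  labels <- rownames(D)
  edge <- phylo_to_search(tree, labels)
  deg <- tabulate(edge, nbins = max(edge))
  n <- length(labels)
  if (any(deg[seq_len(n)] != 1L) || any(deg[-seq_len(n)][deg[-seq_len(n)] > 0] != 3L))
    stop("pauplin_length requires a binary (fully resolved) tree")
  bme_score(edge, D)
}

#' Greedy taxon-insertion starting tree for BME
#'
#' Starts from the unique unrooted tree on the first three taxa of the
#' insertion order and inserts every remaining taxon on the edge whose
#' subdivision minimizes the Pauplin length of the grown tree. Ties are
#' broken by edge enumeration order, so the result is deterministic given
#' the order.
#'
#' @param D complete symmetric distance matrix with dimnames (or an
#'   `avg_dist` with no missing entries).
#' @param insertion_order `"matrix"` (row order, default) or `"random"`.
#' @param seed RNG seed used when `insertion_order = "random"`.
#' @return a binary `phylo` tree with attribute `"balanced_length"`.
#' @export
greedy_bme <- function(D, insertion_order = c("matrix", "random"), seed = NULL) {
  D <- as_complete_matrix(D)
  insertion_order <- match.arg(insertion_order)
  n <- nrow(D)
  labels <- rownames(D)
  if (n < 3) {
    warning("fewer than 3 taxa; trivial tree returned")
    txt <- if (n == 2) paste0("(", labels[1], ",", labels[2], ");") else
      paste0("(", labels[1], ");")
    return(ape::read.tree(text = txt))
  }
  ord <- seq_len(n)
  if (insertion_order == "random") {
    if (!is.null(seed)) set.seed(seed)
    ord <- sample.int(n)
  }
  edge <- cbind(n + 1L, ord[1:3])
  next_int <- n + 1L
  for (j in seq_len(n)[-(1:3)]) {
    x <- ord[j]
    present <- ord[seq_len(j)]
    next_int <- next_int + 1L
    best <- Inf; best_edge <- NULL
    for (e in seq_len(nrow(edge))) {
      cand <- rbind(edge, c(next_int, edge[e, 2]), c(next_int, x))
      cand[e, 2] <- next_int
      s <- bme_score(cand, D, present)
      if (s < best) { best <- s; best_edge <- cand }
    }
    edge <- best_edge
  }
  out <- search_to_phylo(edge, labels)
  attr(out, "balanced_length") <- bme_score(edge, D)
  out
}

# --- local moves -----------------------------------------------------------

# rows of `edge` incident to node v
incident_rows <- function(edge, v) which(edge[, 1] == v | edge[, 2] == v)

swap_endpoint <- function(edge, row, from, to) {
  if (edge[row, 1] == from) edge[row, 1] <- to else edge[row, 2] <- to
  edge
}

# component of `v` after deleting edge row `e` (node ids)
side_of <- function(edge, e, v) {
  adj <- edge[-e, , drop = FALSE]
  comp <- v
  frontier <- v
  while (length(frontier)) {
    hit <- adj[, 1] %in% frontier | adj[, 2] %in% frontier
    nxt <- setdiff(as.vector(adj[hit, ]), comp)
    adj <- adj[!hit, , drop = FALSE]
    comp <- c(comp, nxt)
    frontier <- nxt
  }
  comp
}

# one steepest-descent NNI pass structure shared by bnni()
nni_candidates <- function(edge, n) {
  int_rows <- which(edge[, 1] > n & edge[, 2] > n)
  out <- list()
  for (e in int_rows) {
    a <- edge[e, 1]; b <- edge[e, 2]
    ia <- setdiff(incident_rows(edge, a), e)
    ib <- setdiff(incident_rows(edge, b), e)
    for (rb in ib) {
      cand <- swap_endpoint(edge, ia[2], a, b)
      cand <- swap_endpoint(cand, rb, b, a)
      out[[length(out) + 1L]] <- cand
    }
  }
  out
}

#' NNI local search under balanced minimum evolution
#'
#' Repeatedly applies, among the two nearest-neighbour-interchange
#' alternatives of every internal edge, the move with the largest decrease
#' in Pauplin length, until no move decreases the score by more than the
#' tolerance. The score is non-increasing across accepted moves.
#'
#' @param tree binary `phylo` starting tree over the labels of `D`.
#' @param D complete symmetric distance matrix with dimnames.
#' @param tol relative score-decrease threshold for accepting a move
#'   (absolute threshold is `tol * current score`).
#' @param max_iter sweep cap; exceeding it returns the best tree so far
#'   with attribute `"converged" = FALSE` and a warning.
#' @return a binary `phylo` with attributes `"balanced_length"` and
#'   `"converged"`.
#' @export
bnni <- function(tree, D, tol = 1e-10, max_iter = 1000L) {
  D <- as_complete_matrix(D)
  edge <- phylo_to_search(tree, rownames(D))
  res <- bnni_edge(edge, nrow(D), D, tol, max_iter)
  out <- search_to_phylo(res$edge, rownames(D))
  attr(out, "balanced_length") <- res$score
  attr(out, "converged") <- res$converged
  out
}

bnni_edge <- function(edge, n, D, tol = 1e-10, max_iter = 1000L) {
  score <- bme_score(edge, D)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cands <- nni_candidates(edge, n)
    if (!length(cands)) { converged <- TRUE; break }
    scores <- vapply(cands, bme_score, numeric(1), D = D)
    best <- which.min(scores)
    if (score - scores[best] > tol * abs(score)) {
      edge <- cands[[best]]
      score <- scores[best]
    } else {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("bnni: max_iter reached before local optimum")
  list(edge = edge, score = score, converged = converged)
}

# one steepest SPR pass; returns NULL when no move improves
spr_pass <- function(edge, n, D, score, tol) {
  best <- score; best_edge <- NULL
  m <- nrow(edge)
  for (e in seq_len(m)) {
    for (dir in 1:2) {
      u <- edge[e, dir]; v <- edge[e, 3 - dir]
      if (u <= n) next  # pruning must leave a suppressible degree-3 node
      sub <- side_of(edge, e, v)
      ru <- setdiff(incident_rows(edge, u), e)
      p <- setdiff(as.vector(edge[ru[1], ]), u)
      q <- setdiff(as.vector(edge[ru[2], ]), u)
      # detach: drop row e and row ru[2]; row ru[1] becomes the merged edge
      base <- edge
      base[ru[1], ] <- c(p, q)
      base <- base[-c(e, ru[2]), , drop = FALSE]
      in_sub <- base[, 1] %in% sub & base[, 2] %in% sub
      merged_row <- which(base[, 1] == p & base[, 2] == q)
      for (t in seq_len(nrow(base))) {
        if (in_sub[t] || t == merged_row) next
        x <- base[t, 1]; y <- base[t, 2]
        cand <- rbind(base, c(u, y), c(u, v))
        cand[t, ] <- c(x, u)
        s <- bme_score(cand, D)
        if (best - s > tol * abs(best) && s < best) { best <- s; best_edge <- cand }
      }
    }
  }
  if (is.null(best_edge)) NULL else list(edge = best_edge, score = best)
}

#' SPR + NNI local search under balanced minimum evolution
#'
#' Steepest-descent subtree-prune-and-regraft search interleaved with NNI:
#' NNI runs to a local optimum, then one SPR pass is tried; the cycle
#' repeats until neither move set improves the score by more than the
#' tolerance.
#'
#' @inheritParams bnni
#' @return a binary `phylo` with attributes `"balanced_length"` and
#'   `"converged"`.
#' @export
bspr <- function(tree, D, tol = 1e-10, max_iter = 1000L) {
  D <- as_complete_matrix(D)
  edge <- phylo_to_search(tree, rownames(D))
  res <- bspr_edge(edge, nrow(D), D, tol, max_iter)
  out <- search_to_phylo(res$edge, rownames(D))
  attr(out, "balanced_length") <- res$score
  attr(out, "converged") <- res$converged
  out
}

bspr_edge <- function(edge, n, D, tol = 1e-10, max_iter = 1000L) {
  res <- bnni_edge(edge, n, D, tol, max_iter)
  repeat {
    stepped <- spr_pass(res$edge, n, D, res$score, tol)
    if (is.null(stepped)) break
    res <- bnni_edge(stepped$edge, n, D, tol, max_iter)
  }
  res
}

#' Balanced minimum evolution tree search
#'
#' The full search used on average intertaxon distance matrices: greedy
#' taxon insertion to build a starting tree, NNI moves to a local optimum,
#' and (by default) SPR passes interleaved with further NNI until no move
#' improves the Pauplin length. The search has a positive safety radius:
#' on a matrix close enough (in max-norm) to the additive matrix of a
#' binary tree it returns that tree's topology.
#'
#' @param D complete symmetric distance matrix with dimnames, or a
#'   complete `avg_dist`.
#' @param moves `"nni_spr"` (default, the accurate setting) or `"nni"`.
#' @param insertion_order,seed see [greedy_bme].
#' @param tol,max_iter see [bnni].
#' @return a binary `phylo` species tree with attribute
#'   `"balanced_length"`.
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
#' D <- ape::cophenetic.phylo(tr)
#' st <- bme_search(D)
#' attr(st, "balanced_length")  # equals the total branch length: 6
#' @export
bme_search <- function(D, moves = c("nni_spr", "nni"),
                       insertion_order = c("matrix", "random"), seed = NULL,
                       tol = 1e-10, max_iter = 1000L) {
  moves <- match.arg(moves)
  D <- as_complete_matrix(D)
  n <- nrow(D)
  start <- greedy_bme(D, insertion_order, seed)
  if (n < 4) {
    attr(start, "balanced_length") <- if (n == 3) bme_score(
      phylo_to_search(start, rownames(D)), D) else NA_real_
    return(start)
  }
  edge <- phylo_to_search(start, rownames(D))
  res <- if (moves == "nni") bnni_edge(edge, n, D, tol, max_iter) else
    bspr_edge(edge, n, D, tol, max_iter)
  out <- search_to_phylo(res$edge, rownames(D))
  attr(out, "balanced_length") <- res$score
  attr(out, "converged") <- res$converged
  out
}

as_complete_matrix <- function(D) {
  if (inherits(D, "avg_dist")) {
    if (D$n_missing > 0)
      stop("distance matrix has missing entries; impute first ",
           "(see two_stage_completion)")
    D <- D$D
  }
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (anyNA(D)) stop("D must be complete (no NA entries)")
  D
}
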