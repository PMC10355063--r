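#' UPGMA* clustering of an incomplete distance matrix
#'
#' Agglomerative clustering restricted to cluster pairs with at least one
#' defined inter-cluster distance. Two clusters are candidates for joining
#' only if some pair `u` in one and `v` in the other has a defined entry;
#' the distance between candidate clusters is the arithmetic mean of all
#' such defined entries. At every step the joinable pair with minimum
#' average is merged; exact ties are broken by the lexicographically
#' smallest pair of cluster representatives (minimum member index), so the
#' result is deterministic. On a complete matrix this is classic
#' average-linkage UPGMA.
#'
#' @param D an `avg_dist` object, or a square symmetric matrix with `NA`
#'   marking missing entries (dimnames required).
#' @return the rooted join tree as a `phylo` (topology only).
#' @examples
#' D <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' upgma_star(D)  # joins {a,b} first
#' @export
upgma_star <- function(D) {
  D <- as_masked_matrix(D)
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 taxa")

  def <- !is.na(D); diag(def) <- FALSE
  check_definedness_connected(def, labels)

  # per cluster-pair defined sums and counts, merged Lance-Williams style
  S <- D; S[!def] <- 0
  N <- matrix(as.numeric(def), n, n)
  active <- rep(TRUE, n)
  rep_idx <- seq_len(n)              # smallest member index per cluster
  frag <- labels                     # newick fragment per cluster

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    A <- S[idx, idx, drop = FALSE] / N[idx, idx, drop = FALSE]  # NaN where N=0
    A[!is.finite(A)] <- Inf
    diag(A) <- Inf
    m0 <- min(A)
    if (!is.finite(m0))
      stop("definedness graph became disconnected during clustering")
    hits <- which(A == m0, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # lexicographic tie-break on sorted representative indices
    key <- cbind(pmin(rep_idx[idx[hits[, 1]]], rep_idx[idx[hits[, 2]]]),
                 pmax(rep_idx[idx[hits[, 1]]], rep_idx[idx[hits[, 2]]]))
    pick <- order(key[, 1], key[, 2])[1]
    a <- idx[hits[pick, 1]]; b <- idx[hits[pick, 2]]

    S[a, ] <- S[a, ] + S[b, ]; S[, a] <- S[, a] + S[, b]
    N[a, ] <- N[a, ] + N[b, ]; N[, a] <- N[, a] + N[, b]
    S[a, a] <- 0; N[a, a] <- 0
    active[b] <- FALSE
    rep_idx[a] <- min(rep_idx[a], rep_idx[b])
    frag[a] <- paste0("(", frag[a], ",", frag[b], ")")
  }
  ape::read.tree(text = paste0(frag[which(active)], ";"))
}

#' Topological leaf-to-leaf path lengths
#'
#' The matrix of edge counts between every pair of leaves in the unrooted
#' tree (a degree-2 root is suppressed first, so the root's two edges
#' count as one).
#'
#' @param tree a `phylo` over the taxa of interest.
#' @return symmetric integer-valued matrix with leaf labels as dimnames;
#'   off-diagonal entries are at least 2.
#' @export
topological_paths <- function(tree) {
  ut <- as_utree(tree)
  utree_path_sums(ut, rep(1, nrow(ut$edge)))
}

#' Fill missing entries of a distance matrix from a reference matrix
#'
#' Defined entries are copied verbatim — an originally defined entry is
#' never altered; each missing entry is replaced by the corresponding
#' entry of `A`.
#'
#' @param D an `avg_dist` object or matrix with `NA` for missing entries.
#' @param A complete matrix over the same taxa (matched by dimnames).
#' @return a complete symmetric matrix in the row order of `D`.
#' @export
complete_matrix <- function(D, A) {
  D <- as_masked_matrix(D)
  A <- A[rownames(D), colnames(D)]
  miss <- is.na(D)
  D[miss] <- A[miss]
  diag(D) <- 0
  D
}

#' Two-stage completion of an incomplete average distance matrix
#'
#' Imputation used when some taxon pair occurs together in no gene tree:
#' 1. cluster the masked matrix with [upgma_star], giving tree `U1`;
#' 2. complete `D` with the topological path lengths of `U1` (`D1`);
#' 3. run the balanced minimum evolution search with NNI moves only on
#'    `D1`, giving tree `U2`;
#' 4. complete `D` with the path lengths of `U2`, giving the final `D2`.
#'
#' Originally defined entries are preserved exactly through both stages.
#'
#' @param D an `avg_dist` with at least one missing entry (or masked
#'   matrix).
#' @param tol,max_iter search controls for the NNI pass (see [bnni]).
#' @return a list of class `completion` with elements `U1`, `U2` (trees),
#'   `A1`, `A2` (path-length matrices), `D1`, `D2` (completed matrices).
#' @export
two_stage_completion <- function(D, tol = 1e-10, max_iter = 1000L) {
  Dm <- as_masked_matrix(D)
  if (!anyNA(Dm)) stop("matrix is already complete; nothing to impute")
  U1 <- upgma_star(Dm)
  A1 <- topological_paths(U1)
  D1 <- complete_matrix(Dm, A1)
  U2 <- bme_search(D1, moves = "nni", tol = tol, max_iter = max_iter)
  A2 <- topological_paths(U2)
  D2 <- complete_matrix(Dm, A2)
  structure(list(U1 = U1, U2 = U2, A1 = A1, A2 = A2, D1 = D1, D2 = D2,
                 n_imputed = sum(is.na(Dm)[upper.tri(Dm)])),
            class = "completion")
}

#' @export
print.completion <- function(x, ...) {
  cat("Two-stage completion:", nrow(x$D2), "taxa,",
      x$n_imputed, "pair(s) imputed\n")
  invisible(x)
}

as_masked_matrix <- function(D) {
  if (inherits(D, "avg_dist")) D <- D$D
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (is.null(rownames(D)))
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  diag(D) <- 0
  D
}

check_definedness_connected <- function(def, labels) {
  n <- nrow(def)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(!seen & colSums(def[frontier, , drop = FALSE]) > 0)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(seen)) {
    stop("definedness graph is disconnected; no distances connect {",
         paste(labels[seen], collapse = ","), "} and {",
         paste(labels[!seen], collapse = ","), "}")
  }
  invisible(TRUE)
}
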