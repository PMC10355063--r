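#' Per-edge weights under a weighting mode
#'
#' Returns the contribution of every unrooted edge of a gene tree to the
#' intertaxon distance, under the selected mode:
#' * `internode` — every edge contributes 1 (classic edge-count distance);
#' * `support` — an internal edge contributes its support `s(e)`
#'   (normalized to `[0, 1]`); a leaf-incident edge contributes 1, since a
#'   trivial bipartition is always correct;
#' * `length` — an edge contributes its branch length `l(e)` divided by
#'   the gene-level scale (see [gene_scale]).
#'
#' A degree-2 root in the stored tree is suppressed first (lengths of its
#' two edges add; supports take the annotated one, or the product when
#' both are annotated), so the result never depends on root placement.
#'
#' @param tree a `phylo` gene tree (supports normalized for `support`
#'   mode; lengths present for `length` mode).
#' @param mode `"internode"`, `"support"` or `"length"`.
#' @param scale divisor for `length` mode, from [gene_scale].
#' @param missing_support value used for internal edges without a support
#'   annotation (default 1), with a warning.
#' @return numeric vector of weights, one per unrooted edge, with the
#'   edge matrix as attribute `"edge"`.
#' @export
edge_weights <- function(tree, mode = c("internode", "support", "length"),
                         scale = 1, missing_support = 1) {
  mode <- match.arg(mode)
  ut <- as_utree(tree)
  w <- switch(mode,
    internode = rep(1, nrow(ut$edge)),
    support = {
      s <- ut$support
      s[ut$leaf_edge] <- 1
      if (anyNA(s)) {
        warning(sum(is.na(s)), " internal edge(s) without support; using ",
                missing_support)
        s[is.na(s)] <- missing_support
      }
      if (any(s < 0 | s > 1))
        stop("supports must be normalized to [0,1]; see normalize_supports()")
      s
    },
    length = {
      if (anyNA(ut$length)) {
        bad <- which(is.na(ut$length))[1]
        stop("edge ", ut$edge[bad, 1], "-", ut$edge[bad, 2],
             " has no branch length (required in length mode)")
      }
      ut$length / scale
    })
  attr(w, "edge") <- ut$edge
  w
}

#' Gene-level branch-length scale
#'
#' For `length` mode, the per-gene divisor applied to all branch lengths.
#' With `normalization = "max_path"` this is the branch-length diameter of
#' the gene tree (the maximum over leaf pairs of the path-length sum),
#' found by a two-sweep farthest-leaf search in O(n); with `"none"` it
#' is 1.
#'
#' @param tree a `phylo` gene tree with branch lengths.
#' @param normalization `"max_path"` or `"none"`.
#' @return a positive scalar.
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,c:1,d:1);")
#' gene_scale(tr)  # diameter: 1 + 1 + 1 = 3
#' @export
gene_scale <- function(tree, normalization = c("max_path", "none")) {
  normalization <- match.arg(normalization)
  if (normalization == "none") return(1)
  ut <- as_utree(tree)
  if (anyNA(ut$length)) stop("branch lengths required for max_path normalization")
  d1 <- utree_sssp(ut, ut$length, 1L)
  far <- which.max(d1[seq_len(ut$n_leaf)])
  d2 <- utree_sssp(ut, ut$length, far)
  diam <- max(d2[seq_len(ut$n_leaf)])
  if (!is.finite(diam) || diam <= 0)
    stop("gene tree has zero branch-length diameter; cannot normalize")
  diam
}

#' Weighted intertaxon distances within one gene tree
#'
#' Computes, for every pair of leaves `u, v` of the gene tree, the sum of
#' edge weights along the path connecting them, in one post-order
#' traversal costing O(L^2) for L leaves. Polytomies are handled by
#' combining all unordered child pairs at each node.
#'
#' @inheritParams edge_weights
#' @param normalization branch-length normalization for `length` mode.
#' @return symmetric numeric matrix with leaf labels as dimnames and zero
#'   diagonal; attribute `"pair_ops"` counts leaf-pair combination steps.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' per_gene_distances(tr, "internode")  # d(a,b) = 2, d(a,c) = 3
#' @export
per_gene_distances <- function(tree, mode = c("internode", "support", "length"),
                               normalization = c("max_path", "none"),
                               missing_support = 1) {
  mode <- match.arg(mode)
  n <- length(tree$tip.label)
  if (n < 2) {
    warning("gene tree has fewer than 2 leaves; empty table")
    d <- matrix(numeric(0), 0, 0)
    return(d)
  }
  scale <- if (mode == "length") gene_scale(tree, normalization) else 1
  w <- edge_weights(tree, mode, scale = scale, missing_support = missing_support)
  ut <- as_utree(tree)
  utree_path_sums(ut, as.numeric(w))
}

#' Average the per-gene distance tables
#'
#' Aggregates per-gene tables into the n x n average matrix over the taxon
#' registry. For each taxon pair the average runs over exactly the genes
#' containing both taxa; pairs present in no gene are flagged missing.
#' Summation order is the gene order, so results are deterministic.
#'
#' @param tables list of matrices from [per_gene_distances] (labelled).
#' @param registry character vector of all taxon labels; defaults to the
#'   union of table labels in first-appearance order.
#' @return an object of class `avg_dist`: list with elements `D` (average,
#'   `NA` where undefined), `S` (sums), `C` (per-pair gene counts),
#'   `labels`, and `n_missing` (count of undefined off-diagonal pairs,
#'   unordered).
#' @export
accumulate <- function(tables, registry = NULL) {
  if (!length(tables)) stop("no distance tables given")
  if (is.null(registry))
    registry <- unique(unlist(lapply(tables, rownames)))
  n <- length(registry)
  S <- matrix(0, n, n, dimnames = list(registry, registry))
  C <- matrix(0L, n, n, dimnames = list(registry, registry))
  for (tab in tables) {
    idx <- match(rownames(tab), registry)
    if (anyNA(idx)) stop("table contains labels outside the registry")
    S[idx, idx] <- S[idx, idx] + tab
    C[idx, idx] <- C[idx, idx] + 1L
  }
  diag(C) <- 0L
  D <- matrix(NA_real_, n, n, dimnames = list(registry, registry))
  def <- C > 0L
  D[def] <- S[def] / C[def]
  diag(D) <- 0
  structure(list(D = D, S = S, C = C, labels = registry,
                 n_missing = sum(C[upper.tri(C)] == 0L)),
            class = "avg_dist")
}

#' @export
print.avg_dist <- function(x, ...) {
  n <- length(x$labels)
  cat("Average intertaxon distance matrix: ", n, " taxa, ",
      x$n_missing, " missing pair(s)\n", sep = "")
  invisible(x)
}

#' Write a distance matrix in PHYLIP square format
#'
#' Missing entries (undefined pairs) are written as the sentinel token.
#'
#' @param x an `avg_dist` object or a square matrix with dimnames.
#' @param file output path.
#' @param sentinel token used for missing entries.
#' @export
write_phylip_dist <- function(x, file, sentinel = "NA") {
  D <- if (inherits(x, "avg_dist")) x$D else x
  labs <- rownames(D)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(format(nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    vals <- ifelse(is.na(D[i, ]), sentinel, format(D[i, ], digits = 10, trim = TRUE))
    writeLines(paste(c(sprintf("%-10s", labs[i]), vals), collapse = " "), con)
  }
  invisible(file)
}

#' Read a PHYLIP square distance matrix
#'
#' @param file path to a PHYLIP square matrix; the sentinel token (or any
#'   non-numeric entry) is read as missing.
#' @return an `avg_dist` object (counts are 1 where defined, 0 where
#'   missing).
#' @export
read_phylip_dist <- function(file) {
  lines <- readLines(file, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  labs <- character(n)
  D <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    labs[i] <- parts[1]
    D[i, ] <- suppressWarnings(as.numeric(parts[-1][seq_len(n)]))
  }
  dimnames(D) <- list(labs, labs)
  diag(D) <- 0
  C <- matrix(as.integer(!is.na(D)), n, n, dimnames = dimnames(D))
  diag(C) <- 0L
  S <- D; S[is.na(S)] <- 0
  structure(list(D = D, S = S, C = C, labels = labs,
                 n_missing = sum(C[upper.tri(C)] == 0L)),
            class = "avg_dist")
}
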