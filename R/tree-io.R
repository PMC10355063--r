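#' Read a file of gene trees
#'
#' Reads a multi-tree newick source (one unrooted gene tree per line) into
#' a `multiPhylo` list. Branch support annotations on internal edges are
#' read either from internal node labels (the FastTree/IQ-TREE convention,
#' the default) or from bracketed comments of the form `[0.95]` or
#' `[&support=0.95]` placed after the closing parenthesis of a clade.
#' Absent annotations are recorded as absent, never as 0.
#'
#' The returned object carries a taxon registry: the union of all leaf
#' labels in first-appearance order across the file. All matrices produced
#' downstream are indexed in registry order, which makes runs
#' deterministic.
#'
#' Storage is rooted (as newick requires) but all semantics downstream are
#' unrooted; no result depends on root placement.
#'
#' @param source path to a newick file, or a character vector of newick
#'   strings (anything containing `";"` is treated as newick text).
#' @param support_dialect `"node_label"` (default) or `"comment"`.
#' @return a `multiPhylo` list of trees, with attribute `"registry"`
#'   (character vector of taxon labels).
#' @examples
#' gts <- read_gene_trees(c("((a,b),(c,d));", "((a,c),(b,d));"))
#' attr(gts, "registry")
#' @export
read_gene_trees <- function(source, support_dialect = c("node_label", "comment")) {
  support_dialect <- match.arg(support_dialect)
  if (length(source) == 1L && !grepl(";", source)) {
    if (!file.exists(source)) stop("file not found: ", source)
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no trees found in input")

  if (support_dialect == "comment") {
    # hoist bracketed support comments into node-label position
    lines <- gsub("\\)\\[&?(?:support=)?([0-9.eE+-]+)\\]", ")\\1", lines)
    lines <- gsub("\\[[^]]*\\]", "", lines)  # drop any remaining comments
  }

  trees <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tr <- tryCatch(ape::read.tree(text = lines[i]),
                   error = function(e) NULL)
    if (is.null(tr))
      stop("malformed newick on line ", i)
    if (anyDuplicated(tr$tip.label))
      stop("duplicate leaf label in tree on line ", i, ": ",
           paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
    if (any(!nzchar(tr$tip.label)))
      stop("empty leaf label in tree on line ", i)
    trees[[i]] <- tr
  }
  registry <- unique(unlist(lapply(trees, `[[`, "tip.label")))
  class(trees) <- "multiPhylo"
  attr(trees, "registry") <- registry
  trees
}

#' Write a tree as newick text
#'
#' Edge lengths, when present, are printed with enough significant digits
#' that parsing the output reproduces the tree exactly (round-trip safe).
#'
#' @param tree a `phylo` tree.
#' @param file optional path; when `NULL` the newick string is returned.
#' @return the newick string, invisibly when written to a file.
#' @export
write_tree <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Support scales
#'
#' Supported raw-support scales and their affine maps onto `[0, 1]`:
#' * `raw01`: values already in `[0, 1]`, used unchanged;
#' * `percent100`: bootstrap-style percentages in `[0, 100]`, divided by 100;
#' * `abayes`: approximate Bayesian supports, whose analytic minimum is
#'   1/3; mapped linearly so that 1/3 becomes 0 and 1 stays 1, i.e.
#'   `(s - 1/3) / (2/3)`;
#' * `none`: the tree carries no usable supports; every internal edge is
#'   assigned the `missing` policy value.
#'
#' @name support_scales
NULL

scale_to_unit <- function(s, scale, tol = 1e-9) {
  switch(scale,
    raw01 = {
      bad <- which(!is.na(s) & (s < -tol | s > 1 + tol))
      if (length(bad))
        stop("support outside [0,1] on edge ", bad[1], ": ", s[bad[1]])
      pmin(pmax(s, 0), 1)
    },
    percent100 = {
      bad <- which(!is.na(s) & (s < -tol | s > 100 + tol))
      if (length(bad))
        stop("support outside [0,100] on edge ", bad[1], ": ", s[bad[1]])
      pmin(pmax(s / 100, 0), 1)
    },
    abayes = {
      bad <- which(!is.na(s) & (s < 1 / 3 - tol | s > 1 + tol))
      if (length(bad))
        stop("aBayes support outside [1/3,1] on edge ", bad[1], ": ", s[bad[1]])
      pmin(pmax((s - 1 / 3) / (2 / 3), 0), 1)
    },
    none = rep(NA_real_, length(s)),
    stop("unknown support scale: ", scale)
  )
}

#' Normalize branch supports onto \[0, 1\]
#'
#' Maps the raw internal-edge supports of a gene tree onto `[0, 1]` under
#' the declared scale (see [support_scales]). Leaf-incident edges always
#' have implicit support 1 and carry no annotation. Internal edges with no
#' annotation receive the `missing` policy value (default 1, i.e. fully
#' trusted, which degrades gracefully to unweighted behaviour) with a
#' warning.
#'
#' @param tree a `phylo` gene tree whose node labels hold raw supports.
#' @param scale one of `"raw01"`, `"percent100"`, `"abayes"`, `"none"`.
#' @param missing value in `[0, 1]` substituted for absent internal
#'   supports.
#' @param quiet suppress the missing-support warning.
#' @return the tree with numeric node labels in `[0, 1]`.
#' @examples
#' tr <- read_gene_trees("((a:1,b:1)0.9:0.5,c:1,d:1);")[[1]]
#' normalize_supports(tr, "raw01")
#' @export
normalize_supports <- function(tree, scale = c("raw01", "percent100", "abayes", "none"),
                               missing = 1, quiet = FALSE) {
  scale <- match.arg(scale)
  stopifnot(missing >= 0, missing <= 1)
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  raw <- rep(NA_real_, nn)
  if (!is.null(tree$node.label)) {
    raw <- suppressWarnings(as.numeric(tree$node.label))
    length(raw) <- nn
  }
  s <- scale_to_unit(raw, scale)

  # only labels that annotate an internal *edge* matter: the root label
  # (and, for a degree-2 root, effectively the merged edge) is handled at
  # path-computation time; here we fill every internal slot.
  root_deg <- sum(tree$edge[, 1] == n + 1L)
  internal_slots <- setdiff(seq_len(nn), if (root_deg >= 2L) 1L else integer(0))
  n_missing <- sum(is.na(s[internal_slots]))
  if (n_missing > 0) {
    s[is.na(s)] <- missing
    if (!quiet && scale != "none")
      warning(n_missing, " internal edge(s) without support; using ", missing)
    if (scale == "none") s[] <- missing
  }
  s[is.na(s)] <- missing
  tree$node.label <- format(s, digits = 10, trim = TRUE)
  attr(tree, "supports_normalized") <- TRUE
  tree
}
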