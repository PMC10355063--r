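#' Infer a species tree from gene trees
#'
#' The full pipeline: read gene trees, normalize supports (support mode),
#' compute per-gene weighted intertaxon distances, average them over the
#' genes containing each pair, impute missing entries when necessary (see
#' [two_stage_completion]), and search for the species tree under balanced
#' minimum evolution.
#'
#' Modes mirror the three intertaxon distances:
#' `"internode"` (edge counts, the unweighted distance), `"support"`
#' (each internal edge contributes its support; the recommended default),
#' and `"length"` (branch lengths, by default normalized per gene by the
#' maximum path length).
#'
#' @param genes path to a newick file, newick text, or a
#'   `multiPhylo`/list of `phylo` gene trees.
#' @param mode `"support"`, `"internode"` or `"length"`.
#' @param support_scale raw support scale for `support` mode (see
#'   [support_scales]).
#' @param support_dialect passed to [read_gene_trees] when `genes` is a
#'   path or text.
#' @param missing_support value substituted for absent internal supports.
#' @param normalization branch-length normalization for `length` mode.
#' @param imputation `"auto"` (impute when the matrix is incomplete) or
#'   `"off"` (incomplete input becomes an error).
#' @param moves,insertion_order,seed,tol,max_iter search controls (see
#'   [bme_search]).
#' @return an object of class `wastrid_run`: list with `tree` (the
#'   unrooted binary `phylo` species tree), `report` (run statistics) and
#'   `matrix` (the `avg_dist` average matrix).
#' @examples
#' gts <- c("((a,b),(c,d));", "((a,b),(c,d));", "((a,c),(b,d));")
#' run <- infer_species_tree(gts, mode = "internode")
#' write_tree(run$tree)
#' @export
infer_species_tree <- function(genes,
                               mode = c("support", "internode", "length"),
                               support_scale = c("raw01", "percent100", "abayes", "none"),
                               support_dialect = c("node_label", "comment"),
                               missing_support = 1,
                               normalization = c("max_path", "none"),
                               imputation = c("auto", "off"),
                               moves = c("nni_spr", "nni"),
                               insertion_order = c("matrix", "random"),
                               seed = NULL, tol = 1e-10, max_iter = 1000L) {
  mode <- match.arg(mode)
  support_scale <- match.arg(support_scale)
  imputation <- match.arg(imputation)
  moves <- match.arg(moves)
  insertion_order <- match.arg(insertion_order)
  t0 <- proc.time()[["elapsed"]]

  if (is.character(genes))
    genes <- read_gene_trees(genes, support_dialect = match.arg(support_dialect))
  registry <- attr(genes, "registry")
  if (is.null(registry))
    registry <- unique(unlist(lapply(genes, `[[`, "tip.label")))
  k <- length(genes)
  n <- length(registry)
  if (n < 4) stop("need at least 4 taxa across the gene trees")

  if (mode == "support")
    genes <- lapply(genes, normalize_supports, scale = support_scale,
                    missing = missing_support, quiet = TRUE)

  tables <- lapply(genes, per_gene_distances, mode = mode,
                   normalization = normalization,
                   missing_support = missing_support)
  tables <- tables[vapply(tables, nrow, integer(1)) >= 2]
  am <- accumulate(tables, registry)
  t1 <- proc.time()[["elapsed"]]

  imputed <- FALSE
  if (am$n_missing > 0) {
    if (imputation == "off")
      stop("average matrix has ", am$n_missing,
           " missing pair(s) and imputation is off")
    comp <- two_stage_completion(am, tol = tol, max_iter = max_iter)
    Dfinal <- comp$D2
    imputed <- TRUE
  } else {
    Dfinal <- am$D
  }
  t2 <- proc.time()[["elapsed"]]

  tree <- bme_search(Dfinal, moves = moves, insertion_order = insertion_order,
                     seed = seed, tol = tol, max_iter = max_iter)
  t3 <- proc.time()[["elapsed"]]

  report <- list(
    n_taxa = n, n_genes = k, mode = mode,
    support_scale = if (mode == "support") support_scale else NULL,
    normalization = if (mode == "length") normalization[1] else NULL,
    missing_pairs = am$n_missing, imputed = imputed,
    moves = moves, insertion_order = insertion_order,
    seed = seed,
    balanced_length = attr(tree, "balanced_length"),
    timings = list(distance = t1 - t0, imputation = t2 - t1,
                   search = t3 - t2, total = t3 - t0)
  )
  structure(list(tree = tree, report = report, matrix = am),
            class = "wastrid_run")
}

#' @export
print.wastrid_run <- function(x, ...) {
  r <- x$report
  cat("Species tree over", r$n_taxa, "taxa from", r$n_genes, "gene trees\n")
  cat("  mode:", r$mode,
      if (r$imputed) sprintf("(imputed %d missing pairs)", r$missing_pairs) else "",
      "\n")
  cat("  balanced length:", format(r$balanced_length, digits = 10), "\n")
  cat("  tree:", write_tree(x$tree), "\n")
  invisible(x)
}

#' Machine-readable run report
#'
#' Serializes the run report of [infer_species_tree] (configuration echo,
#' matrix statistics, final score, timings) as JSON with stable key
#' order.
#'
#' @param run a `wastrid_run` object.
#' @param file optional path to write to.
#' @return the JSON string, invisibly when written to a file.
#' @export
run_report <- function(run, file = NULL) {
  stopifnot(inherits(run, "wastrid_run"))
  json <- jsonlite::toJSON(run$report, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (!is.null(file)) {
    writeLines(json, file)
    return(invisible(json))
  }
  json
}
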