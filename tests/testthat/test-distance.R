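quartet <- ape::read.tree(text = "((a,b),(c,d));")

test_that("internode distances count edges on the unrooted tree", {
  d <- per_gene_distances(quartet, "internode")
  expect_equal(d["a", "b"], 2)
  expect_equal(d["a", "c"], 3)
  expect_equal(d["c", "d"], 2)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0, d = 0))
})

test_that("support mode sums supports with leaf edges fixed at 1", {
  # the rooted quartet's two root edges are the same unrooted edge: with
  # s = 0.5 annotated on both, d(a,c) = 1 + 0.5 + 1
  tr <- read_gene_trees("((a,b)0.5,(c,d)0.5);")[[1]]
  d <- per_gene_distances(tr, "support")
  expect_equal(d["a", "c"], 2.5)
  expect_equal(d["a", "b"], 2)
})

test_that("edge weights follow the declared mode", {
  tr <- read_gene_trees("((a:1,b:1)0.5:0.25,c:1,d:1);")[[1]]
  w_u <- edge_weights(tr, "internode")
  expect_true(all(w_u == 1))
  w_s <- edge_weights(tr, "support")
  expect_setequal(unique(w_s), c(1, 0.5))
  w_l <- edge_weights(tr, "length", scale = 2)
  expect_equal(sort(unique(w_l)), c(0.125, 0.5))
})

test_that("gene_scale finds the branch-length diameter", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:1,d:1);")
  expect_equal(gene_scale(tr), 3)
  star <- ape::read.tree(text = "(a:2,b:3,c:5);")
  expect_equal(gene_scale(star), 8)
  set.seed(21)
  for (i in 1:20) {
    tr <- rand_gene_tree(sample(5:30, 1))
    brute <- max(oracle_dists(tr, "length"))
    expect_equal(gene_scale(tr), brute, tolerance = 1e-9)
  }
  zero <- ape::read.tree(text = "(a:0,b:0,c:0);")
  expect_error(gene_scale(zero), "diameter")
})

test_that("per-gene distances equal the graph-search oracle in all modes", {
  set.seed(31)
  for (i in 1:50) {
    tr <- rand_gene_tree(sample(4:25, 1), polytomies = i %% 2 == 0)
    for (mode in c("internode", "support", "length")) {
      d <- per_gene_distances(tr, mode, normalization = "none")
      o <- oracle_dists(tr, mode)
      expect_equal(d, o[rownames(d), colnames(d)], tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
    dn <- per_gene_distances(tr, "length", normalization = "max_path")
    on <- oracle_dists(tr, "length", normalization = "max_path")
    expect_equal(dn, on[rownames(dn), colnames(dn)], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(max(dn), 1, tolerance = 1e-9)  # normalized diameter
  }
})

test_that("support mode with all supports 1 equals internode mode exactly", {
  set.seed(41)
  for (i in 1:10) {
    tr <- rand_gene_tree(sample(4:20, 1))
    tr$node.label <- rep("1", tr$Nnode)
    expect_identical(per_gene_distances(tr, "support"),
                     per_gene_distances(tr, "internode"))
  }
})

test_that("lowering one support weakly lowers exactly the paths using it", {
  set.seed(51)
  tr <- rand_gene_tree(10)
  tr$node.label <- rep("1", tr$Nnode)
  before <- per_gene_distances(tr, "support")
  # pick an internal node that is neither the root nor a root child, so
  # its parent edge is a plain internal edge
  root_kids <- tr$edge[tr$edge[, 1] == 11, 2]
  victim <- setdiff(12:(10 + tr$Nnode), root_kids)[1] - 10
  tr$node.label[victim] <- "0.4"
  after <- per_gene_distances(tr, "support")
  delta <- before - after
  expect_true(all(delta >= -1e-12))
  expect_true(any(delta > 0.5))
  expect_true(all(abs(delta[delta > 1e-12] - 0.6) < 1e-9))
})

test_that("pair-combination work is exactly choose(n,2) on binary trees", {
  set.seed(61)
  for (n in c(8, 16, 32)) {
    tr <- rand_gene_tree(n)
    d <- per_gene_distances(tr, "internode")
    expect_equal(attr(d, "pair_ops"), choose(n, 2))
  }
})

test_that("accumulate averages per pair over the genes containing it", {
  g1 <- ape::read.tree(text = "((a,b),(c,d));")
  g2 <- ape::read.tree(text = "((a,c),(b,d));")
  g3 <- ape::read.tree(text = "((a,b),(c,e));")
  tabs <- lapply(list(g1, g2, g3), per_gene_distances, mode = "internode")
  am <- accumulate(tabs)
  expect_equal(am$C["a", "b"], 3L)
  expect_equal(am$D["a", "b"], (2 + 3 + 2) / 3)
  expect_equal(am$C["d", "e"], 0L)          # never co-occur
  expect_true(is.na(am$D["d", "e"]))
  expect_equal(am$n_missing, 1L)
  expect_equal(am$D, t(am$D))
})

test_that("accumulate matches a naive double-loop over random gene subsets", {
  set.seed(71)
  taxa <- paste0("t", 1:12)
  genes <- lapply(1:20, function(i) {
    keep <- sample(taxa, sample(4:12, 1))
    tr <- ape::rtree(length(keep), tip.label = sample(keep))
    tr
  })
  tabs <- lapply(genes, per_gene_distances, mode = "internode")
  am <- accumulate(tabs, taxa)
  for (i in 1:11) for (j in (i + 1):12) {
    vals <- unlist(lapply(tabs, function(tb) {
      if (taxa[i] %in% rownames(tb) && taxa[j] %in% rownames(tb))
        tb[taxa[i], taxa[j]] else NULL
    }))
    if (length(vals)) {
      expect_equal(am$D[i, j], mean(vals))
      expect_equal(am$C[i, j], length(vals))
    } else {
      expect_true(is.na(am$D[i, j]))
    }
  }
})

test_that("phylip square export round-trips including missing entries", {
  g1 <- ape::read.tree(text = "((a,b),(c,d));")
  g2 <- ape::read.tree(text = "((a,b),(c,e));")
  am <- accumulate(lapply(list(g1, g2), per_gene_distances, mode = "internode"))
  f <- tempfile(fileext = ".phy")
  write_phylip_dist(am, f)
  back <- read_phylip_dist(f)
  expect_equal(back$D, am$D, tolerance = 1e-9)
  expect_equal(back$n_missing, am$n_missing)
})
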