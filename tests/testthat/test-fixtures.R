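test_that("random species trees are binary, seeded and reproducible", {
  sp <- random_species_tree(4, seed = 1)
  expect_equal(length(sp$tip.label), 4)
  expect_equal(sp$Nnode, 3)  # rooted binary
  expect_identical(write_tree(random_species_tree(9, seed = 5)),
                   write_tree(random_species_tree(9, seed = 5)))
  expect_true(all(random_species_tree(20, seed = 2)$edge.length > 0))
})

test_that("5-taxon topologies are generated uniformly", {
  set.seed(271)
  draws <- 3000
  keys <- character(draws)
  for (i in 1:draws) {
    sp <- random_species_tree(5)
    keys[i] <- paste(sort(bipartitions(sp)), collapse = "|")
  }
  tab <- table(keys)
  expect_length(tab, 15)  # all unrooted 5-leaf topologies appear
  p <- 1 / 15
  sigma <- sqrt(p * (1 - p) / draws)
  expect_true(all(abs(tab / draws - p) < 4 * sigma))
})

test_that("no ILS when internal branches are very long", {
  sp <- random_species_tree(10, seed = 7,
                            length_law = function(m) rep(25, m))
  gts <- msc_simulate(sp, 20, seed = 7)
  expect_equal(average_discordance(sp, gts), 0)
})

test_that("quartet concordance collapses to 1/3 at zero internal length", {
  k <- 1500
  sp <- ape::read.tree(text = "((A:1,B:1):1e-9,(C:1,D:1):1e-9);")
  sp$tip.label <- c("A", "B", "C", "D")
  gts <- msc_simulate(sp, k, seed = 11)
  match_ab <- vapply(gts, function(g) {
    d <- per_gene_distances(g, "internode")
    d["A", "B"] == 2
  }, logical(1))
  p <- mean(match_ab)
  expect_lt(abs(p - 1 / 3), 4 * sqrt(1 / 3 * 2 / 3 / k))
})

test_that("gene trees carry coalescent branch lengths and the full leaf set", {
  sp <- random_species_tree(8, seed = 13)
  gts <- msc_simulate(sp, 10, seed = 13)
  expect_length(gts, 10)
  for (g in gts) {
    expect_setequal(g$tip.label, sp$tip.label)
    expect_true(all(g$edge.length >= 0))
  }
})

test_that("inject_error leaves trees untouched at count 0 and flags edges", {
  sp <- random_species_tree(10, seed = 17)
  gts <- msc_simulate(sp, 5, seed = 17)
  clean <- inject_error(gts, count = 0, seed = 17, length_sd = 0)
  for (i in seq_along(gts)) {
    expect_equal(rf_distance(clean[[i]], gts[[i]]), 0)
    s <- suppressWarnings(as.numeric(clean[[i]]$node.label))
    expect_true(all(s[!is.na(s)] >= 0.6))  # all edges correct -> high law
  }
})

test_that("erroneous-edge flags coincide with splits absent from the truth", {
  set.seed(281)
  sp <- random_species_tree(12, seed = 19)
  gts <- msc_simulate(sp, 10, seed = 19)
  noisy <- inject_error(gts, count = 3, seed = 19)
  for (i in seq_along(gts)) {
    truth <- bipartitions(gts[[i]])
    tr <- noisy[[i]]
    ut <- wastrid:::as_utree(tr)
    n <- ut$n_leaf
    ref <- sort(ut$labels)[1]
    for (e in which(!ut$leaf_edge)) {
      side <- wastrid:::side_of(ut$edge, e, ut$edge[e, 1])
      side <- side[side <= n]
      labs <- ut$labels[side]
      if (ref %in% labs) labs <- setdiff(ut$labels, labs)
      key <- paste(sort(labs), collapse = "\r")
      s <- ut$support[e]
      if (key %in% truth) expect_gte(s, 0.6) else expect_lte(s, 0.7)
    }
  }
})

test_that("error severity grows with the number of NNI moves", {
  sp <- random_species_tree(14, seed = 23)
  gts <- msc_simulate(sp, 30, seed = 23)
  mean_err <- vapply(c(0, 2, 8), function(cnt) {
    noisy <- inject_error(gts, count = cnt, seed = 29)
    gtee(gts, noisy)
  }, numeric(1))
  expect_true(all(diff(mean_err) > 0))
})

test_that("iid deletion removes exactly m uniformly chosen taxa per gene", {
  sp <- random_species_tree(10, seed = 31)
  gts <- msc_simulate(sp, 400, seed = 31)
  del <- delete_iid(gts, m = 2, seed = 31)
  expect_true(all(vapply(del, function(t) length(t$tip.label), integer(1)) == 8))
  freq <- table(factor(unlist(lapply(del, `[[`, "tip.label")),
                       levels = sp$tip.label))
  p <- 8 / 10
  sigma <- sqrt(p * (1 - p) / 400)
  expect_true(all(abs(freq / 400 - p) < 4 * sigma))
  expect_error(delete_iid(gts, m = 7), "n - m >= 4")
})

test_that("clade deletion always retains a species-tree clade", {
  sp <- random_species_tree(16, seed = 37)
  gts <- msc_simulate(sp, 50, seed = 37)
  del <- delete_m_clade(gts, sp, x = 0.4, seed = 37)
  clades <- ape::prop.part(sp)
  clade_keys <- vapply(clades, function(i)
    paste(sort(sp$tip.label[i]), collapse = "|"), character(1))
  for (t in del) {
    key <- paste(sort(t$tip.label), collapse = "|")
    expect_true(key %in% clade_keys)
    expect_gte(length(t$tip.label), ceiling(0.4 * 16))
  }
})

test_that("larger x means less deletion on average; x = 1 deletes nothing", {
  sp <- random_species_tree(16, seed = 41)
  gts <- msc_simulate(sp, 80, seed = 41)
  frac_deleted <- vapply(c(0.2, 0.4, 0.6), function(x) {
    del <- delete_m_clade(gts, sp, x, seed = 43)
    1 - mean(vapply(del, function(t) length(t$tip.label), integer(1))) / 16
  }, numeric(1))
  expect_true(all(diff(frac_deleted) <= 0))
  full <- delete_m_clade(gts, sp, x = 1, seed = 43)
  expect_true(all(vapply(full, function(t) length(t$tip.label), integer(1)) == 16))
})
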