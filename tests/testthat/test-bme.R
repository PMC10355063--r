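test_that("Pauplin length equals tree length on additive input", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):0);")
  D <- ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]]
  expect_equal(pauplin_length(tr, D), 5)
  set.seed(131)
  for (i in 1:10) {
    inst <- additive_instance(sample(5:15, 1))
    expect_equal(pauplin_length(inst$tree, inst$D), sum(inst$tree$edge.length),
                 tolerance = 1e-9)
  }
})

test_that("Pauplin length matches a literal double-loop implementation", {
  set.seed(141)
  for (i in 1:20) {
    n <- 6
    tr <- ape::rtree(n)
    D <- rand_sym_matrix(n)
    rownames(D) <- colnames(D) <- sample(tr$tip.label)
    p <- oracle_dists(tr, "internode")
    ref <- 0
    for (u in 1:(n - 1)) for (v in (u + 1):n) {
      lu <- rownames(D)[u]; lv <- rownames(D)[v]
      ref <- ref + 2^(1 - p[lu, lv]) * D[u, v]
    }
    expect_equal(pauplin_length(tr, D), ref, tolerance = 1e-9)
  }
})

test_that("leaf weights 2^(-p_uv) sum to 1/2 for every leaf", {
  set.seed(151)
  for (i in 1:10) {
    n <- sample(4:20, 1)
    st <- bme_search(rand_sym_matrix(n))
    p <- topological_paths(st)
    sums <- rowSums(2^(-p)) - 1  # remove the diagonal 2^0 term
    expect_equal(unname(sums), rep(0.5, n), tolerance = 1e-12)
  }
})

test_that("pauplin_length refuses non-binary trees", {
  star <- ape::read.tree(text = "(a,b,c,d);")
  D <- rand_sym_matrix(4)
  rownames(D) <- colnames(D) <- letters[1:4]
  expect_error(pauplin_length(star, D), "binary")
})

test_that("greedy insertion recovers additive quartets and 10-leaf trees", {
  set.seed(161)
  q <- additive_instance(4)
  expect_equal(nrf(greedy_bme(q$D), q$tree), 0)
  for (i in 1:25) {
    inst <- additive_instance(10)
    g1 <- greedy_bme(inst$D)
    g2 <- greedy_bme(inst$D, insertion_order = "random", seed = i)
    expect_equal(nrf(g1, inst$tree), 0)
    expect_equal(nrf(g2, inst$tree), 0)
  }
})

test_that("trivial sizes are handled", {
  D3 <- rand_sym_matrix(3)
  tr <- greedy_bme(D3)
  expect_equal(sort(tr$tip.label), paste0("t", 1:3))
  expect_warning(greedy_bme(rand_sym_matrix(2)), "trivial")
})

test_that("NNI search is monotone and finds additive topologies", {
  set.seed(171)
  for (i in 1:10) {
    inst <- additive_instance(8)
    # start from a deliberately wrong topology
    start <- rand_topology(rownames(inst$D))
    s0 <- pauplin_length(start, inst$D)
    out <- bnni(start, inst$D)
    expect_lte(attr(out, "balanced_length"), s0 + 1e-12)
    expect_equal(nrf(out, inst$tree), 0)
    expect_equal(attr(out, "balanced_length"), sum(inst$tree$edge.length),
                 tolerance = 1e-9)
  }
  # already optimal: no move applied
  inst <- additive_instance(8)
  opt <- bnni(inst$tree, inst$D)
  expect_equal(nrf(opt, inst$tree), 0)
  expect_equal(attr(opt, "balanced_length"), sum(inst$tree$edge.length),
               tolerance = 1e-9)
})

test_that("search never beats exhaustive enumeration (n = 6)", {
  set.seed(181)
  topos <- enumerate_topologies(6)
  expect_length(topos, 105)  # (2*6-5)!!
  hits <- 0
  for (i in 1:40) {
    D <- rand_sym_matrix(6)
    best <- min(vapply(topos, wastrid:::bme_score, numeric(1), D = D))
    got <- attr(bme_search(D), "balanced_length")
    expect_gte(got, best - 1e-9)
    if (got <= best + 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * 40)  # steepest descent finds the optimum almost always
})

test_that("SPR escapes NNI-local optima and never worsens the score", {
  set.seed(191)
  escaped <- FALSE
  for (i in 1:40) {
    D <- rand_sym_matrix(8)
    start <- rand_topology(rownames(D))
    res_nni <- bnni(start, D)
    res_spr <- bspr(start, D)
    expect_lte(attr(res_spr, "balanced_length"),
               attr(res_nni, "balanced_length") + 1e-12)
    if (attr(res_spr, "balanced_length") <
        attr(res_nni, "balanced_length") - 1e-8) escaped <- TRUE
  }
  expect_true(escaped)
})

test_that("full search recovers near-additive 12-leaf instances", {
  set.seed(201)
  for (i in 1:20) {
    inst <- additive_instance(12)
    D <- perturb(inst$D, 0.45 * inst$min_bl)
    st <- bme_search(D)
    expect_equal(nrf(st, inst$tree), 0)
  }
})

test_that("search is deterministic given matrix and configuration", {
  set.seed(211)
  D <- perturb(additive_instance(10)$D, 0.2)
  a <- write_tree(bme_search(D))
  b <- write_tree(bme_search(D))
  expect_identical(a, b)
})

test_that("n = 4 search solves the three-topology problem exhaustively", {
  set.seed(221)
  for (i in 1:20) {
    D <- rand_sym_matrix(4)
    topos <- enumerate_topologies(4)
    best <- which.min(vapply(topos, wastrid:::bme_score, numeric(1), D = D))
    st <- bme_search(D)
    got <- attr(st, "balanced_length")
    expect_equal(got, wastrid:::bme_score(topos[[best]], D), tolerance = 1e-9)
  }
})
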