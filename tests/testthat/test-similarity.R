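test_that("the residual recursion reproduces the hand-worked three-leaf case", {
  tree <- three_leaf_tree()
  a <- c(L1 = 0.5, L2 = 0.5, L3 = 0)
  b <- c(L1 = 0.5, L2 = 0, L3 = 0.5)
  # leaf match 0.5; L2 residual 0.5*0.8 = 0.4 at the inner node, *0.5 = 0.2
  # at the root meets L3 residual 0.5*0.6 = 0.3 -> extra match 0.2
  expect_equal(metastorms_similarity(a, b, tree), 0.7, tolerance = 1e-12)
  expect_equal(ms_oracle(a, b, tree), 0.7, tolerance = 1e-12)
})

test_that("closed-form limits hold: unit branches give shared abundance, zero branches give 1", {
  t1 <- ape::read.tree(text = "(L1:1,L2:1);")
  expect_equal(metastorms_similarity(c(L1 = 0.6, L2 = 0.4),
                                     c(L1 = 0.2, L2 = 0.8), t1), 0.6,
               tolerance = 1e-12)
  t0 <- ape::read.tree(text = "(L1:0,L2:0);")
  expect_equal(metastorms_similarity(c(L1 = 1, L2 = 0), c(L1 = 0, L2 = 1), t0), 1)

  # on bigger random trees as well
  set.seed(42)
  for (i in 1:10) {
    tree <- make_tree(32, seed = 100 + i)
    a <- rprofile(tree); b <- rprofile(tree)
    tree1 <- tree; tree1$edge.length <- rep(1, nrow(tree$edge))
    expect_equal(metastorms_similarity(a, b, tree1), sum(pmin(a, b)),
                 tolerance = 1e-12)
    tree0 <- tree; tree0$edge.length <- rep(0, nrow(tree$edge))
    expect_equal(metastorms_similarity(a, b, tree0), 1, tolerance = 1e-9)
  }
})

test_that("kernel agrees with an independent recursive implementation on random instances", {
  set.seed(11)
  for (i in 1:30) {
    tree <- make_tree(sample(4:40, 1), seed = 500 + i)
    a <- rprofile(tree); b <- rprofile(tree)
    expect_equal(metastorms_similarity(a, b, tree), ms_oracle(a, b, tree),
                 tolerance = 1e-12)
  }
})

test_that("all metrics are symmetric, reach 1 at identity, and stay in [0, 1]", {
  set.seed(3)
  tree <- make_tree(24, seed = 9)
  for (i in 1:50) {
    a <- rprofile(tree); b <- rprofile(tree)
    for (f in list(function(x, y) metastorms_similarity(x, y, tree),
                   cosine_sim, euclidean_sim)) {
      sab <- f(a, b); sba <- f(b, a)
      expect_lt(abs(sab - sba), 1e-12)
      expect_gte(sab, 0); expect_lte(sab, 1)
      expect_equal(f(a, a), 1, tolerance = 1e-9)
    }
  }
})

test_that("similarity is non-increasing as branch lengths are scaled up", {
  set.seed(21)
  for (i in 1:20) {
    tree <- make_tree(16, seed = 700 + i, max_branch = 1)
    a <- rprofile(tree); b <- rprofile(tree)
    s <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(t) {
      tt <- tree; tt$edge.length <- tree$edge.length * t
      metastorms_similarity(a, b, tt)
    }, numeric(1))
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("resolving a multifurcation with zero-length edges leaves the score unchanged", {
  multi <- ape::read.tree(text = "(L1:0.3,L2:0.4,L3:0.5,L4:0.2);")
  binar <- ape::read.tree(text = "(((L1:0.3,L2:0.4):0,L3:0.5):0,L4:0.2);")
  set.seed(5)
  for (i in 1:25) {
    a <- rprofile(multi); b <- rprofile(multi)
    expect_lt(abs(metastorms_similarity(a, b, multi) -
                  metastorms_similarity(a, b, binar)), 1e-12)
  }
  nested <- ape::read.tree(text = "((L1:0.1,L2:0.2,L3:0.3):0.4,(L4:0.5,L5:0.6,L6:0.7):0.2);")
  resolved <- ape::read.tree(text = "(((L1:0.1,L2:0.2):0,L3:0.3):0.4,((L4:0.5,L5:0.6):0,L6:0.7):0.2);")
  for (i in 1:25) {
    a <- rprofile(nested); b <- rprofile(nested)
    expect_lt(abs(metastorms_similarity(a, b, nested) -
                  metastorms_similarity(a, b, resolved)), 1e-12)
  }
})

test_that("cosine and Euclidean similarities match hand arithmetic", {
  a <- c(x = 0.5, y = 0.5); b <- c(x = 1, y = 0)
  expect_equal(cosine_sim(a, b), 0.5 / sqrt(0.5), tolerance = 1e-9)  # 0.7071
  expect_equal(euclidean_sim(a, b), 0.5, tolerance = 1e-9)
  expect_equal(cosine_sim(a, a), 1)
  expect_equal(euclidean_sim(c(x = 1, y = 0), c(x = 0, y = 1)), 0)
  # disjoint supports
  expect_equal(cosine_sim(c(x = 1, y = 0), c(x = 0, y = 1)), 0)
  expect_error(cosine_sim(c(x = 0, y = 0), b), "zero")
})

test_that("profiles not aligned to the tree are rejected", {
  tree <- three_leaf_tree()
  bad <- c(L1 = 0.5, OTHER = 0.5)
  expect_error(metastorms_similarity(bad, c(L1 = 1, L2 = 0, L3 = 0), tree),
               "not aligned")
  expect_error(metastorms_similarity(c(L1 = 0.4, L2 = 0.4), c(L1 = 1, L2 = 0), tree),
               "summing to 1")
})

test_that("pairwise_matrix equals element-wise single-pair evaluation", {
  tree <- make_tree(12, seed = 31)
  set.seed(31)
  m <- t(vapply(1:5, function(i) rprofile(tree), numeric(12)))
  dimnames(m) <- list(paste0("s", 1:5), tree$tip.label)
  tbl <- as_otu_tibble(m)
  for (metric in c("phylogenetic", "cosine", "euclidean")) {
    M <- pairwise_matrix(tbl, metric, tree = tree)
    expect_true(isSymmetric(M))
    expect_equal(unname(diag(M)), rep(1, 5))
    pair_fun <- switch(metric,
      phylogenetic = function(x, y) metastorms_similarity(x, y, tree),
      cosine = cosine_sim, euclidean = euclidean_sim)
    for (i in 1:5) for (j in 1:5) if (i != j)
      expect_equal(M[i, j], pair_fun(m[i, ], m[j, ]), tolerance = 1e-12)
  }
  expect_equal(pairwise_matrix(tbl[1, ], "cosine"), matrix(1, 1, 1,
               dimnames = list("s1", "s1")))
  # identical samples give an all-ones matrix
  same <- as_otu_tibble(matrix(rep(m[1, ], 3), 3, byrow = TRUE,
                               dimnames = list(paste0("r", 1:3), colnames(m))))
  expect_equal(unname(pairwise_matrix(same, "phylogenetic", tree = tree)),
               matrix(1, 3, 3), tolerance = 1e-9)
})
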