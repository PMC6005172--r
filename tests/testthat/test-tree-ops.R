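test_that("newick reading validates input and round-trips", {
  tr <- read_newick("((A:1,B:2):0.5,(C:1,D:1):0.5);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  rt <- read_newick(write_newick(tr))
  expect_equal(splits_sig <- hgtscreen:::splits_signature(rt),
               hgtscreen:::splits_signature(tr))
  expect_equal(sum(rt$edge.length), sum(tr$edge.length), tolerance = 1e-9)

  star <- read_newick("(A,B,C);")
  expect_equal(star$Nnode, 1L)
  expect_error(read_newick("((A,A),B);"), "duplicate")
})

test_that("round-trip preserves bipartitions and branch length sum", {
  for (seed in 1:10) {
    tr <- random_labeled_tree(10, seed)
    rt <- read_newick(write_newick(tr))
    expect_equal(hgtscreen:::splits_signature(rt),
                 hgtscreen:::splits_signature(tr))
    expect_equal(sum(rt$edge.length), sum(tr$edge.length), tolerance = 1e-9)
  }
})

test_that("monophyly is defined by unrooted bipartitions", {
  tr <- read_newick("((A,B),(C,D));")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, "C"))
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D")))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown")
  expect_error(is_monophyletic(tr, character()), "non-empty")
})

test_that("monophyly of a group equals monophyly of its complement", {
  for (seed in 1:15) {
    tr <- random_labeled_tree(9, seed)
    g <- sample(tr$tip.label, sample(2:7, 1))
    expect_equal(is_monophyletic(tr, g),
                 is_monophyletic(tr, setdiff(tr$tip.label, g)))
    expect_equal(is_monophyletic(tr, g), oracle_monophyletic(tr, g))
  }
})

test_that("pruning finds the smallest removal set deterministically", {
  tr <- read_newick("((A,B),((C,X),D));")
  # group {A,B,X}: removing X makes {A,B} monophyletic
  pr <- prune_to_monophyly(tr, c("A", "B", "X"))
  expect_true(pr$success)
  expect_equal(pr$removed, "X")

  # already monophyletic: empty removal
  pr0 <- prune_to_monophyly(tr, c("A", "B"))
  expect_true(pr0$success)
  expect_equal(pr0$removed, character())

  # a small group shrunk to a single member counts as trivially monophyletic
  tr3 <- read_newick("(((g1,o1),(g2,o2)),((g3,o3),(o4,o5)));")
  pr3 <- prune_to_monophyly(tr3, c("g1", "g2", "g3"))
  expect_true(pr3$success)
  expect_length(pr3$removed, 2)

  # three disruptors isolated around a solid core clade: not rescuable
  tr4 <- read_newick(
    "(((g1,g2),(g3,g4)),((x1,o1),((x2,o2),(x3,(o3,o4)))));")
  pr4 <- prune_to_monophyly(tr4, c(paste0("g", 1:4), paste0("x", 1:3)))
  expect_false(pr4$success)

  # protected leaves are never removed
  prp <- prune_to_monophyly(tr, c("A", "B", "X"), protected = "X",
                            max_prune = 1)
  expect_false(prp$success)
  prx <- prune_to_monophyly(tr, c("A", "B", "X"), protected = c("A", "B"))
  expect_equal(prx$removed, "X")
})

test_that("pruning agrees with exhaustive subset search on random trees", {
  for (seed in 1:30) {
    tr <- random_labeled_tree(12, seed)
    set.seed(seed + 1000)
    group <- sample(tr$tip.label, sample(3:8, 1))
    got <- prune_to_monophyly(tr, group)
    want <- oracle_prune(tr, group, character())
    expect_equal(got$success, want$success)
    if (want$success) expect_equal(got$removed, want$removed)
  }
})

test_that("tree deduplication keys on unrooted topology only", {
  t1 <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t1b <- read_newick("((C:9,D:2):4,(B:1,A:3):1);") # same topology, rerooted/rotated
  t2 <- read_newick("((A:1,C:1):1,(B:1,D:1):1);")
  expect_length(dedupe_trees(list(t1, t1b)), 1)
  expect_length(dedupe_trees(list(t1, t2)), 2)
  t3 <- read_newick("((A,B),(C,E));")
  expect_error(dedupe_trees(list(t1, t3)), "differing leaf sets")
})

test_that("deduplication matches a pairwise brute-force count", {
  base <- random_labeled_tree(8, 99)
  set.seed(7)
  trees <- list(base)
  for (i in 1:40) {
    nb <- hgtscreen:::nni_neighbors(trees[[sample(length(trees), 1)]])
    trees <- c(trees, list(nb[[sample(length(nb), 1)]]))
  }
  kept <- dedupe_trees(trees)
  # O(n^2) oracle via Robinson-Foulds distance
  n_unique <- 0L
  for (i in seq_along(trees)) {
    dup <- FALSE
    if (i > 1) for (j in 1:(i - 1)) {
      if (phangorn::RF.dist(trees[[i]], trees[[j]]) == 0) { dup <- TRUE; break }
    }
    if (!dup) n_unique <- n_unique + 1L
  }
  expect_length(kept, n_unique)
})

test_that("clade shuffling is seeded, leaf-preserving and non-identical", {
  tr <- random_labeled_tree(12, 3)
  s1 <- shuffle_clades_of_three(tr, 10, seed = 5)
  s2 <- shuffle_clades_of_three(tr, 10, seed = 5)
  expect_equal(lapply(s1, write_newick), lapply(s2, write_newick))
  expect_gt(length(s1), 0)
  sig0 <- hgtscreen:::splits_signature(tr)
  for (t in s1) {
    expect_setequal(t$tip.label, tr$tip.label)
    expect_false(identical(hgtscreen:::splits_signature(t), sig0))
  }
  # outputs are mutually distinct topologies
  sigs <- vapply(s1, hgtscreen:::splits_signature, "")
  expect_equal(anyDuplicated(sigs), 0L)
  expect_error(shuffle_clades_of_three(tr, 0, seed = 1), "positive")
})
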