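test_that("substitution model satisfies stochasticity and detailed balance", {
  set.seed(1)
  fr <- rexp(20) + 0.1
  fr <- fr / sum(fr)
  S <- matrix(runif(400, 0.1, 2), 20, 20)
  S <- (S + t(S)) / 2
  m <- substitution_model(exchangeabilities = S, frequencies = fr)
  expect_equal(sum(m$frequencies), 1, tolerance = 1e-12)
  expect_equal(max(abs(rowSums(m$Q))), 0, tolerance = 1e-10)
  expect_equal(-sum(m$frequencies * diag(m$Q)), 1, tolerance = 1e-10)
  for (t in c(0.01, 0.5, 3)) {
    P <- transition_probabilities(m, t)
    expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-10)
    # detailed balance: pi_i P_ij = pi_j P_ji
    F <- diag(m$frequencies) %*% P
    expect_equal(max(abs(F - t(F))), 0, tolerance = 1e-10)
  }
})

test_that("discrete gamma categories average to rate one", {
  for (shape in c(0.3, 1, 5)) {
    r <- hgtscreen:::discrete_gamma_rates(shape, 4)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
  }
})

test_that("degenerate likelihood cases have closed forms", {
  m <- POISSON
  # single leaf: stationary frequency
  single <- structure(list(tip.label = "A"), class = "phylo")
  expect_equal(site_log_likelihoods(single, c(A = "AC"), m),
               rep(log(1 / 20), 2))
  # two leaves joined by zero total length, identical residue
  tr <- read_newick("(A:0,B:0);")
  expect_equal(site_log_likelihoods(tr, c(A = "C", B = "C"), m), log(1 / 20))
  # ambiguity: gap contributes likelihood 1
  expect_equal(site_log_likelihoods(tr, c(A = "-", B = "-"), m), 0)
})

test_that("site likelihoods sum to one over all patterns (4-leaf oracle)", {
  pats <- as.matrix(expand.grid(1:20, 1:20, 1:20, 1:20))
  seqs <- apply(pats, 2, function(ix) paste0(AA20[ix], collapse = ""))
  set.seed(11)
  for (rep in 1:2) {
    tr <- ape::rtree(4, rooted = FALSE, tip.label = c("A", "B", "C", "D"))
    fr <- rexp(20) + 0.2
    m <- substitution_model(frequencies = fr / sum(fr))
    aln <- as_alignment(setNames(seqs, c("A", "B", "C", "D")))
    lnl <- site_log_likelihoods(tr, aln, m)
    expect_equal(sum(exp(lnl)), 1, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to rerooting and rotation", {
  tr <- read_newick(
    "(((A:0.2,B:0.1):0.1,C:0.3):0.2,(D:0.1,E:0.2):0.1,F:0.4);")
  aln <- simulate_alignment(tr, POISSON, 80, seed = 7)
  l0 <- site_log_likelihoods(tr, aln, POISSON)
  rerooted <- ape::root(tr, outgroup = "D", resolve.root = TRUE)
  rotated <- read_newick(
    "((D:0.1,E:0.2):0.1,F:0.4,(C:0.3,(B:0.1,A:0.2):0.1):0.2);")
  expect_equal(site_log_likelihoods(rerooted, aln, POISSON), l0,
               tolerance = 1e-9)
  expect_equal(site_log_likelihoods(rotated, aln, POISSON), l0,
               tolerance = 1e-9)
})

test_that("two-sequence MLE distance matches the 20-state correction", {
  m <- POISSON
  # p = 0: optimized distance collapses to the lower clamp
  aln0 <- as_alignment(c(A = strrep("ACDEF", 40), B = strrep("ACDEF", 40)))
  tr <- read_newick("(A:0.1,B:0.1);")
  fit0 <- optimize_branch_lengths(tr, aln0, m)
  expect_lt(sum(fit0$edge.length), 1e-6)

  # random divergence: compare against the closed form
  set.seed(3)
  for (i in 1:5) {
    n <- 1500
    s1 <- sample(AA20, n, TRUE)
    s2 <- s1
    nm <- sample(n, round(n * runif(1, 0.2, 0.55)))
    s2[nm] <- sample(AA20, length(nm), TRUE)
    p <- mean(s1 != s2)
    aln <- as_alignment(c(A = paste0(s1, collapse = ""),
                          B = paste0(s2, collapse = "")))
    fit <- optimize_branch_lengths(tr, aln, m)
    closed <- -(19 / 20) * log(1 - 20 * p / 19)
    expect_equal(sum(fit$edge.length), closed, tolerance = 1e-4)
  }
})

test_that("re-optimizing an optimal tree is a fixed point", {
  tr <- read_newick("((A:0.3,B:0.2):0.1,(C:0.25,D:0.15):0.1);")
  aln <- simulate_alignment(tr, POISSON, 300, seed = 5)
  f1 <- optimize_branch_lengths(tr, aln, POISSON)
  f2 <- optimize_branch_lengths(f1, aln, POISSON)
  expect_lt(abs(attr(f2, "loglik") - attr(f1, "loglik")), 1e-6)
})

test_that("branch-length optimization agrees with an independent engine", {
  skip_if_not_installed("phangorn")
  tr <- read_newick("((A:0.3,B:0.2):0.15,(C:0.25,D:0.15):0.1,E:0.3);")
  aln <- simulate_alignment(tr, POISSON, 250, seed = 13)
  fit <- optimize_branch_lengths(tr, aln, POISSON)
  pd <- phangorn::phyDat(
    t(sapply(unclass(aln), function(s) strsplit(s, "")[[1]])),
    type = "AA")
  pml0 <- phangorn::pml(ape::unroot(tr), pd, model = NULL, bf = rep(1/20, 20))
  pfit <- phangorn::optim.pml(pml0, optEdge = TRUE,
                              control = phangorn::pml.control(trace = 0))
  expect_equal(attr(fit, "loglik"), pfit$logLik, tolerance = 1e-3)
})

test_that("exhaustive 4-taxon search matches brute force over 3 topologies", {
  tr <- read_newick("((A:0.4,B:0.4):0.25,(C:0.4,D:0.4):0.25);")
  aln <- simulate_alignment(tr, POISSON, 400, seed = 2)
  fit <- ml_search(aln, POISSON)
  topos <- list("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));")
  brute <- sapply(topos, function(s)
    attr(optimize_branch_lengths(read_newick(s), aln, POISSON), "loglik"))
  expect_equal(attr(fit, "loglik"), max(brute), tolerance = 1e-4)
  expect_equal(hgtscreen:::splits_signature(fit),
               hgtscreen:::splits_signature(read_newick(topos[[which.max(brute)]])))
})

test_that("a vacuous constraint equals the unconstrained search", {
  tr <- read_newick("((A:0.3,B:0.3):0.2,(C:0.3,D:0.3):0.2,E:0.4);")
  aln <- simulate_alignment(tr, POISSON, 300, seed = 9)
  f1 <- ml_search(aln, POISSON)
  f2 <- ml_search(aln, POISSON, constraint = names(aln))
  expect_equal(attr(f1, "loglik"), attr(f2, "loglik"), tolerance = 1e-8)
  expect_error(ml_search(aln, POISSON, constraint = c("A", "ZZ")), "absent")
})

test_that("the true 6-leaf topology is recovered from long alignments", {
  truth <- read_newick(
    "(((A:0.2,B:0.2):0.15,C:0.35):0.1,(D:0.25,E:0.25):0.1,F:0.4);")
  sig <- hgtscreen:::splits_signature(truth)
  hits <- sapply(1:20, function(i) {
    aln <- simulate_alignment(truth, POISSON, 2000, seed = 100 + i)
    identical(hgtscreen:::splits_signature(ml_search(aln, POISSON)), sig)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("constrained search keeps the constraint monophyletic", {
  truth <- read_newick(
    "(((A:0.2,B:0.2):0.1,C:0.3):0.2,((D:0.1,F:0.1):0.15,E:0.25):0.2);")
  aln <- simulate_alignment(truth, POISSON, 400, seed = 21)
  cset <- c("A", "B", "C", "F")
  fit <- ml_search(aln, POISSON, constraint = cset)
  expect_true(is_monophyletic(fit, cset))
  free <- ml_search(aln, POISSON)
  expect_gte(attr(free, "loglik"), attr(fit, "loglik") - 1e-6)
})

test_that("NNI search recovers clear structure above 7 leaves", {
  truth <- read_newick(paste0(
    "(((A:0.15,B:0.15):0.2,(C:0.15,D:0.15):0.2):0.15,",
    "((E:0.15,F:0.15):0.2,(G:0.15,H:0.15):0.2):0.15,I:0.4);"))
  aln <- simulate_alignment(truth, POISSON, 1000, seed = 31)
  fit <- ml_search(aln, POISSON)
  expect_identical(hgtscreen:::splits_signature(fit),
                   hgtscreen:::splits_signature(truth))
})

test_that("alignment simulation is seeded and respects degenerate trees", {
  tr <- read_newick("((A:0,B:0):0,(C:0,D:0):0);")
  aln <- simulate_alignment(tr, POISSON, 50, seed = 4)
  expect_equal(length(unique(unclass(aln))), 1) # zero lengths: all identical
  tr2 <- read_newick("((A:0.3,B:0.3):0.2,(C:0.3,D:0.3):0.2);")
  a1 <- simulate_alignment(tr2, POISSON, 100, seed = 8)
  a2 <- simulate_alignment(tr2, POISSON, 100, seed = 8)
  expect_identical(unclass(a1), unclass(a2))
  a3 <- simulate_alignment(tr2, POISSON, 100, seed = 9)
  expect_false(identical(unclass(a1), unclass(a3)))
})

test_that("simulated residue frequencies converge to the model's", {
  set.seed(2)
  fr <- rexp(20) + 0.3
  m <- substitution_model(frequencies = fr / sum(fr))
  tr <- read_newick("(A:0.4,B:0.4);")
  aln <- simulate_alignment(tr, m, 1e5, seed = 6)
  emp <- table(factor(strsplit(unclass(aln)[["A"]], "")[[1]], levels = AA20))
  expect_lt(max(abs(emp / 1e5 - m$frequencies)), 0.01)
})

test_that("alignment and site-matrix I/O round-trip", {
  aln <- as_alignment(c(seq_a = "ACDEF-", seq_b = "ACDEYX"))
  fa <- tempfile(fileext = ".fa")
  write_fasta_alignment(aln, fa)
  expect_equal(unclass(read_fasta_alignment(fa)), unclass(aln))
  ph <- tempfile(fileext = ".phy")
  write_phylip_alignment(aln, ph)
  expect_equal(unclass(read_phylip_alignment(ph)), unclass(aln))

  tr <- read_newick("((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1);")
  aln4 <- simulate_alignment(tr, POISSON, 30, seed = 3)
  mat <- site_loglik_matrix(list(t1 = tr, t2 = tr), aln4, POISSON,
                            optimize = FALSE)
  tsv <- tempfile(fileext = ".tsv")
  write_site_logliks(mat, tsv)
  expect_equal(read_site_logliks(tsv), mat, tolerance = 1e-12)
})
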