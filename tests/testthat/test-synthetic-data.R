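test_that("scenario construction places the query per its kind", {
  sv <- simulate_hgt_scenario("VERTICAL", 3, 3, 4, n_sites = 60, seed = 1)
  mets <- grep("^MET", sv$tree$tip.label, value = TRUE)
  expect_true(is_monophyletic(sv$tree, c(mets, sv$query)))

  sb <- simulate_hgt_scenario("HGT_FROM_BACTERIA", 3, 3, 4, n_sites = 60,
                              seed = 2)
  metsb <- grep("^MET", sb$tree$tip.label, value = TRUE)
  expect_true(is_monophyletic(sb$tree, metsb))
  expect_false(is_monophyletic(sb$tree, c(metsb, sb$query)))
  bacs <- grep("^BAC", sb$tree$tip.label, value = TRUE)
  expect_true(is_monophyletic(sb$tree, c(bacs, sb$query)))

  se <- simulate_hgt_scenario("HGT_FROM_EUK", 3, 3, 4, n_sites = 60, seed = 3)
  euks <- grep("^EUK", se$tree$tip.label, value = TRUE)
  expect_true(is_monophyletic(se$tree, c(euks, se$query)))

  expect_error(simulate_hgt_scenario("VERTICAL", 1, 3, 4), ">= 2")
  expect_error(simulate_hgt_scenario("VERTICAL", 3, 3, 4, n_sites = 10),
               ">= 50")
})

test_that("scenarios are deterministic under a fixed seed", {
  s1 <- simulate_hgt_scenario("HGT_FROM_BACTERIA", 3, 2, 3, n_sites = 60,
                              seed = 9)
  s2 <- simulate_hgt_scenario("HGT_FROM_BACTERIA", 3, 2, 3, n_sites = 60,
                              seed = 9)
  expect_equal(write_newick(s1$tree), write_newick(s2$tree))
  expect_identical(unclass(s1$alignment), unclass(s2$alignment))
  expect_equal(s1$taxon_map, s2$taxon_map)
})

test_that("contamination scenarios relabel bacterial leaves as metazoan", {
  sc <- simulate_hgt_scenario("CONTAMINATION", 4, 2, 4, n_sites = 60,
                              seed = 4, n_contaminants = 2)
  expect_length(sc$contaminant_leaves, 2)
  cls <- setNames(sc$taxon_map$class, sc$taxon_map$subject)
  expect_true(all(cls[sc$contaminant_leaves] == "metazoan"))
  # the labeled animal clade (query included: vertical placement) is
  # disrupted, and pruning the contaminants rescues it
  group <- names(cls)[cls == "metazoan"]
  expect_false(is_monophyletic(sc$tree, group))
  pr <- prune_to_monophyly(sc$tree, group, protected = sc$query)
  expect_true(pr$success)
  expect_setequal(pr$removed, sc$contaminant_leaves)
})

test_that("two contaminants are rescued, three are not", {
  for (seed in 1:5) {
    s2 <- simulate_hgt_scenario("CONTAMINATION", 5, 2, 4, n_sites = 60,
                                seed = seed, n_contaminants = 2)
    cls <- setNames(s2$taxon_map$class, s2$taxon_map$subject)
    g2 <- names(cls)[cls == "metazoan"]
    expect_true(prune_to_monophyly(s2$tree, g2, protected = s2$query)$success)

    s3 <- simulate_hgt_scenario("CONTAMINATION", 5, 2, 4, n_sites = 60,
                                seed = seed, n_contaminants = 3)
    cls3 <- setNames(s3$taxon_map$class, s3$taxon_map$subject)
    g3 <- names(cls3)[cls3 == "metazoan"]
    expect_false(prune_to_monophyly(s3$tree, g3,
                                    protected = s3$query)$success)
  }
})

test_that("similarity synthesis clamps extremes and ranks by E-value", {
  sc <- simulate_hgt_scenario("HGT_FROM_BACTERIA", 3, 2, 3, n_sites = 60,
                              seed = 5)
  # identical sequence: identity 1 -> minimum E-value clamp
  aln <- unclass(sc$alignment)
  aln[["CLONE"]] <- aln[[sc$query]]
  sc$alignment <- as_alignment(aln)
  tab <- simulate_similarity_table(sc)
  expect_equal(tab$evalue[tab$subject == "CLONE"], 1e-180)
  expect_equal(tab$subject[1], "CLONE")
  expect_true(all(diff(tab$evalue) >= 0))
  expect_true(all(tab$evalue <= 10 & tab$evalue >= 1e-180))
})

test_that("strong HGT scenarios scream past the alien-index threshold", {
  ais <- sapply(1:20, function(i) {
    sc <- simulate_hgt_scenario("HGT_FROM_BACTERIA", 3, 2, 3, n_sites = 150,
                                seed = 400 + i)
    tab <- simulate_similarity_table(sc)
    score_alien_index(tab, sc$taxon_map, "Ctenophora")$alien_index
  })
  expect_gte(sum(ais > 45), 18)
})

test_that("expression profiles are seeded and shaped as described", {
  profiles <- c(gm = "maternal", gz = "zygotic_spike", gc = "cyclic",
                gs = "silent")
  e1 <- simulate_expression_matrix(profiles, seed = 6)
  e2 <- simulate_expression_matrix(profiles, seed = 6)
  expect_identical(e1$counts, e2$counts)
  expect_equal(length(unique(e1$sample_meta$hours)), 25)

  sc <- developmental_expression_score(normalize_per_million(e1),
                                       genes = names(profiles))
  expect_lt(sc$score[sc$gene == "gs"], 100)
  expect_gt(sc$score[sc$gene == "gm"], 100)
  # maternal expression peaks at fertilization
  norm <- normalize_per_million(e1)
  tp0 <- norm$sample_meta$sample[norm$sample_meta$hours == 0]
  tpN <- norm$sample_meta$sample[norm$sample_meta$hours == max(norm$sample_meta$hours)]
  expect_gt(median(norm$counts["gm", tp0]), median(norm$counts["gm", tpN]))

  expect_error(simulate_expression_matrix(c(g = "sideways"), seed = 1),
               "unknown profile")
})
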