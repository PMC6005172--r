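test_that("splice sites are read in transcript orientation", {
  # + strand: exons (1,10) and (21,30); intron 11-20 with GT...AG
  fwd <- paste0("ACGTACGTAC", "GTCCCCCCAG", "ACGTACGTAC")
  genome <- c(chr1 = fwd)
  rep1 <- check_splice_sites("g1", "chr1", "+",
                             cbind(c(1, 21), c(10, 30)), genome)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$donor, "GT")
  expect_equal(rep1$acceptor, "AG")
  expect_true(rep1$canonical)

  # - strand gene whose forward intron reads CT...AC
  rev <- paste0("ACGTACGTAC", "CTCCCCCCAC", "ACGTACGTAC")
  rep2 <- check_splice_sites("g2", "chr2", "-",
                             cbind(c(1, 21), c(10, 30)), c(chr2 = rev))
  expect_true(rep2$canonical)
  expect_equal(rep2$donor, "GT")

  # single exon: zero introns
  rep3 <- check_splice_sites("g3", "chr1", "+", cbind(1, 10), genome)
  expect_equal(nrow(rep3), 0)

  expect_error(check_splice_sites("g", "chr1", "+",
                                  cbind(c(1, 40), c(10, 45)), genome),
               "outside scaffold")
  expect_error(check_splice_sites("g", "chr1", "+",
                                  cbind(c(1, 13), c(10, 30)), genome),
               "shorter than 4")
})

test_that("splice reports are strand-symmetric", {
  for (seed in 1:5) {
    fx <- simulate_gene_models(4, 3, canonical_fraction = 0.5, seed = seed)
    rep1 <- splice_report(fx$models, fx$genome)
    # lift every model to the opposite strand of the reverse-complemented genome
    rc_genome <- Biostrings::reverseComplement(fx$genome)
    flipped <- fx$models
    for (i in seq_len(nrow(flipped))) {
      L <- Biostrings::width(fx$genome)[
        match(flipped$scaffold[i], names(fx$genome))]
      ex <- flipped$exons[[i]]
      ex2 <- cbind(start = L - ex[, 2] + 1, end = L - ex[, 1] + 1)
      flipped$exons[[i]] <- ex2[order(ex2[, 1]), , drop = FALSE]
      flipped$strand[i] <- if (flipped$strand[i] == "+") "-" else "+"
    }
    rep2 <- splice_report(flipped, rc_genome)
    expect_equal(rep1, rep2)
  }
})

test_that("synthetic gene models match their truth table", {
  all1 <- simulate_gene_models(5, 2, canonical_fraction = 1, seed = 3)
  r1 <- splice_report(all1$models, all1$genome)
  expect_true(all(r1$canonical))
  all0 <- simulate_gene_models(5, 2, canonical_fraction = 0, seed = 4)
  r0 <- splice_report(all0$models, all0$genome)
  expect_false(any(r0$canonical))
  mix <- simulate_gene_models(8, 3, canonical_fraction = 0.5, seed = 5)
  rm_ <- splice_report(mix$models, mix$genome)
  merged <- dplyr::inner_join(rm_, mix$truth, by = c("gene", "intron"),
                              suffix = c("_got", "_want"))
  expect_equal(merged$canonical_got, merged$canonical_want)
})

test_that("gene models survive a GFF3 round-trip", {
  fx <- simulate_gene_models(4, 2, canonical_fraction = 1, seed = 11)
  path <- tempfile(fileext = ".gff3")
  write_gff3(fx$models, path)
  back <- read_gene_models(path)
  back <- back[match(fx$models$gene, back$gene), ]
  expect_equal(back$scaffold, fx$models$scaffold)
  expect_equal(back$strand, fx$models$strand)
  for (i in seq_len(nrow(back)))
    expect_equal(unname(back$exons[[i]]), unname(fx$models$exons[[i]]))
})

test_that("reciprocal best hits require mutual best and the cutoff", {
  mk <- function(q, s, e) tibble::tibble(
    query = q, subject = s, pident = 50, length = 100,
    evalue = e, bitscore = 100, rank = ave(seq_along(q), q, FUN = seq_along))
  ab <- mk(c("a1", "a1"), c("b1", "b2"), c(1e-20, 1e-5))
  ba <- mk(c("b1", "b2"), c("a1", "a1"), c(1e-20, 1e-5))
  expect_equal(reciprocal_best_hits(ab, ba),
               tibble::tibble(a = "a1", b = "b1"))

  # asymmetry: b1's best is a2, not a1
  ba2 <- mk(c("b1", "b1"), c("a2", "a1"), c(1e-30, 1e-20))
  expect_equal(nrow(reciprocal_best_hits(ab, ba2)), 0)

  # cutoff excludes weak best hits
  ab3 <- mk("a1", "b1", 0.5)
  ba3 <- mk("b1", "a1", 0.5)
  expect_equal(nrow(reciprocal_best_hits(ab3, ba3)), 0)
})

test_that("reciprocal best hits are symmetric under table swap", {
  set.seed(8)
  mk_rand <- function(qs, ss) {
    n <- 30
    tibble::tibble(query = sample(qs, n, TRUE), subject = sample(ss, n, TRUE),
                   pident = 50, length = 100,
                   evalue = 10^runif(n, -40, 0),
                   bitscore = runif(n, 30, 300)) |>
      dplyr::group_by(query) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  ab <- mk_rand(paste0("a", 1:6), paste0("b", 1:6))
  ba <- mk_rand(paste0("b", 1:6), paste0("a", 1:6))
  fwd <- reciprocal_best_hits(ab, ba)
  rev <- reciprocal_best_hits(ba, ab)
  expect_setequal(paste(fwd$a, fwd$b), paste(rev$b, rev$a))
})

test_that("close-relative screen looks only at the top passing hit", {
  map <- as_taxon_map(tibble::tibble(
    subject = c("choano1", "bact1"),
    class = c("euk_nonmetazoan", "bacteria"),
    phylum = c("Choanoflagellatea", "Proteobacteria")))
  mk <- function(subj, ev) tibble::tibble(
    query = "g", subject = subj, pident = 50, length = 100,
    evalue = ev, bitscore = 100, rank = seq_along(subj))
  expect_true(screen_close_relatives(mk("choano1", 1e-10), map))
  expect_false(screen_close_relatives(mk(c("bact1", "choano1"),
                                         c(1e-20, 1e-10)), map))
  expect_false(screen_close_relatives(mk("choano1", 0.5), map))
  expect_error(screen_close_relatives(mk(character(), numeric()), map),
               "non-empty")
})

test_that("phylogeny taxon selection dedups genera within groups", {
  subs <- sprintf("s%02d", 1:16)
  map <- as_taxon_map(tibble::tibble(
    subject = subs,
    organism = c(sprintf("Bacillus%d cereus", 1:12),
                 "Bacillus1 thuringiensis", "Homo sapiens",
                 "Saccharomyces cerevisiae", "Chlamydomonas reinhardtii"),
    class = c(rep("bacteria", 13), "metazoan",
              "euk_nonmetazoan", "euk_nonmetazoan"),
    phylum = c(rep("Firmicutes", 13), "Chordata", "Ascomycota",
               "Chlorophyta"),
    is_fungus = c(rep(FALSE, 14), TRUE, FALSE)))
  hits <- tibble::tibble(query = "g", subject = subs, pident = 50,
                         length = 100, evalue = 1e-10, bitscore = 100,
                         rank = seq_along(subs))
  sel <- select_phylo_taxa(hits, map, per_group = 10)
  bact <- sel[sel$group == "bacteria", ]
  # 12 distinct genera ranked first -> first 10 kept; the shared-genus
  # subject s13 (Bacillus1 again) is skipped
  expect_equal(nrow(bact), 10)
  expect_equal(bact$subject, sprintf("s%02d", 1:10))
  expect_false("s13" %in% sel$subject)
  expect_equal(sel$group[sel$subject == "s15"], "fungi")
  # no duplicated genus within any group
  expect_true(all(!duplicated(paste(sel$group, sel$genus))))

  # must_include: organism with no passing hit is silently omitted
  sel2 <- select_phylo_taxa(hits, map, per_group = 2,
                            must_include = c("Homo sapiens", "Ghost organism"))
  expect_true("s14" %in% sel2$subject)
  expect_false(any(grepl("Ghost", sel2$subject)))
})

test_that("candidate classification follows the animal-hit counts", {
  expect_equal(classify_candidate(0, 15), "NO_ANIMAL_HITS_HGT")
  expect_equal(classify_candidate(2, 15), "TOO_FEW_ANIMAL_HITS_DISCARD")
  expect_equal(classify_candidate(1, 15), "TOO_FEW_ANIMAL_HITS_DISCARD")
  expect_equal(classify_candidate(10, 15), "PHYLO_TEST")
  expect_equal(classify_candidate(3, 1), "PHYLO_TEST")
  expect_error(classify_candidate(0, 0), "screened in")
})

test_that("presence/absence matrix reflects reciprocal hits per dataset", {
  rbh <- list(sp1 = tibble::tibble(a = c("g1", "g2"), b = c("x", "y")),
              sp2 = tibble::tibble(a = "g2", b = "z"))
  pa <- presence_absence_matrix(rbh, c("g1", "g2", "g3"))
  expect_equal(pa$sp1, c(TRUE, TRUE, FALSE))
  expect_equal(pa$sp2, c(FALSE, TRUE, FALSE))
})
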