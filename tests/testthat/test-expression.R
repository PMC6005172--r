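make_expr <- function(counts, hours = NULL, reps = NULL) {
  ns <- ncol(counts)
  if (is.null(hours)) hours <- rep(seq_len(ns %/% 2), each = 2)[seq_len(ns)]
  if (is.null(reps)) reps <- ave(hours, hours, FUN = seq_along)
  expression_matrix(counts, tibble::tibble(
    sample = colnames(counts), hours = hours, replicate = reps))
}

test_that("per-million normalization has the defining properties", {
  counts <- matrix(c(50, 499950, 10, 90), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  em <- make_expr(counts, hours = c(0, 1), reps = c(1, 1))
  nm <- normalize_per_million(em)
  expect_equal(nm$counts["g1", "s1"], 100)
  expect_equal(unname(colSums(nm$counts)), c(1e6, 1e6), tolerance = 1e-6)
  expect_error(normalize_per_million(nm), "already")

  # scale invariance per sample
  em2 <- make_expr(counts * c(7, 7, 3, 3), hours = c(0, 1), reps = c(1, 1))
  nm2 <- normalize_per_million(em2)
  expect_equal(nm2$counts, nm$counts, tolerance = 1e-9)

  # all-zero sample stays zero with a warning
  cz <- counts
  cz[, 2] <- 0
  expect_warning(nz <- normalize_per_million(make_expr(cz, c(0, 1), c(1, 1))),
                 "zero counted reads")
  expect_equal(unname(nz$counts[, 2]), c(0, 0))

  expect_error(expression_matrix(matrix(-1, 1, 1,
                                        dimnames = list("g", "s")),
                                 tibble::tibble(sample = "s", hours = 0,
                                                replicate = 1)),
               "non-negative")
})

test_that("developmental score sums per-time-point replicate medians", {
  # 25 time points x 3 replicates, constant value 4 -> score 100
  counts <- matrix(4, 1, 75, dimnames = list("g", sprintf("s%02d", 1:75)))
  em <- make_expr(counts, hours = rep(0:24, each = 3),
                  reps = rep(1:3, 25))
  em$normalized <- TRUE
  sc <- developmental_expression_score(em)
  expect_equal(sc$score, 100)
  expect_true(sc$expressed) # boundary inclusive

  # median is robust to a replicate outlier
  counts2 <- matrix(c(0, 10, 1000), 1, 3, dimnames = list("g", c("a", "b", "c")))
  em2 <- make_expr(counts2, hours = c(5, 5, 5), reps = 1:3)
  em2$normalized <- TRUE
  expect_equal(developmental_expression_score(em2)$score, 10)

  expect_error(developmental_expression_score(em, genes = "nope"), "absent")
  expect_error(developmental_expression_score(make_expr(counts,
                                                        rep(0:24, each = 3),
                                                        rep(1:3, 25))),
               "normalize")
})

test_that("score matches a naive oracle and is replicate-permutation invariant", {
  set.seed(20)
  ng <- 6; ntp <- 10; reps <- 4
  counts <- matrix(rpois(ng * ntp * reps, 30), ng,
                   dimnames = list(paste0("g", 1:ng), NULL))
  colnames(counts) <- sprintf("s%03d", seq_len(ncol(counts)))
  hours <- rep(seq_len(ntp), each = reps)
  em <- make_expr(counts, hours = hours, reps = rep(seq_len(reps), ntp))
  em$normalized <- TRUE
  got <- developmental_expression_score(em, threshold = 100)

  naive <- sapply(rownames(counts), function(g) {
    s <- 0
    for (tp in unique(hours)) {
      v <- sort(counts[g, hours == tp])
      n <- length(v)
      s <- s + if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    }
    s
  })
  expect_equal(got$score, unname(naive))

  # permute replicates within each time point
  perm <- unlist(lapply(split(seq_along(hours), hours),
                        function(ix) sample(ix)), use.names = FALSE)
  emp <- make_expr(counts[, perm], hours = hours,
                   reps = rep(seq_len(reps), ntp))
  emp$normalized <- TRUE
  expect_equal(developmental_expression_score(emp)$score, got$score)
})

test_that("classification threshold is inclusive", {
  expect_true(classify_expressed(100))
  expect_false(classify_expressed(99.999))
  expect_false(classify_expressed(0))
  expect_error(classify_expressed(-5), "non-negative")
})

test_that("an engineered 9-gene fixture splits exactly 6 expressed / 3 not", {
  profiles <- c(hgt1 = "maternal", hgt2 = "zygotic_spike", hgt3 = "cyclic",
                hgt4 = "maternal", hgt5 = "zygotic_spike", hgt6 = "cyclic",
                hgt7 = "silent", hgt8 = "silent", hgt9 = "silent")
  em <- simulate_expression_matrix(profiles, seed = 77)
  sc <- developmental_expression_score(normalize_per_million(em),
                                       genes = names(profiles))
  expect_equal(sum(sc$expressed), 6)
  expect_setequal(sc$gene[!sc$expressed], c("hgt7", "hgt8", "hgt9"))
})

test_that("expression TSV round-trip preserves counts and metadata", {
  counts <- matrix(rpois(12, 40), 3, 4,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  em <- make_expr(counts, hours = c(0, 0, 1, 1), reps = c(1, 2, 1, 2))
  cpath <- tempfile(fileext = ".tsv")
  mpath <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(counts, rownames = "gene"), cpath)
  readr::write_tsv(em$sample_meta, mpath)
  back <- read_expression_tsv(cpath, mpath)
  expect_equal(back$counts, em$counts)
  expect_equal(back$sample_meta, em$sample_meta)
})
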