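# shared fixtures and independent oracles used across the test files

POISSON <- substitution_model()

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa_string <- function(n) paste0(sample(AA20, n, TRUE), collapse = "")

# random similarity table over a handful of genes; subjects drawn from a
# taxon universe that includes self-phylum organisms
random_similarity_fixture <- function(seed, n_genes = 3, max_hits = 12) {
  set.seed(seed)
  classes <- c("bacteria", "archaea", "euk_nonmetazoan", "metazoan")
  subjects <- sprintf("SUBJ%03d", 1:40)
  map <- tibble::tibble(
    subject = subjects,
    organism = paste("Genus", subjects),
    class = sample(classes, 40, TRUE,
                   prob = c(0.3, 0.1, 0.25, 0.35)),
    phylum = NA_character_
  )
  map$phylum <- ifelse(map$class == "metazoan",
                       sample(c("Ctenophora", "Chordata", "Porifera"),
                              40, TRUE, prob = c(0.2, 0.4, 0.4)),
                       sample(c("Proteobacteria", "Ascomycota",
                                "Chlorophyta"), 40, TRUE))
  hits <- dplyr::bind_rows(lapply(seq_len(n_genes), function(g) {
    k <- sample(0:max_hits, 1)
    if (k == 0) return(NULL)
    tibble::tibble(
      query = sprintf("GENE%02d", g),
      subject = sample(subjects, k, TRUE),
      pident = runif(k, 20, 95),
      length = sample(80:400, k, TRUE),
      evalue = 10^runif(k, -80, 1),
      bitscore = runif(k, 20, 500),
      rank = seq_len(k)
    )
  }))
  list(hits = hits, map = as_taxon_map(map))
}

# brute-force per-gene rescan: plain loops, no tie-break helpers shared
# with the implementation
oracle_score_gene <- function(hits, map, self_phylum) {
  cls <- setNames(map$class, map$subject)
  phy <- setNames(map$phylum, map$subject)
  best <- list(meta = NULL, nonmeta = NULL)
  counts <- c(meta = 0L, nonmeta = 0L)
  for (i in seq_len(nrow(hits))) {
    s <- hits$subject[i]
    if (is.na(cls[s])) next
    if (phy[s] == self_phylum) next
    side <- if (cls[s] == "metazoan") "meta" else "nonmeta"
    counts[side] <- counts[side] + 1L
    b <- best[[side]]
    better <- is.null(b) ||
      hits$evalue[i] < b$evalue ||
      (hits$evalue[i] == b$evalue && hits$bitscore[i] > b$bitscore) ||
      (hits$evalue[i] == b$evalue && hits$bitscore[i] == b$bitscore &&
         hits$rank[i] < b$rank)
    if (better) best[[side]] <- hits[i, ]
  }
  e_m <- if (is.null(best$meta)) 1 else best$meta$evalue
  e_n <- if (is.null(best$nonmeta)) 1 else best$nonmeta$evalue
  b_m <- if (is.null(best$meta)) 0 else best$meta$bitscore
  b_n <- if (is.null(best$nonmeta)) 0 else best$nonmeta$bitscore
  list(ai = log(e_m + 1e-200) - log(e_n + 1e-200), hgt = b_n - b_m,
       n_meta = counts[["meta"]], n_nonmeta = counts[["nonmeta"]],
       e_m = if (is.null(best$meta)) NA_real_ else best$meta$evalue,
       e_n = if (is.null(best$nonmeta)) NA_real_ else best$nonmeta$evalue)
}

# independent monophyly check: root at an outside tip and use ape
oracle_monophyletic <- function(tree, group) {
  if (length(group) <= 1 || length(group) >= length(tree$tip.label))
    return(TRUE)
  out <- setdiff(tree$tip.label, group)[1]
  rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  ape::is.monophyletic(rooted, group)
}

# exhaustive reference for prune_to_monophyly
oracle_prune <- function(tree, group, protected, max_prune = 2) {
  removable <- sort(setdiff(group, protected))
  for (k in 0:max_prune) {
    if (k > length(removable)) break
    subsets <- if (k == 0) list(character()) else
      apply(combn(removable, k), 2, identity, simplify = FALSE)
    for (rem in subsets) {
      kept <- setdiff(group, rem)
      pruned <- if (length(rem)) ape::drop.tip(tree, rem) else tree
      if (length(kept) <= 1 || oracle_monophyletic(pruned, kept))
        return(list(removed = rem, success = TRUE))
    }
  }
  list(removed = character(), success = FALSE)
}

random_labeled_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   tip.label = sprintf("t%02d", seq_len(n)))
  tr
}
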