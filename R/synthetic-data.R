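#' Simulate a ground-truthed HGT scenario
#'
#' Builds a labeled gene tree with three domain clades (bacteria, non-
#' metazoan eukaryotes, metazoans) joined by long stems, grafts a ctenophore
#' query leaf according to the scenario kind, simulates an alignment along
#' the tree, and emits the matching taxon class map:
#'
#' * `HGT_FROM_BACTERIA` / `HGT_FROM_EUK` — the query attaches inside the
#'   donor clade (recent transfer, short branch);
#' * `VERTICAL` — the query attaches inside the metazoan clade;
#' * `CONTAMINATION` — vertical placement, but `n_contaminants` bacterial
#'   leaves are (falsely) labeled metazoan in the class map, emulating
#'   database contamination that disrupts animal monophyly.
#'
#' Clade-internal branch lengths are exponential with mean
#' `0.15 * divergence_scale`; domain stems add `0.4 * divergence_scale`
#' plus an exponential tail, so domains are well separated at the default
#' scale. Deterministic for a fixed seed.
#'
#' @param kind one of `"HGT_FROM_BACTERIA"`, `"HGT_FROM_EUK"`,
#'   `"VERTICAL"`, `"CONTAMINATION"`.
#' @param n_bacteria,n_euk,n_metazoa clade sizes (each >= 2).
#' @param n_sites alignment length (>= 50).
#' @param divergence_scale multiplies every branch length.
#' @param seed integer seed.
#' @param model substitution model used for sequence simulation.
#' @param n_contaminants bacterial leaves relabeled metazoan
#'   (CONTAMINATION only).
#' @return an object of class `hgt_scenario`: `kind`, `tree`, `alignment`,
#'   `query`, `taxon_map`, `contaminant_leaves`, `model`.
#' @export
simulate_hgt_scenario <- function(kind = c("HGT_FROM_BACTERIA",
                                           "HGT_FROM_EUK", "VERTICAL",
                                           "CONTAMINATION"),
                                  n_bacteria = 10L, n_euk = 10L,
                                  n_metazoa = 10L, n_sites = 300L,
                                  divergence_scale = 1, seed = 1L,
                                  model = substitution_model(),
                                  n_contaminants = 2L) {
  kind <- match.arg(kind)
  if (min(n_bacteria, n_euk, n_metazoa) < 2) stop("clade sizes must be >= 2")
  if (n_sites < 50) stop("n_sites must be >= 50")
  seeds <- derive_seeds(seed, 2)
  query <- "QUERY_CTENO"
  bac <- sprintf("BAC%02d", seq_len(n_bacteria))
  euk <- sprintf("EUK%02d", seq_len(n_euk))
  met <- sprintf("MET%02d", seq_len(n_metazoa))
  ds <- divergence_scale

  tree <- with_seed(seeds[1], {
    clade <- function(labs, mean_len) {
      pool <- paste0(labs, ":", signif(rexp(length(labs), 1 / mean_len) +
                                         0.01, 4))
      while (length(pool) > 1) {
        i <- sample(length(pool), 2)
        joined <- paste0("(", pool[i[1]], ",", pool[i[2]], "):",
                         signif(rexp(1, 1 / mean_len) + 0.01, 4))
        pool <- c(pool[-i], joined)
      }
      sub(":[0-9.eE+-]+$", "", pool)
    }
    stem <- function() signif(0.4 * ds + rexp(1, 1 / (0.2 * ds)), 4)
    nwk <- paste0("(", clade(bac, 0.15 * ds), ":", stem(), ",",
                  clade(euk, 0.15 * ds), ":", stem(), ",",
                  clade(met, 0.15 * ds), ":", stem(), ");")
    tr <- ape::read.tree(text = nwk)
    host <- switch(kind,
                   HGT_FROM_BACTERIA = sample(bac, 1),
                   HGT_FROM_EUK = sample(euk, 1),
                   sample(met, 1))
    graft_len <- signif(0.1 * ds + 0.01, 4)
    attach_query(tr, host, query, graft_len)
  })

  aln <- simulate_alignment(tree, model, n_sites, seeds[2])

  contaminants <- character()
  cls <- c(setNames(rep("bacteria", n_bacteria), bac),
           setNames(rep("euk_nonmetazoan", n_euk), euk),
           setNames(rep("metazoan", n_metazoa), met),
           setNames("metazoan", query))
  phyla <- c(setNames(rep(c("Proteobacteria", "Firmicutes"),
                          length.out = n_bacteria), bac),
             setNames(rep(c("Chlorophyta", "Streptophyta"),
                          length.out = n_euk), euk),
             setNames(rep(c("Chordata", "Arthropoda", "Cnidaria",
                            "Porifera", "Annelida"),
                          length.out = n_metazoa), met),
             setNames("Ctenophora", query))
  if (kind == "CONTAMINATION") {
    if (n_contaminants > n_bacteria)
      stop("more contaminants than bacterial leaves")
    contaminants <- bac[seq_len(n_contaminants)]
    cls[contaminants] <- "metazoan"
    phyla[contaminants] <- "Chordata"
  }
  taxon_map <- as_taxon_map(tibble::tibble(
    subject = names(cls),
    organism = paste0("Genus_", names(cls), " species"),
    class = unname(cls), phylum = unname(phyla)
  ))
  structure(
    list(kind = kind, tree = tree, alignment = aln, query = query,
         taxon_map = taxon_map, contaminant_leaves = contaminants,
         model = model,
         params = list(n_bacteria = n_bacteria, n_euk = n_euk,
                       n_metazoa = n_metazoa, n_sites = n_sites,
                       divergence_scale = divergence_scale, seed = seed)),
    class = "hgt_scenario"
  )
}

# replace leaf `host` by the cherry (host, query), both on short branches
attach_query <- function(tree, host, query, len) {
  nwk <- ape::write.tree(tree)
  stopifnot(grepl(host, nwk, fixed = TRUE))
  cherry <- paste0("(", host, ":", len, ",", query, ":", len, ")")
  ape::read.tree(text = sub(paste0(host, "(?=[:,)])"), cherry, nwk,
                            perl = TRUE))
}

#' @export
print.hgt_scenario <- function(x, ...) {
  cat("<hgt_scenario> ", x$kind, ": ", length(x$tree$tip.label),
      " leaves, ", n_sites(x$alignment), " sites",
      if (length(x$contaminant_leaves))
        paste0(", ", length(x$contaminant_leaves), " contaminant leaf/leaves"),
      "\n", sep = "")
  invisible(x)
}

#' Synthesize a similarity table from a scenario
#'
#' Maps pairwise identity between the query and every subject sequence to a
#' bit score and E-value with a Karlin-Altschul-shaped fixture convention:
#' `bits = max(0, 2 * identity * n_sites)` and
#' `evalue = n_sites^2 * 2^(-bits)`, clamped to `[1e-180, 10]`. Hits are
#' sorted by ascending E-value. The constants are fixture conventions, not
#' claims about any search program.
#'
#' @param scenario an `hgt_scenario`.
#' @param seed kept for interface symmetry; the table is a deterministic
#'   function of the scenario alignment.
#' @return similarity tibble in the shape of [read_similarity_table()].
#' @export
simulate_similarity_table <- function(scenario, seed = 1L) {
  aln <- scenario$alignment
  q <- scenario$query
  subjects <- setdiff(names(aln), q)
  qs <- strsplit(unclass(aln)[[q]], "")[[1]]
  n <- length(qs)
  p <- vapply(subjects, function(s) {
    ss <- strsplit(unclass(aln)[[s]], "")[[1]]
    mean(qs == ss)
  }, 0)
  bits <- pmax(0, 2 * p * n)
  evalue <- pmin(pmax(n * n * 2^(-bits), 1e-180), 10)
  out <- tibble::tibble(
    query = q, subject = subjects, pident = 100 * p, length = n,
    evalue = unname(evalue), bitscore = unname(bits)
  )
  out <- out[order(out$evalue, -out$bitscore), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Write a similarity tibble as 12-column tabular text
#'
#' @param hits similarity tibble.
#' @param path output path.
#' @export
write_similarity_table <- function(hits, path) {
  df <- data.frame(
    qseqid = hits$query, sseqid = hits$subject,
    pident = round(hits$pident, 3), length = hits$length,
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = hits$length,
    sstart = 1L, send = hits$length,
    evalue = format(hits$evalue, digits = 3, scientific = TRUE),
    bitscore = round(hits$bitscore, 1)
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Simulate a developmental expression timecourse
#'
#' Draws negative-binomial counts for focal genes with one of four profile
#' shapes over the timecourse, plus a constant background transcriptome
#' that absorbs the library so per-million values are realistic:
#'
#' * `maternal` — high at fertilization, exponentially decaying;
#' * `zygotic_spike` — Gaussian bump around tentacle morphogenesis
#'   (10 hours post fertilization);
#' * `cyclic` — sinusoid over development (6 h period);
#' * `silent` — near-zero throughout.
#'
#' @param profiles named character vector: gene id -> profile.
#' @param n_timepoints distinct time points (default 25 over 0-20 h).
#' @param reps_per_tp replicates per time point.
#' @param seed integer seed.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param n_background background genes (`BG0001`, ...).
#' @return an `expression_matrix` of raw counts.
#' @export
simulate_expression_matrix <- function(profiles, n_timepoints = 25L,
                                       reps_per_tp = 3L, seed = 1L,
                                       dispersion = 0.2,
                                       n_background = 500L) {
  stopifnot(reps_per_tp >= 1)
  known <- c("maternal", "zygotic_spike", "cyclic", "silent")
  bad <- setdiff(unique(profiles), known)
  if (length(bad)) stop("unknown profile(s): ", paste(bad, collapse = ", "))
  hours <- seq(0, 20, length.out = n_timepoints)
  mu_of <- function(profile) switch(
    profile,
    maternal = 300 * exp(-hours / 3) + 0.5,
    zygotic_spike = 250 * exp(-(hours - 10)^2 / (2 * 1.5^2)) + 2,
    cyclic = 60 * (1 + sin(2 * pi * hours / 6)) + 5,
    silent = rep(0.05, n_timepoints)
  )
  with_seed(seed, {
    genes <- names(profiles)
    bg <- sprintf("BG%04d", seq_len(n_background))
    bg_mu <- exp(rnorm(n_background, log(80), 0.8))
    samples <- as.vector(t(outer(seq_len(n_timepoints), seq_len(reps_per_tp),
                                 function(t, r) sprintf("T%02d_R%d", t, r))))
    meta <- tibble::tibble(
      sample = samples,
      hours = rep(hours, each = reps_per_tp),
      replicate = rep(seq_len(reps_per_tp), n_timepoints)
    )
    size <- 1 / dispersion
    counts <- matrix(0, length(genes) + n_background, nrow(meta),
                     dimnames = list(c(genes, bg), meta$sample))
    for (g in seq_along(genes)) {
      mu <- mu_of(profiles[[g]])[match(meta$hours, hours)]
      counts[g, ] <- rnbinom(nrow(meta), mu = mu, size = size)
    }
    for (b in seq_len(n_background)) {
      counts[length(genes) + b, ] <- rnbinom(nrow(meta), mu = bg_mu[b],
                                             size = size)
    }
    expression_matrix(counts, meta, normalized = FALSE)
  })
}

#' Simulate intron-bearing gene models with a genome
#'
#' Emits a random small genome (one scaffold per gene, both strands used),
#' exon/intron gene models, and a per-intron truth table saying whether the
#' splice sites were written canonically (GT donor / AG acceptor in
#' transcript orientation). Fixture for the splice-site contamination
#' screen.
#'
#' @param n_genes number of genes.
#' @param introns_per_gene introns per gene.
#' @param canonical_fraction probability each intron is written canonical.
#' @param seed integer seed.
#' @return list with `genome` (`DNAStringSet`), `models` (tibble in the
#'   [read_gene_models()] shape), `truth` (tibble gene/intron/canonical).
#' @export
simulate_gene_models <- function(n_genes = 6L, introns_per_gene = 2L,
                                 canonical_fraction = 1, seed = 1L) {
  stopifnot(canonical_fraction >= 0, canonical_fraction <= 1)
  with_seed(seed, {
    genomes <- character(n_genes)
    scaffolds <- sprintf("scf%02d", seq_len(n_genes))
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    models <- vector("list", n_genes)
    truth <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      strand <- sample(c("+", "-"), 1)
      n_exons <- introns_per_gene + 1L
      exon_len <- sample(30:90, n_exons, replace = TRUE)
      intron_len <- sample(20:60, max(introns_per_gene, 1), replace = TRUE)
      pos <- 51L
      exons <- matrix(0L, n_exons, 2)
      introns <- matrix(0L, introns_per_gene, 2)
      for (i in seq_len(n_exons)) {
        exons[i, ] <- c(pos, pos + exon_len[i] - 1L)
        pos <- pos + exon_len[i]
        if (i <= introns_per_gene) {
          introns[i, ] <- c(pos, pos + intron_len[i] - 1L)
          pos <- pos + intron_len[i]
        }
      }
      glen <- pos + 50L
      seqc <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
      canon <- if (introns_per_gene > 0)
        runif(introns_per_gene) < canonical_fraction else logical()
      for (i in seq_len(introns_per_gene)) {
        s <- introns[i, 1]; e <- introns[i, 2]
        if (canon[i]) {
          if (strand == "+") {
            seqc[s:(s + 1)] <- c("G", "T"); seqc[(e - 1):e] <- c("A", "G")
          } else {
            seqc[s:(s + 1)] <- c("C", "T"); seqc[(e - 1):e] <- c("A", "C")
          }
        } else {
          seqc[s:(s + 1)] <- c("A", "A"); seqc[(e - 1):e] <- c("A", "A")
        }
      }
      genomes[g] <- paste0(seqc, collapse = "")
      models[[g]] <- tibble::tibble(
        gene = genes[g], scaffold = scaffolds[g], strand = strand,
        exons = list(cbind(start = exons[, 1], end = exons[, 2]))
      )
      if (introns_per_gene > 0) {
        ord <- if (strand == "+") seq_len(introns_per_gene)
               else rev(seq_len(introns_per_gene))
        truth[[g]] <- tibble::tibble(gene = genes[g],
                                     intron = seq_len(introns_per_gene),
                                     canonical = canon[ord])
      }
    }
    genome <- Biostrings::DNAStringSet(setNames(genomes, scaffolds))
    list(genome = genome, models = dplyr::bind_rows(models),
         truth = dplyr::bind_rows(truth))
  })
}

#' Write gene models as GFF3
#'
#' @param models tibble in the [read_gene_models()] shape.
#' @param path output path.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    g <- models$gene[i]
    lines <- c(lines,
               paste(models$scaffold[i], "hgtscreen", "gene",
                     min(ex[, 1]), max(ex[, 2]), ".", models$strand[i], ".",
                     paste0("ID=", g), sep = "\t"),
               vapply(seq_len(nrow(ex)), function(j)
                 paste(models$scaffold[i], "hgtscreen", "exon",
                       ex[j, 1], ex[j, 2], ".", models$strand[i], ".",
                       paste0("ID=", g, ".exon", j, ";Parent=", g),
                       sep = "\t"), ""))
  }
  writeLines(lines, path)
  invisible(path)
}
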