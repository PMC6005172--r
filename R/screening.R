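#' Read exon-level gene models from GFF3
#'
#' Extracts exon rows from a GFF3 file into one record per gene: scaffold,
#' strand, and an ordered list of 1-based inclusive exon coordinates. The
#' parent gene is taken from the `Parent=` attribute (falling back to
#' `ID=`), with the common `.tN`/`-RA` transcript suffixes stripped.
#'
#' @param path GFF3 file path.
#' @return tibble with columns `gene`, `scaffold`, `strand`, `exons`
#'   (list-column of two-column start/end matrices sorted by start).
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(f) == 9
  if (!all(ok)) stop("malformed GFF3 line(s): ", which(!ok)[1])
  type <- vapply(f, `[`, "", 3)
  keep <- which(type == "exon")
  if (!length(keep)) stop("no exon features in ", path)
  attr9 <- vapply(f[keep], `[`, "", 9)
  parent <- stringr::str_match(attr9, "Parent=([^;]+)")[, 2]
  id <- stringr::str_match(attr9, "ID=([^;]+)")[, 2]
  gene <- ifelse(is.na(parent), id, parent)
  gene <- sub("\\.t\\d+$|-R[A-Z]$", "", gene)
  df <- tibble::tibble(
    gene = gene,
    scaffold = vapply(f[keep], `[`, "", 1),
    strand = vapply(f[keep], `[`, "", 7),
    start = as.integer(vapply(f[keep], `[`, "", 4)),
    end = as.integer(vapply(f[keep], `[`, "", 5))
  )
  if (any(is.na(df$gene))) stop("exon row without Parent/ID attribute")
  df |>
    dplyr::group_by(.data$gene, .data$scaffold, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(exons = list(cbind(start = .data$start,
                                        end = .data$end)),
                     .groups = "drop")
}

#' Splice-site check for a gene model
#'
#' Reads the donor and acceptor dinucleotides of every intron of a gene
#' model from the genome and flags the canonical U2 spliceosomal pattern
#' (GT donor, AG acceptor, case-insensitive). Introns are the gaps between
#' consecutive exons; on the minus strand the dinucleotides are read from
#' the reverse complement, in transcript orientation. Spliceosomal introns
#' are eukaryote-specific, so canonical splice sites argue against a gene
#' model being bacterial contamination.
#'
#' @param gene gene id.
#' @param scaffold scaffold name (must exist in `genome`).
#' @param strand "+" or "-".
#' @param exons two-column start/end matrix, 1-based inclusive,
#'   non-overlapping, sorted by start.
#' @param genome a `Biostrings::DNAStringSet` (or named character vector).
#' @return tibble with one row per intron: `gene`, `intron`, `donor`,
#'   `acceptor`, `canonical`; zero rows for single-exon models.
#' @export
check_splice_sites <- function(gene, scaffold, strand, exons, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!scaffold %in% names(genome)) stop("scaffold not in genome: ", scaffold)
  seqlen <- Biostrings::width(genome)[match(scaffold, names(genome))]
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 1] > exons[, 2])) stop("exon with start > end")
  if (any(exons[, 1] < 1) || any(exons[, 2] > seqlen))
    stop("exon outside scaffold bounds for ", gene)
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("overlapping exons for ", gene)
  n_introns <- nrow(exons) - 1
  if (n_introns < 1)
    return(tibble::tibble(gene = character(), intron = integer(),
                          donor = character(), acceptor = character(),
                          canonical = logical()))
  chr <- genome[[scaffold]]
  rows <- lapply(seq_len(n_introns), function(i) {
    istart <- exons[i, 2] + 1L
    iend <- exons[i + 1, 1] - 1L
    if (iend - istart + 1L < 4L)
      stop("intron ", i, " of ", gene, " is shorter than 4 bases")
    left <- as.character(Biostrings::subseq(chr, istart, istart + 1L))
    right <- as.character(Biostrings::subseq(chr, iend - 1L, iend))
    if (strand == "+") {
      donor <- left; acceptor <- right
    } else {
      rc <- function(s) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
      donor <- rc(right); acceptor <- rc(left)
    }
    tibble::tibble(donor = toupper(donor), acceptor = toupper(acceptor))
  })
  out <- dplyr::bind_rows(rows)
  # introns are numbered in transcript orientation
  ord <- if (strand == "+") seq_len(n_introns) else rev(seq_len(n_introns))
  tibble::tibble(gene = gene, intron = seq_len(n_introns),
                 donor = out$donor[ord], acceptor = out$acceptor[ord],
                 canonical = out$donor[ord] == "GT" &
                   out$acceptor[ord] == "AG")
}

#' Splice report over a set of gene models
#'
#' @param models tibble from [read_gene_models()] (or the same shape).
#' @param genome genome sequences.
#' @return tibble with one row per intron across all genes.
#' @export
splice_report <- function(models, genome) {
  dplyr::bind_rows(purrr::pmap(
    models[c("gene", "scaffold", "strand", "exons")],
    function(gene, scaffold, strand, exons)
      check_splice_sites(gene, scaffold, strand, exons, genome)))
}

# best hit per query under the reciprocal-best-hit tie-break rules
best_per_query <- function(hits, evalue_cutoff) {
  hits |>
    dplyr::filter(.data$evalue <= evalue_cutoff) |>
    dplyr::group_by(.data$query) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$rank,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Reciprocal best hits between two datasets
#'
#' A pair `(a, b)` is reciprocal when `b` is `a`'s best hit in the A-vs-B
#' table and `a` is `b`'s best hit in the B-vs-A table, both passing the
#' E-value cutoff (default 0.1, the screen used for cross-transcriptome
#' presence checks). Best = lowest E-value, ties broken by bit score then
#' file rank.
#'
#' @param hits_ab,hits_ba similarity tibbles (see
#'   [read_similarity_table()]).
#' @param evalue_cutoff inclusive cutoff.
#' @return tibble with columns `a`, `b`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_cutoff = 0.1) {
  ab <- best_per_query(hits_ab, evalue_cutoff)
  ba <- best_per_query(hits_ba, evalue_cutoff)
  m <- dplyr::inner_join(
    dplyr::select(ab, a = "query", b = "subject"),
    dplyr::select(ba, b = "query", a_back = "subject"),
    by = "b")
  m |>
    dplyr::filter(.data$a == .data$a_back) |>
    dplyr::select("a", "b")
}

#' Close-relative screen
#'
#' Flags a gene when its top-ranked hit passing the E-value cutoff belongs
#' to one of the flagged groups (by default Choanoflagellatea and
#' Filasterea, the closest protistan relatives of animals): such hits make
#' vertical inheritance plausible, so the gene is removed from HGT
#' contention.
#'
#' @param hits similarity tibble for one gene.
#' @param taxon_map taxon map whose `phylum` carries the group labels.
#' @param flagged_groups group labels that trigger removal.
#' @param evalue_cutoff inclusive cutoff for the top hit.
#' @return logical: `TRUE` when the gene should be removed.
#' @export
screen_close_relatives <- function(hits, taxon_map,
                                   flagged_groups = c("Choanoflagellatea",
                                                      "Filasterea"),
                                   evalue_cutoff = 0.1) {
  if (!nrow(hits)) stop("hits must be non-empty")
  taxon_map <- as_taxon_map(taxon_map)
  h <- dplyr::left_join(hits, taxon_map, by = "subject") |>
    dplyr::filter(.data$evalue <= evalue_cutoff) |>
    dplyr::arrange(.data$rank)
  if (!nrow(h)) return(FALSE)
  h$phylum[1] %in% flagged_groups
}

#' Select taxa for gene-tree inference from ranked hits
#'
#' Walks a gene's hits in rank order and keeps the top `per_group` subjects
#' in each of four groups — bacteria (with archaea), non-fungal non-metazoan
#' eukaryotes, fungi, and animals — skipping any subject whose genus was
#' already taken within that group (one sequence per genus). Hits must pass
#' the E-value cutoff. Afterwards the best hit of each `must_include`
#' organism is appended if not already selected.
#'
#' @param hits similarity tibble for one gene.
#' @param taxon_map taxon map (organism names supply the genus: first word).
#' @param per_group subjects kept per group.
#' @param evalue_cutoff inclusive cutoff.
#' @param must_include organisms whose best passing hit is always added.
#' @return tibble of selected hits with `group` and `genus` columns.
#' @export
select_phylo_taxa <- function(hits, taxon_map, per_group = 10L,
                              evalue_cutoff = 0.1,
                              must_include = character()) {
  taxon_map <- as_taxon_map(taxon_map)
  h <- dplyr::inner_join(hits, taxon_map, by = "subject") |>
    dplyr::filter(.data$evalue <= evalue_cutoff) |>
    dplyr::mutate(
      genus = stringr::word(.data$organism, 1),
      group = dplyr::case_when(
        .data$class %in% c("bacteria", "archaea") ~ "bacteria",
        .data$class == "metazoan" ~ "animals",
        .data$is_fungus ~ "fungi",
        TRUE ~ "eukaryotes"
      )
    ) |>
    dplyr::arrange(.data$rank)
  sel <- h |>
    dplyr::group_by(.data$group) |>
    dplyr::filter(!duplicated(.data$genus)) |>
    dplyr::slice_head(n = per_group) |>
    dplyr::ungroup()
  extra <- h |>
    dplyr::filter(.data$organism %in% must_include,
                  !.data$subject %in% sel$subject) |>
    dplyr::group_by(.data$organism) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$rank,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  dplyr::bind_rows(sel, extra)
}

#' Classify an HGT candidate by its animal-hit counts
#'
#' Branching rule applied after the database-wide screen (counts computed
#' at E-value <= 0.1 after self-phylum exclusion): a candidate with no
#' animal hits at all is treated as an HGT absent from other animals (no
#' phylogenetic test possible); one with only one or two animal hits is
#' discarded as possible contamination; three or more animal hits send the
#' candidate to phylogenetic testing.
#'
#' @param n_animal_hits,n_nonanimal_hits hit counts.
#' @return one of `"NO_ANIMAL_HITS_HGT"`, `"TOO_FEW_ANIMAL_HITS_DISCARD"`,
#'   `"PHYLO_TEST"`.
#' @export
classify_candidate <- function(n_animal_hits, n_nonanimal_hits) {
  stopifnot(length(n_animal_hits) == 1, length(n_nonanimal_hits) == 1)
  if (n_animal_hits == 0 && n_nonanimal_hits == 0)
    stop("candidate with no hits at all cannot have been screened in")
  if (n_animal_hits == 0) return("NO_ANIMAL_HITS_HGT")
  if (n_animal_hits <= 2) return("TOO_FEW_ANIMAL_HITS_DISCARD")
  "PHYLO_TEST"
}

#' Presence/absence matrix across transcriptome datasets
#'
#' Summarizes reciprocal-best-hit results of a gene set against several
#' transcriptomes into a gene x dataset presence matrix.
#'
#' @param rbh_by_dataset named list of tibbles from
#'   [reciprocal_best_hits()] (column `a` = gene).
#' @param genes gene universe for the rows.
#' @return tibble, first column `gene`, one logical column per dataset.
#' @export
presence_absence_matrix <- function(rbh_by_dataset, genes) {
  cols <- lapply(rbh_by_dataset, function(tb) genes %in% tb$a)
  tibble::as_tibble(c(list(gene = genes), cols))
}
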