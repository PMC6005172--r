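#' Read tabular similarity-search output (outfmt-6 dialect)
#'
#' Parses the standard 12+ column tab-separated BLAST tabular format
#' (qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore). Extra columns are ignored. Hits keep their file
#' order; `rank` numbers them 1..n within each query.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of raw lines (overrides `path`).
#' @return tibble of hits with columns `query`, `subject`, `pident`,
#'   `length`, `evalue`, `bitscore`, `rank`.
#' @export
read_similarity_table <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(tibble::tibble(query = character(), subject = character(),
                          pident = numeric(), length = integer(),
                          evalue = numeric(), bitscore = numeric(),
                          rank = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop("malformed similarity table: line ", which(nf < 12)[1],
         " has ", nf[which(nf < 12)[1]], " fields (expected >= 12)")
  get <- function(i) vapply(fields, `[`, "", i)
  evalue <- suppressWarnings(as.numeric(get(11)))
  bitscore <- suppressWarnings(as.numeric(get(12)))
  bad <- which(is.na(evalue) | is.na(bitscore))
  if (length(bad))
    stop("malformed similarity table: non-numeric evalue/bitscore at line ",
         bad[1])
  if (any(evalue < 0) || any(bitscore < 0))
    stop("negative evalue or bitscore at line ",
         which(evalue < 0 | bitscore < 0)[1])
  out <- tibble::tibble(
    query = get(1), subject = get(2),
    pident = suppressWarnings(as.numeric(get(3))),
    length = suppressWarnings(as.integer(get(4))),
    evalue = evalue, bitscore = bitscore
  )
  dplyr::mutate(dplyr::group_by(out, .data$query),
                rank = dplyr::row_number()) |> dplyr::ungroup()
}

#' Read a taxon class map
#'
#' Maps database subject identifiers to an organism, one of the four closed
#' taxon classes (`bacteria`, `archaea`, `euk_nonmetazoan`, `metazoan`),
#' and a phylum. Accepts a TSV (columns: subject, class, phylum, and
#' optionally organism, is_fungus) or a JSON object keyed by subject.
#' Unknown class labels are rejected at load.
#'
#' @param path file path (TSV or JSON, detected by extension).
#' @return tibble with columns `subject`, `organism`, `class`, `phylum`,
#'   `is_fungus`.
#' @export
read_taxon_map <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- tibble::as_tibble(obj)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE)
  }
  as_taxon_map(df)
}

#' @rdname read_taxon_map
#' @param df data frame with at least `subject`, `class`, `phylum`.
#' @export
as_taxon_map <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("subject", "class", "phylum")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("taxon map lacks columns: ", paste(miss, collapse = ", "))
  if (!"organism" %in% names(df)) df$organism <- df$subject
  if (!"is_fungus" %in% names(df)) df$is_fungus <- FALSE
  df$class <- tolower(df$class)
  bad <- setdiff(unique(df$class), TAXON_CLASSES)
  if (length(bad))
    stop("unknown taxon class label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(TAXON_CLASSES, collapse = ", "), ")")
  if (anyDuplicated(df$subject))
    stop("subjects mapped more than once: ",
         paste(unique(df$subject[duplicated(df$subject)]), collapse = ", "))
  df[c("subject", "organism", "class", "phylum", "is_fungus")]
}

#' Alien index
#'
#' Log-scale difference between the best (smallest) animal and non-animal
#' E-values: `AI = ln(E_meta + 1e-200) - ln(E_nonmeta + 1e-200)`. Positive
#' values favour a non-animal origin; the candidate screen uses `AI > 45`.
#' A class with no hit contributes `E = 1` (the worst plausible hit), which
#' keeps the index finite and directionally correct.
#'
#' @param best_meta_evalue,best_nonmeta_evalue best E-values per class
#'   (vectorized); `NA` means no hit in that class.
#' @return numeric alien index.
#' @export
#' @examples
#' alien_index(1e-10, 1e-10) # 0
#' alien_index(NA, 1e-30)    # ~ 69.08 = 30 * ln(10)
alien_index <- function(best_meta_evalue, best_nonmeta_evalue) {
  e_m <- ifelse(is.na(best_meta_evalue), 1, best_meta_evalue)
  e_n <- ifelse(is.na(best_nonmeta_evalue), 1, best_nonmeta_evalue)
  if (any(e_m < 0, na.rm = TRUE) || any(e_n < 0, na.rm = TRUE))
    stop("E-values must be non-negative")
  log(e_m + 1e-200) - log(e_n + 1e-200)
}

#' HGT index
#'
#' Difference between the highest non-animal and animal bit scores; a class
#' with no hit contributes 0 bits. Reported alongside the alien index but
#' never used for candidate filtering.
#'
#' @param best_nonmeta_bits,best_meta_bits best bit scores per class
#'   (vectorized); `NA` means no hit.
#' @return numeric HGT index.
#' @export
hgt_index <- function(best_nonmeta_bits, best_meta_bits) {
  b_n <- ifelse(is.na(best_nonmeta_bits), 0, best_nonmeta_bits)
  b_m <- ifelse(is.na(best_meta_bits), 0, best_meta_bits)
  b_n - b_m
}

#' Best hit per taxon class for one query
#'
#' Splits a query's hits into animal (metazoan) and non-animal classes and
#' returns the best hit of each: lowest E-value, ties broken by higher bit
#' score, then earlier file rank. Hits whose subject phylum equals
#' `self_phylum` are excluded from both classes, so the query organism's own
#' phylum in the database cannot mask a transfer. Subjects missing from the
#' map are skipped with a warning.
#'
#' @param hits tibble of hits for a single query (see
#'   [read_similarity_table()]).
#' @param taxon_map taxon map (see [read_taxon_map()]).
#' @param self_phylum phylum of the query organism.
#' @return list with `best_meta` and `best_nonmeta` (each a one-row tibble
#'   or `NULL`), plus hit counts per class.
#' @export
best_hits_by_class <- function(hits, taxon_map, self_phylum) {
  taxon_map <- as_taxon_map(taxon_map)
  h <- dplyr::left_join(hits, taxon_map, by = "subject")
  unresolved <- is.na(h$class)
  if (any(unresolved)) {
    warning("skipping ", sum(unresolved), " hit(s) with unmapped subjects: ",
            paste(head(unique(h$subject[unresolved]), 3), collapse = ", "))
    h <- h[!unresolved, ]
  }
  h <- h[h$phylum != self_phylum, ]
  pick <- function(sub) {
    if (!nrow(sub)) return(NULL)
    sub <- sub[order(sub$evalue, -sub$bitscore, sub$rank), ]
    sub[1, ]
  }
  meta <- h[h$class == "metazoan", ]
  nonmeta <- h[h$class != "metazoan", ]
  list(best_meta = pick(meta), best_nonmeta = pick(nonmeta),
       n_meta_hits = nrow(meta), n_nonmeta_hits = nrow(nonmeta))
}

#' Score genes by alien index and HGT index
#'
#' Per-query summary of a similarity table: best animal and non-animal
#' E-values and bit scores (after self-phylum exclusion), hit counts, the
#' alien index, the HGT index, and the candidate flag (`AI > ai_threshold`,
#' strict).
#'
#' @param hits similarity tibble (possibly many queries).
#' @inheritParams best_hits_by_class
#' @param ai_threshold candidate threshold on the alien index (strict `>`).
#' @return tibble with one row per query gene.
#' @export
score_alien_index <- function(hits, taxon_map, self_phylum,
                              ai_threshold = 45) {
  taxon_map <- as_taxon_map(taxon_map)
  empty <- tibble::tibble(
    gene = character(), best_meta_evalue = numeric(),
    best_nonmeta_evalue = numeric(), best_meta_bits = numeric(),
    best_nonmeta_bits = numeric(), n_meta_hits = integer(),
    n_nonmeta_hits = integer(), alien_index = numeric(),
    hgt_index = numeric(), candidate = logical()
  )
  if (!nrow(hits)) return(empty)
  hits |>
    dplyr::group_by(gene = .data$query) |>
    dplyr::group_modify(function(g, key) {
      b <- suppressWarnings(
        best_hits_by_class(g, taxon_map, self_phylum))
      tibble::tibble(
        best_meta_evalue = if (is.null(b$best_meta)) NA_real_
                           else b$best_meta$evalue,
        best_nonmeta_evalue = if (is.null(b$best_nonmeta)) NA_real_
                              else b$best_nonmeta$evalue,
        best_meta_bits = if (is.null(b$best_meta)) NA_real_
                         else b$best_meta$bitscore,
        best_nonmeta_bits = if (is.null(b$best_nonmeta)) NA_real_
                            else b$best_nonmeta$bitscore,
        n_meta_hits = b$n_meta_hits,
        n_nonmeta_hits = b$n_nonmeta_hits
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      alien_index = alien_index(.data$best_meta_evalue,
                                .data$best_nonmeta_evalue),
      hgt_index = hgt_index(.data$best_nonmeta_bits, .data$best_meta_bits),
      candidate = .data$alien_index > ai_threshold
    )
}

#' Filter HGT candidates by alien index
#'
#' Retains genes with `alien_index` strictly greater than the threshold
#' (the published screen used `AI > 45`), sorted by descending alien index.
#'
#' @param scored tibble from [score_alien_index()].
#' @param ai_threshold strict threshold.
#' @return filtered, sorted tibble.
#' @export
candidate_filter <- function(scored, ai_threshold = 45) {
  scored |>
    dplyr::filter(.data$alien_index > ai_threshold) |>
    dplyr::arrange(dplyr::desc(.data$alien_index))
}

#' Write the per-gene score table
#'
#' @param scored tibble from [score_alien_index()].
#' @param path TSV output path.
#' @export
write_score_table <- function(scored, path) {
  readr::write_tsv(scored, path)
  invisible(path)
}
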