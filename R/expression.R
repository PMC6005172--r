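#' Developmental expression matrices
#'
#' Container for a gene x sample count matrix from a 3'-tag protocol
#' (CEL-Seq style) plus per-sample metadata (hours post fertilization and
#' replicate). Counts are normalized per million without transcript-length
#' correction, because 3'-end counting yields one tag per transcript.
#'
#' @param counts numeric gene x sample matrix (rownames = genes, colnames =
#'   samples), non-negative.
#' @param sample_meta data frame with columns `sample`, `hours`,
#'   `replicate` covering every count column.
#' @param normalized whether `counts` are already per-million values.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, sample_meta, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  sample_meta <- tibble::as_tibble(sample_meta)
  need <- c("sample", "hours", "replicate")
  miss <- setdiff(need, names(sample_meta))
  if (length(miss)) stop("sample_meta lacks columns: ",
                         paste(miss, collapse = ", "))
  absent <- setdiff(colnames(counts), sample_meta$sample)
  if (length(absent)) stop("samples without metadata: ",
                           paste(absent, collapse = ", "))
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample), ]
  structure(list(counts = counts, sample_meta = sample_meta,
                 normalized = normalized),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$counts), " genes x ",
      ncol(x$counts), " samples (",
      length(unique(x$sample_meta$hours)), " time points; ",
      if (x$normalized) "per-million normalized" else "raw counts",
      ")\n", sep = "")
  invisible(x)
}

#' Read counts + metadata from TSV files
#'
#' @param counts_path genes x samples TSV, first column = gene id.
#' @param meta_path sample metadata TSV with columns `sample`, `hours`,
#'   `replicate`.
#' @return an `expression_matrix` of raw counts.
#' @export
read_expression_tsv <- function(counts_path, meta_path) {
  cdf <- readr::read_tsv(counts_path, show_col_types = FALSE)
  counts <- as.matrix(cdf[, -1])
  rownames(counts) <- as.character(cdf[[1]])
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  expression_matrix(counts, meta, normalized = FALSE)
}

#' Per-million normalization
#'
#' Divides each sample's counts by the sample total and multiplies by 1e6
#' (tags per million; no transcript-length term). Samples with zero counted
#' reads are left all-zero with a warning.
#'
#' @param mat an `expression_matrix` of raw counts.
#' @return a normalized `expression_matrix` (columns sum to 1e6 for
#'   non-empty samples).
#' @export
normalize_per_million <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (mat$normalized) stop("matrix is already normalized")
  totals <- colSums(mat$counts)
  zero <- totals == 0
  if (any(zero))
    warning("sample(s) with zero counted reads left unnormalized: ",
            paste(colnames(mat$counts)[zero], collapse = ", "))
  scaled <- sweep(mat$counts, 2, ifelse(zero, 1, totals), "/") * 1e6
  scaled[, zero] <- 0
  expression_matrix(scaled, mat$sample_meta, normalized = TRUE)
}

#' Summed-median developmental expression score
#'
#' For each gene, takes the median normalized value across replicates at
#' every distinct time point and sums those medians over the timecourse.
#' Even replicate counts use the midpoint median. Genes scoring at or above
#' the threshold (default 100 tpm summed over the timecourse) are flagged
#' as developmentally expressed.
#'
#' @param mat a normalized `expression_matrix`.
#' @param genes genes to score (default: all).
#' @param threshold inclusive expression threshold.
#' @return tibble with columns `gene`, `score`, `expressed`.
#' @export
developmental_expression_score <- function(mat, genes = rownames(mat$counts),
                                           threshold = 100) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (!mat$normalized)
    stop("scores are defined on per-million normalized values; ",
         "run normalize_per_million() first")
  absent <- setdiff(genes, rownames(mat$counts))
  if (length(absent)) stop("gene(s) absent from matrix: ",
                           paste(absent, collapse = ", "))
  hours <- mat$sample_meta$hours
  tps <- sort(unique(hours))
  med_by_tp <- vapply(tps, function(tp) {
    cols <- which(hours == tp)
    apply(mat$counts[genes, cols, drop = FALSE], 1, median)
  }, numeric(length(genes)))
  score <- if (length(genes) == 1) sum(med_by_tp) else rowSums(med_by_tp)
  tibble::tibble(gene = genes, score = unname(score),
                 expressed = classify_expressed(unname(score), threshold))
}

#' Expression classification rule
#'
#' @param score summed-median score (non-negative).
#' @param threshold inclusive threshold (default 100).
#' @return logical: `score >= threshold`.
#' @export
#' @examples
#' classify_expressed(100)    # TRUE (boundary inclusive)
#' classify_expressed(99.999) # FALSE
classify_expressed <- function(score, threshold = 100) {
  if (any(score < 0)) stop("scores must be non-negative")
  score >= threshold
}

#' Long-format view of an expression matrix
#'
#' @param x an `expression_matrix`.
#' @param ... unused.
#' @return tibble with `gene`, `sample`, `hours`, `replicate`, `value`.
#' @export
tidy.expression_matrix <- function(x, ...) {
  df <- tibble::as_tibble(x$counts, rownames = "gene")
  long <- tidyr::pivot_longer(df, -"gene", names_to = "sample",
                              values_to = "value")
  dplyr::left_join(long, x$sample_meta, by = "sample")
}
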