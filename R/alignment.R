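#' Protein alignments
#'
#' Alignments are represented as named character vectors of equal-length
#' residue strings (upper case). [as_alignment()] coerces from
#' `Biostrings::AAStringSet`, character matrices, or named character vectors
#' and validates lengths and names. Residues outside the 20 canonical amino
#' acids (gaps `-`/`.`, `X`, `B`, `Z`, ...) are kept and treated as fully
#' ambiguous by the likelihood engine.
#'
#' @param x object to coerce.
#' @return named character vector with class `aa_alignment`.
#' @export
as_alignment <- function(x) {
  if (inherits(x, "AAStringSet")) {
    x <- setNames(as.character(x), names(x))
  } else if (is.matrix(x) && is.character(x)) {
    x <- setNames(apply(x, 1, paste0, collapse = ""), rownames(x))
  }
  if (!is.character(x)) stop("cannot coerce to an alignment")
  if (is.null(names(x)) || any(!nzchar(names(x)))) stop("sequences must be named")
  if (anyDuplicated(names(x))) stop("duplicate sequence names")
  x <- toupper(x)
  if (length(unique(nchar(x))) != 1)
    stop("aligned sequences must all have the same length")
  class(x) <- c("aa_alignment", "character")
  x
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("<aa_alignment> ", length(x), " sequences x ", nchar(x[[1]]),
      " sites\n", sep = "")
  invisible(x)
}

n_sites <- function(aln) nchar(unclass(aln)[[1]])

#' Read / write alignments
#'
#' FASTA I/O goes through Biostrings; the PHYLIP reader accepts the relaxed
#' sequential format (name and sequence separated by whitespace, possibly
#' interleaved continuation lines are not supported).
#'
#' @param path file path.
#' @return an `aa_alignment`.
#' @export
read_fasta_alignment <- function(path) {
  as_alignment(Biostrings::readAAStringSet(path))
}

#' @rdname read_fasta_alignment
#' @param aln an `aa_alignment`.
#' @export
write_fasta_alignment <- function(aln, path) {
  aln <- as_alignment(aln)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(unclass(aln)), path)
  invisible(path)
}

#' @rdname read_fasta_alignment
#' @export
read_phylip_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || any(is.na(hdr)))
    stop("malformed PHYLIP header: ", lines[1])
  body <- lines[-1]
  if (length(body) != hdr[1]) stop("expected ", hdr[1], " sequence lines")
  parts <- strsplit(trimws(body), "\\s+")
  nm <- vapply(parts, `[`, "", 1)
  sq <- vapply(parts, function(p) paste0(p[-1], collapse = ""), "")
  if (any(nchar(sq) != hdr[2])) stop("sequence length disagrees with header")
  as_alignment(setNames(sq, nm))
}

#' @rdname read_fasta_alignment
#' @export
write_phylip_alignment <- function(aln, path) {
  aln <- as_alignment(aln)
  writeLines(c(paste(length(aln), n_sites(aln)),
               paste(names(aln), unclass(aln))), path)
  invisible(path)
}

# integer encoding: 0..19 canonical states, 20 = ambiguous/gap
aln_codes <- function(aln, tips) {
  aln <- as_alignment(aln)
  missing <- setdiff(tips, names(aln))
  if (length(missing))
    stop("leaves without sequences: ", paste(missing, collapse = ", "))
  m <- matrix(20L, nrow = n_sites(aln), ncol = length(tips))
  lookup <- setNames(seq_along(AA_STATES) - 1L, AA_STATES)
  for (j in seq_along(tips)) {
    ch <- strsplit(unclass(aln)[[tips[j]]], "")[[1]]
    code <- unname(lookup[ch])
    code[is.na(code)] <- 20L
    m[, j] <- code
  }
  m
}

# site-pattern compression: unique rows of the site x tip matrix
compress_patterns <- function(codes) {
  key <- apply(codes, 1, paste0, collapse = ",")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(patterns = codes[first, , drop = FALSE],
       weights = as.numeric(tabulate(idx, sum(first))),
       index = idx)
}
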