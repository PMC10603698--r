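#' @importFrom Biostrings getGeneticCode DNAStringSet reverseComplement DNAString
NULL

# package-level cache for codon machinery (built once per session)
.mitosel_env <- new.env(parent = emptyenv())

#' Vertebrate mitochondrial genetic code
#'
#' Returns the vertebrate mitochondrial genetic code (NCBI translation
#' table 2) as a named character vector mapping each of the 64 DNA codons
#' to a one-letter amino acid, with `*` for the four stops
#' (TAA, TAG, AGA, AGG).
#'
#' @return Named character vector of length 64.
#' @export
mito_genetic_code <- function() {
  if (is.null(.mitosel_env$code)) {
    .mitosel_env$code <- Biostrings::getGeneticCode("2")
  }
  .mitosel_env$code
}

#' Sense codons of the vertebrate mitochondrial code
#'
#' The 60 sense codons of translation table 2, in fixed lexicographic
#' (A < C < G < T) order. This ordering defines the state space used by
#' all codon-model computations in the package.
#'
#' @return Character vector of length 60.
#' @export
mito_codons <- function() {
  if (is.null(.mitosel_env$codons)) {
    nt <- c("A", "C", "G", "T")
    all64 <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
    all64 <- sort(all64)
    code <- mito_genetic_code()
    .mitosel_env$codons <- all64[code[all64] != "*"]
  }
  .mitosel_env$codons
}

#' Stop codons of the vertebrate mitochondrial code
#' @return Character vector (TAA, TAG, AGA, AGG).
#' @export
mito_stop_codons <- function() {
  code <- mito_genetic_code()
  names(code)[code == "*"]
}

# Translate a vector of codons under table 2; "*" for stops, NA otherwise.
translate_codons <- function(codons) {
  unname(mito_genetic_code()[codons])
}

# Pairwise classification of the 60x60 sense-codon pairs:
#   0 = identical or >1 nucleotide difference (instantaneous rate 0)
#   1 = synonymous transversion
#   2 = synonymous transition
#   3 = nonsynonymous transversion
#   4 = nonsynonymous transition
codon_pair_classes <- function() {
  if (!is.null(.mitosel_env$pair_classes)) return(.mitosel_env$pair_classes)
  codons <- mito_codons()
  n <- length(codons)
  mat <- do.call(rbind, strsplit(codons, ""))
  aa <- translate_codons(codons)
  is_ts <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  cls <- matrix(0L, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    ndiff <- vapply(seq_len(n), function(j) sum(mat[i, ] != mat[j, ]), 0L)
    one <- which(ndiff == 1L)
    for (j in one) {
      pos <- which(mat[i, ] != mat[j, ])
      ts <- is_ts(mat[i, pos], mat[j, pos])
      syn <- aa[i] == aa[j]
      cls[i, j] <- if (syn && !ts) 1L else if (syn && ts) 2L
        else if (!syn && !ts) 3L else 4L
    }
  }
  .mitosel_env$pair_classes <- cls
  cls
}

# Map codon strings to 1..60 state indices; NA for anything not a sense codon.
codon_index <- function(codons) {
  match(codons, mito_codons())
}

# Split a nucleotide string into codon triplets (truncating a 3' remainder).
split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Count codon usage in coding sequences
#'
#' Tallies codon occurrences over one or more in-frame coding sequences.
#' Codons containing characters outside A/C/G/T are skipped; stop codons
#' are counted separately and excluded from the sense-codon tally.
#'
#' @param cds Character vector of nucleotide strings (each in frame).
#' @return Named integer vector over the 60 sense codons, with the number
#'   of skipped (ambiguous) and stop codons in attributes `"ambiguous"`
#'   and `"stops"`.
#' @export
count_codons <- function(cds) {
  codons <- unlist(lapply(cds, split_codons), use.names = FALSE)
  clean <- grepl("^[ACGT]{3}$", codons)
  stops <- sum(codons[clean] %in% mito_stop_codons())
  sense <- codons[clean & !(codons %in% mito_stop_codons())]
  counts <- table(factor(sense, levels = mito_codons()))
  out <- as.integer(counts)
  names(out) <- mito_codons()
  attr(out, "ambiguous") <- sum(!clean)
  attr(out, "stops") <- stops
  out
}

# Reverse-complement of a plain character DNA string.
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
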