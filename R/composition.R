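#' Nucleotide composition and strand skew of a sequence
#'
#' Counts A/C/G/T (ambiguity codes are excluded from counts and reported
#' separately), computes AT% and GC%, and the heavy-strand compositional
#' skews AT skew = (A − T)/(A + T) and GC skew = (G − C)/(G + C). Full
#' precision is kept internally; the print method rounds percentages to
#' 1 decimal and skews to 3, the conventions of published composition
#' tables.
#'
#' @param seq A nucleotide sequence as a single character string (or a
#'   `Biostrings::DNAString`).
#' @param label Region label for reporting.
#' @return Object of class `composition_summary`: a list with `label`,
#'   `length`, `counts` (named A/C/G/T), `ambiguous`, `at_pct`, `gc_pct`,
#'   `at_skew`, `gc_skew`.
#' @export
composition <- function(seq, label = "region") {
  seq <- toupper(as.character(seq))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  counts <- c(A = sum(chars == "A"), C = sum(chars == "C"),
              G = sum(chars == "G"), T = sum(chars == "T"))
  ambiguous <- length(chars) - sum(counts)
  total <- sum(counts)
  if (total == 0L) stop("sequence contains no unambiguous bases")
  sk <- skews(counts[["A"]], counts[["T"]], counts[["G"]], counts[["C"]])
  structure(list(
    label = label, length = length(chars), counts = counts,
    ambiguous = ambiguous,
    at_pct = 100 * (counts[["A"]] + counts[["T"]]) / total,
    gc_pct = 100 * (counts[["G"]] + counts[["C"]]) / total,
    at_skew = sk$at_skew, gc_skew = sk$gc_skew
  ), class = "composition_summary")
}

# shared skew arithmetic; zero denominators give NA with a warning
skews <- function(a, t, g, c) {
  at <- a + t
  gc <- g + c
  at_skew <- if (at > 0) (a - t) / at else {
    warning("A+T is zero; AT skew undefined"); NA_real_
  }
  gc_skew <- if (gc > 0) (g - c) / gc else {
    warning("G+C is zero; GC skew undefined"); NA_real_
  }
  list(at_skew = at_skew, gc_skew = gc_skew)
}

#' Skews from printed percentage compositions
#'
#' Applies the AT/GC skew formulas directly to percentage compositions,
#' allowing published composition tables to be verified without the
#' underlying sequences.
#'
#' @param pct_a,pct_t,pct_g,pct_c Base percentages (non-negative).
#' @return List with `at_skew` and `gc_skew`.
#' @export
skew_from_percentages <- function(pct_a, pct_t, pct_g, pct_c) {
  if (any(c(pct_a, pct_t, pct_g, pct_c) < 0))
    stop("percentages must be non-negative")
  skews(pct_a, pct_t, pct_g, pct_c)
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("%s: %d bp (A %d, C %d, G %d, T %d, other %d)\n",
              x$label, x$length, x$counts[["A"]], x$counts[["C"]],
              x$counts[["G"]], x$counts[["T"]], x$ambiguous))
  cat(sprintf("  AT%% %.1f  GC%% %.1f  AT skew %.3f  GC skew %.3f\n",
              x$at_pct, x$gc_pct, x$at_skew, x$gc_skew))
  invisible(x)
}

# Synonymous-family labels under the vertebrate mitochondrial code, with
# leucine and serine split by codon box (Leu1 = CTN, Leu2 = TTR;
# Ser1 = TCN, Ser2 = AGY), the convention of RSCU bar charts.
rscu_families <- function() {
  codons <- mito_codons()
  aa <- translate_codons(codons)
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
           Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
           L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
           S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")
  fam <- aa3[aa]
  fam[aa == "L"] <- ifelse(substr(codons[aa == "L"], 1, 1) == "C",
                           "Leu1", "Leu2")
  fam[aa == "S"] <- ifelse(substr(codons[aa == "S"], 1, 1) == "T",
                           "Ser1", "Ser2")
  stats::setNames(fam, codons)
}

#' Relative synonymous codon usage
#'
#' RSCU of each sense codon: its observed count divided by the mean
#' count of its synonymous family, i.e. `count * family_size /
#' family_total`. A value of 1 means no preference within the family.
#' Families follow the vertebrate mitochondrial code with Leu and Ser
#' split by codon box (Leu1/Leu2, Ser1/Ser2). Families with zero total
#' count get RSCU 0 and are flagged.
#'
#' @param counts Named integer vector of codon counts over (a subset of)
#'   the 60 sense codons, e.g. from [count_codons()].
#' @return data.frame of class `rscu_table` with columns `codon`,
#'   `family`, `count`, `rscu`, `undefined`.
#' @export
rscu <- function(counts) {
  bad <- intersect(names(counts), mito_stop_codons())
  if (length(bad))
    stop("stop codon(s) in counts: ", paste(bad, collapse = ", "))
  unknown <- setdiff(names(counts), mito_codons())
  if (length(unknown))
    stop("not sense codons of the vertebrate mitochondrial code: ",
         paste(unknown, collapse = ", "))
  full <- stats::setNames(rep(0L, 60L), mito_codons())
  full[names(counts)] <- as.integer(counts)
  fam <- rscu_families()
  fam_total <- tapply(full, fam, sum)
  fam_size <- tapply(full, fam, length)
  tot <- fam_total[fam]
  sz <- fam_size[fam]
  val <- ifelse(tot > 0, full * sz / tot, 0)
  out <- data.frame(codon = names(full), family = unname(fam),
                    count = unname(full), rscu = unname(val),
                    undefined = unname(tot == 0),
                    stringsAsFactors = FALSE)
  class(out) <- c("rscu_table", "data.frame")
  out
}
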