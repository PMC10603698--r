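#' Codon alignment objects
#'
#' A `codon_alignment` stores a taxa-by-site matrix of codon states over
#' the 60 sense codons of the vertebrate mitochondrial code (integer
#' indices into [mito_codons()]). Alignments are gap-free by
#' construction: columns containing gaps or ambiguity codes are removed
#' when reading (complete deletion).
#'
#' @param states Integer matrix (taxa x codon sites) of indices into
#'   [mito_codons()], with taxon rownames; or a character matrix of
#'   codon strings.
#' @param gene_label Gene name for reporting/partitions.
#' @param partition_map Optional data.frame (`gene`, `start`, `end`) in
#'   codon columns, used for concatenated alignments.
#' @return Object of class `codon_alignment`.
#' @export
codon_alignment <- function(states, gene_label = "gene",
                            partition_map = NULL) {
  if (is.character(states)) {
    idx <- codon_index(states)
    bad <- which(is.na(idx) & !is.na(states))
    if (length(bad)) {
      pos <- arrayInd(bad[1L], dim(states))
      stop("invalid codon '", states[bad[1L]], "' for taxon ",
           rownames(states)[pos[1L]], " at codon site ", pos[2L])
    }
    states <- matrix(idx, nrow = nrow(states),
                     dimnames = dimnames(states))
  }
  storage.mode(states) <- "integer"
  if (is.null(rownames(states))) stop("taxon names required as rownames")
  if (anyDuplicated(rownames(states))) stop("duplicate taxon labels")
  if (is.null(partition_map))
    partition_map <- data.frame(gene = gene_label, start = 1L,
                                end = ncol(states),
                                stringsAsFactors = FALSE)
  structure(list(states = states, taxa = rownames(states),
                 gene_label = gene_label, partition_map = partition_map),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment '%s': %d taxa x %d codon sites",
              x$gene_label, nrow(x$states), ncol(x$states)))
  if (nrow(x$partition_map) > 1L)
    cat(sprintf(" (%d partitions)", nrow(x$partition_map)))
  cat("\n")
  invisible(x)
}

#' @export
dim.codon_alignment <- function(x) dim(x$states)

# normalize taxon labels to a shared key across FASTA, tree, habitat files
normalize_taxa <- function(x) gsub("[ ]+", "_", trimws(x))

#' Read a codon-aligned FASTA file
#'
#' Reads an aligned, in-frame nucleotide FASTA into a codon alignment
#' under the vertebrate mitochondrial code. Preparation steps: a final
#' codon column containing a stop or a partial (gap-containing) codon in
#' any row is removed, then every column containing a gap or ambiguity
#' code in any row is removed (complete deletion); the number of dropped
#' columns is reported. Any in-frame stop remaining after preparation is
#' an error naming the taxon and site.
#'
#' @param path FASTA file of aligned sequences, equal lengths divisible
#'   by 3.
#' @param gene_label Gene name; defaults to the file name.
#' @return A [codon_alignment()] with attribute `dropped_columns`.
#' @export
read_codon_fasta <- function(path, gene_label = sub("\\.[^.]*$", "", basename(path))) {
  dna <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(dna))
  names(seqs) <- normalize_taxa(names(seqs))
  prepare_codon_matrix(seqs, gene_label = gene_label)
}

# shared preparation from named nucleotide strings
prepare_codon_matrix <- function(seqs, gene_label = "gene") {
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("aligned sequences have unequal lengths")
  if (widths[1L] %% 3L != 0L)
    stop("alignment length ", widths[1L], " is not divisible by 3")
  cod <- t(vapply(seqs, split_codons, character(widths[1L] %/% 3L)))
  if (widths[1L] %/% 3L == 1L) {
    cod <- matrix(cod, ncol = 1L, dimnames = list(names(seqs), NULL))
  }
  dropped <- 0L
  # strip trailing columns holding terminal stops or 3'-partial codons
  repeat {
    nc <- ncol(cod)
    if (nc == 0L) break
    last <- cod[, nc]
    if (any(last %in% mito_stop_codons()) ||
        any(grepl("-", last, fixed = TRUE))) {
      cod <- cod[, -nc, drop = FALSE]
      dropped <- dropped + 1L
    } else break
  }
  # complete deletion of columns with any gap/ambiguity
  clean <- apply(cod, 2L, function(col) all(grepl("^[ACGT]{3}$", col)))
  dropped <- dropped + sum(!clean)
  cod <- cod[, clean, drop = FALSE]
  if (dropped > 0L)
    message(gene_label, ": dropped ", dropped,
            " codon column(s) (gaps/ambiguities/terminal stops)")
  # no in-frame stops may remain
  stops <- which(matrix(cod %in% mito_stop_codons(), nrow = nrow(cod)),
                 arr.ind = TRUE)
  if (nrow(stops)) {
    stop("in-frame stop codon for taxon ", rownames(cod)[stops[1L, 1L]],
         " at codon site ", stops[1L, 2L], " in ", gene_label)
  }
  aln <- codon_alignment(cod, gene_label = gene_label)
  attr(aln, "dropped_columns") <- dropped
  aln
}

#' Concatenate codon alignments
#'
#' Column-wise concatenation of per-gene codon alignments over an
#' identical taxon set, recording gene boundaries in the partition map.
#' Taxon order is canonicalized alphabetically.
#'
#' @param alignments List of [codon_alignment()] objects (names override
#'   the per-alignment gene labels if given).
#' @param label Label for the concatenated alignment (default "13PCG"
#'   when 13 genes are supplied, else "concat").
#' @return A [codon_alignment()] with a multi-gene partition map.
#' @export
concatenate <- function(alignments,
                        label = if (length(alignments) == 13L) "13PCG" else "concat") {
  stopifnot(length(alignments) >= 1L)
  if (is.null(names(alignments)))
    names(alignments) <- vapply(alignments, function(a) a$gene_label, "")
  taxa <- sort(alignments[[1L]]$taxa)
  for (a in alignments) {
    if (!setequal(a$taxa, taxa)) {
      diffs <- c(setdiff(a$taxa, taxa), setdiff(taxa, a$taxa))
      stop("taxon sets differ (", a$gene_label, "): ",
           paste(diffs, collapse = ", "))
    }
  }
  mats <- lapply(alignments, function(a) a$states[taxa, , drop = FALSE])
  states <- do.call(cbind, mats)
  lens <- vapply(mats, ncol, 0L)
  ends <- cumsum(lens)
  pm <- data.frame(gene = names(alignments),
                   start = c(1L, utils::head(ends, -1L) + 1L),
                   end = ends, stringsAsFactors = FALSE)
  codon_alignment(states, gene_label = label, partition_map = pm)
}

#' Extract one gene partition from a concatenated alignment
#'
#' @param aln A concatenated [codon_alignment()].
#' @param gene Gene name present in the partition map.
#' @return The single-gene [codon_alignment()].
#' @export
extract_partition <- function(aln, gene) {
  pm <- aln$partition_map
  k <- match(gene, pm$gene)
  if (is.na(k)) stop("no partition named ", gene)
  codon_alignment(aln$states[, pm$start[k]:pm$end[k], drop = FALSE],
                  gene_label = gene)
}

#' Extract a coding sequence from a genome
#'
#' Slices a gene's span (1-based inclusive heavy-strand coordinates,
#' wrapping across the origin when `start > end` on a circular genome)
#' and reverse-complements it for light-strand genes. A 3' partial codon
#' (the template of an incomplete stop completed by polyadenylation) is
#' trimmed, not padded.
#'
#' @param genome Genome sequence as a character string.
#' @param start,end 1-based inclusive coordinates on the heavy strand.
#' @param strand `"+"` (heavy) or `"-"` (light).
#' @param trim_partial Trim a 3' partial codon so the result length is a
#'   multiple of 3? Default `TRUE`.
#' @return Character string with the coding-strand sequence.
#' @export
extract_cds <- function(genome, start, end, strand = "+",
                        trim_partial = TRUE) {
  genome <- toupper(as.character(genome))
  n <- nchar(genome)
  if (start < 1L || end < 1L || start > n || end > n)
    stop("coordinates outside genome (length ", n, ")")
  s <- if (start <= end) substr(genome, start, end)
       else paste0(substr(genome, start, n), substr(genome, 1L, end))
  if (strand == "-") s <- revcomp(s)
  if (trim_partial) {
    keep <- (nchar(s) %/% 3L) * 3L
    s <- substr(s, 1L, keep)
  }
  s
}

#' Write a codon alignment as sequential PHYLIP
#'
#' Plain sequential PHYLIP (nucleotide space) for interoperability
#' checks with other codon-model software.
#'
#' @param aln A [codon_alignment()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_phylip <- function(aln, path) {
  codons <- mito_codons()
  seqs <- apply(aln$states, 1L, function(r) paste(codons[r], collapse = ""))
  lines <- c(sprintf(" %d %d", nrow(aln$states), 3L * ncol(aln$states)),
             sprintf("%-12s%s", substr(names(seqs), 1L, 10L), seqs))
  writeLines(lines, path)
  invisible(path)
}

# character codon matrix of an alignment (used by composition/RSCU glue)
codon_strings <- function(aln) {
  m <- matrix(mito_codons()[aln$states], nrow = nrow(aln$states),
              dimnames = dimnames(aln$states))
  m
}
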