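test_that("annotation parsing validates structure and names offending rows", {
  genes <- data.frame(gene = "g1", start = 1L, end = 100L, strand = "+",
                      category = "tRNA", start_codon = NA, stop_codon = NA)
  expect_s3_class(mito_annotation(genes, 200L), "mito_annotation")
  expect_error(mito_annotation(genes[0, ], 200L), "empty gene list")
  bad <- genes; bad$strand <- "x"
  expect_error(mito_annotation(bad, 200L), "strand symbol in row\\(s\\): 1")
  bad <- genes; bad$start <- -5L
  expect_error(mito_annotation(bad, 200L), "malformed coordinates")
  two_ctrl <- rbind(genes, genes)
  two_ctrl$category <- "control"
  two_ctrl$end <- c(50L, 100L); two_ctrl$start <- c(10L, 60L)
  expect_error(mito_annotation(two_ctrl, 200L), "duplicate control region")
  pcg_nostart <- genes; pcg_nostart$category <- "PCG"
  expect_error(mito_annotation(pcg_nostart, 200L), "without start codon")
})

test_that("origin-spanning genes are accepted on circular genomes", {
  genes <- data.frame(
    gene = c("g1", "dloop"), start = c(10L, 180L), end = c(150L, 9L),
    strand = "+", category = c("tRNA", "control"),
    start_codon = NA_character_, stop_codon = NA_character_,
    stringsAsFactors = FALSE)
  ann <- mito_annotation(genes, 200L)
  expect_equal(gene_length(180L, 9L, 200L), 200L - 180L + 1L + 9L)
  expect_equal(gene_length(5L, 5L), 1L)
})

test_that("spacer and overlap arithmetic matches hand enumeration", {
  # abutting genes -> spacer 0
  lay <- data.frame(gene = c("a", "b", "c"), length = c(100L, 50L, 30L),
                    spacer = c(NA, 0L, -5L), strand = "+",
                    category = "tRNA", start_codon = NA, stop_codon = NA)
  toy <- make_toy_annotation(lay, control_length = 40L)
  sp <- intergenic_spacers(toy$annotation)
  expect_equal(unname(sp), c(0L, -5L))
  ov <- overlap_summary(toy$annotation)
  expect_equal(ov$total_bp, 5L)
  expect_equal(ov$longest_pair, "b|c")
  # equal overlaps: tie broken by genome order
  lay2 <- data.frame(gene = c("a", "b", "c"), length = c(100L, 60L, 60L),
                     spacer = c(NA, -5L, -5L), strand = "+",
                     category = "tRNA", start_codon = NA, stop_codon = NA)
  ov2 <- overlap_summary(make_toy_annotation(lay2)$annotation)
  expect_equal(ov2$total_bp, 10L)
  expect_equal(ov2$longest_pair, "a|b")
  # no overlaps
  lay3 <- data.frame(gene = c("a", "b"), length = c(50L, 50L),
                     spacer = c(NA, 3L), strand = "+", category = "tRNA",
                     start_codon = NA, stop_codon = NA)
  ov3 <- overlap_summary(make_toy_annotation(lay3)$annotation)
  expect_equal(ov3$total_bp, 0L)
  expect_true(is.na(ov3$longest_pair))
})

test_that("toy layouts reproduce their analytic expectations (cross-module)", {
  for (seed in 1:20) {
    set.seed(seed)
    lay <- fix_layout_codons(random_layout(8L))
    toy <- tryCatch(make_toy_annotation(lay), error = function(e) NULL)
    if (is.null(toy)) next  # inconsistent random layout rejected
    ann <- toy$annotation
    ex <- toy$expected
    expect_equal(unname(intergenic_spacers(ann)), ex$spacers)
    ov <- overlap_summary(ann)
    expect_equal(ov$total_bp, ex$total_overlap)
    expect_equal(ov$longest_bp, ex$longest_overlap)
    strp <- strand_partition(ann)
    expect_equal(strp$heavy, ex$heavy)
    expect_equal(strp$light, ex$light)
    # circular consistency: lengths + signed spacers + control = genome
    g <- ann$genes[ann$genes$category != "control", ]
    lens <- gene_length(g$start, g$end, ann$genome_length)
    expect_equal(sum(lens) + sum(ex$spacers) + ex$control_length,
                 ann$genome_length)
  }
})

test_that("overlap summary agrees with the spacer code path", {
  set.seed(99)
  for (i in 1:10) {
    lay <- fix_layout_codons(random_layout(10L))
    toy <- tryCatch(make_toy_annotation(lay), error = function(e) NULL)
    if (is.null(toy)) next
    sp <- intergenic_spacers(toy$annotation)
    expect_equal(overlap_summary(toy$annotation)$total_bp,
                 sum(-sp[sp < 0]))
  }
})

test_that("codon tallies count PCGs only and flag missing codons", {
  lay <- data.frame(
    gene = c("p1", "t1", "p2"), length = c(90L, 70L, 120L),
    spacer = c(NA, 2L, 2L), strand = c("+", "-", "+"),
    category = c("PCG", "tRNA", "PCG"),
    start_codon = c("ATG", NA, "ATA"), stop_codon = c("TAA", NA, "TA-"),
    stringsAsFactors = FALSE)
  tal <- codon_tallies(make_toy_annotation(lay)$annotation)
  expect_equal(as.integer(tal$start[c("ATG", "ATA")]), c(1L, 1L))
  expect_equal(as.integer(tal$stop[c("TAA", "TA-")]), c(1L, 1L))
  lay$stop_codon[1] <- NA
  expect_error(codon_tallies(make_toy_annotation(lay)$annotation), "p1")
  # zero PCGs -> empty tallies
  lay2 <- lay[2, ]; lay2$spacer <- NA
  tal2 <- codon_tallies(make_toy_annotation(lay2)$annotation)
  expect_length(tal2$start, 0L)
  expect_length(tal2$stop, 0L)
})

test_that("strand partition equals a direct tally on random strands", {
  set.seed(4)
  for (i in 1:5) {
    lay <- fix_layout_codons(random_layout(12L))
    toy <- tryCatch(make_toy_annotation(lay), error = function(e) NULL)
    if (is.null(toy)) next
    strp <- strand_partition(toy$annotation)
    expect_equal(strp$heavy, sum(lay$strand == "+"))
    expect_equal(strp$light, sum(lay$strand == "-"))
    expect_setequal(strp$light_genes, lay$gene[lay$strand == "-"])
  }
})

test_that("gene order comparison reports the first difference", {
  lay <- data.frame(gene = paste0("g", 1:5),
                    length = rep(80L, 5), spacer = c(NA, rep(2L, 4)),
                    strand = "+", category = "tRNA",
                    start_codon = NA, stop_codon = NA)
  a <- make_toy_annotation(lay)$annotation
  expect_true(compare_gene_orders(a, a)$identical)
  lay2 <- lay[c(1, 2, 4, 3, 5), ]
  lay2$spacer <- c(NA, rep(2L, 4))
  b <- make_toy_annotation(lay2)$annotation
  cmp <- compare_gene_orders(a, b)
  expect_false(cmp$identical)
  expect_equal(cmp$first_difference, 3L)
  lay3 <- lay; lay3$gene[5] <- "other"
  d <- make_toy_annotation(lay3)$annotation
  expect_error(compare_gene_orders(a, d), "unmatched")
})

test_that("control region is inferred as the largest unannotated gap", {
  tmp <- tempfile(fileext = ".tsv")
  genes <- data.frame(gene = c("a", "b"), start = c(1L, 210L),
                      end = c(200L, 400L), strand = "+",
                      category = "tRNA", start_codon = NA,
                      stop_codon = NA)
  utils::write.table(genes, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_message(ann <- read_annotation_table(tmp, genome_length = 1000L),
                 "control region inferred")
  ctrl <- ann$genes[ann$genes$category == "control", ]
  expect_equal(ctrl$start, 401L)
  expect_equal(ctrl$end, 1000L)
})
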