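make_fake_fit <- function(tree, omega_edge, model = "free_ratio") {
  structure(list(model_class = model, tree = tree,
                 kappa = 2, omega = omega_edge,
                 lnL = 0, pi = uniform_codon_frequencies(),
                 foreground_edges = NULL,
                 branch_lengths_estimated = FALSE,
                 gene_label = "toy", nsites = 1L, npatterns = 1L,
                 convergence = list(iterations = 0L,
                                    gradient_norm = 0, code = 0L)),
            class = "branch_fit")
}

test_that("two-ratio fits never fall below the nested one-ratio fit", {
  cfg <- simulation_config(tree6(), omega = 0.3, kappa = 4,
                           codons = 150, seed = 41)
  aln <- simulate_codon_alignment(cfg)
  f0 <- fit_branch_model(aln, tree6(), "one_ratio",
                         frequencies = "uniform")
  f1 <- fit_branch_model(aln, tree6(), "two_ratio",
                         foreground = c("A", "B"), null_fit = f0,
                         frequencies = "uniform")
  expect_gte(f1$lnL, f0$lnL - 1e-4)
  # under one-ratio truth the two omegas stay close and the LRT small
  r <- lrt(f0, f1)
  expect_equal(r$df, 1L)
  expect_lt(r$statistic, 10)
  expect_gte(r$p, 0)
  # free-ratio nests them both
  fr <- fit_branch_model(aln, tree6(), "free_ratio", null_fit = f0,
                         frequencies = "uniform")
  expect_gte(fr$lnL, f0$lnL - 1e-4)
  expect_length(fr$omega, nrow(tree6()$edge))
})

test_that("one-ratio fit recovers simulation truth on a single dataset", {
  cfg <- simulation_config(tree6(), omega = 0.2, kappa = 4,
                           codons = 1000, seed = 77)
  aln <- simulate_codon_alignment(cfg)
  f <- fit_branch_model(aln, tree6(), "one_ratio",
                        frequencies = "uniform")
  expect_gt(f$omega[[1]], 0.15)
  expect_lt(f$omega[[1]], 0.25)
  expect_gt(f$kappa, 3)
  expect_lt(f$kappa, 5)
  # co-estimated branch lengths stay in a sane range around 0.2
  expect_true(all(f$tree$edge.length > 0.05 & f$tree$edge.length < 0.6))
  ll <- logLik(f)
  expect_equal(attr(ll, "df"), 2L + nrow(tree6()$edge))
})

test_that("likelihood-ratio machinery clamps and validates", {
  expect_equal(lrt(-100, -100, df = 1)$p, 1)
  r <- lrt(-105, -100, df = 1)
  expect_equal(r$statistic, 10)
  expect_equal(r$p, stats::pchisq(10, 1, lower.tail = FALSE))
  # marginal negative statistic clamps to zero
  expect_equal(lrt(-99.99995, -100, df = 1)$statistic, 0)
  # substantial violation errors
  expect_error(lrt(-90, -100, df = 1), "nesting violated")
  expect_error(lrt(-100, -99, df = 0), "positive")
  expect_error(lrt(-100, -99), "df required")
  # monotone decreasing p in the statistic
  p <- vapply(c(0, 1, 3.84, 10), function(s) lrt(0, s / 2, df = 1)$p, 0)
  expect_true(all(diff(p) < 0))
})

test_that("root-to-tip omega averages branch estimates along paths", {
  # 5-taxon caterpillar with hand-assigned branch omegas
  tr <- ape::read.tree(
    text = "(A:1,(B:1,(C:1,(D:1,E:1):1):1):1);")
  nedge <- nrow(tr$edge)
  om <- numeric(nedge)
  # name edges by child node for hand bookkeeping
  tip <- function(lbl) which(tr$tip.label == lbl)
  edge_to <- function(node) which(tr$edge[, 2] == node)
  ntip <- 5L
  # internal nodes on the path to E: root=6 -> 7 -> 8 -> 9 -> E
  om[edge_to(tip("A"))] <- 0.1
  om[edge_to(tip("B"))] <- 0.3
  om[edge_to(tip("C"))] <- 0.5
  om[edge_to(tip("D"))] <- 0.7
  om[edge_to(tip("E"))] <- 0.9
  om[edge_to(7L)] <- 0.2
  om[edge_to(8L)] <- 0.4
  om[edge_to(9L)] <- 0.6
  fit <- make_fake_fit(tr, om)
  rtt <- root_to_tip_omega(fit)
  expect_equal(rtt[["A"]], 0.1)
  expect_equal(rtt[["B"]], mean(c(0.2, 0.3)))
  expect_equal(rtt[["C"]], mean(c(0.2, 0.4, 0.5)))
  expect_equal(rtt[["D"]], mean(c(0.2, 0.4, 0.6, 0.7)))
  expect_equal(rtt[["E"]], mean(c(0.2, 0.4, 0.6, 0.9)))
  # values bounded by the path extremes
  expect_true(all(rtt >= 0.1 & rtt <= 0.9))
  # branch-length weighting with equal lengths changes nothing
  expect_equal(root_to_tip_omega(fit, weighted = TRUE), rtt)
})

test_that("on a star tree each tip reports its own branch omega", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  om <- c(0.1, 0.2, 0.3, 0.4)
  fit <- make_fake_fit(tr, om)
  rtt <- root_to_tip_omega(fit)
  expect_length(rtt, 4L)
  # each path is a single branch, so the tip reports its own omega
  for (i in 1:4) {
    e <- which(tr$edge[, 2L] == i)
    expect_equal(rtt[[tr$tip.label[i]]], om[e])
  }
})

test_that("the selection screen reports one row per dataset", {
  set.seed(6)
  genes <- paste0("g", 1:3)
  cfg <- simulation_config(tree6(), omega = 0.2, kappa = 4,
                           codons = 60, genes = genes, seed = 19)
  alns <- simulate_gene_set(cfg)
  scr <- rapid_evolution_screen(alns, tree6(), foreground = c("A", "B"),
                                frequencies = "uniform")
  expect_s3_class(scr, "selection_screen")
  expect_equal(nrow(scr), 4L)  # 3 genes + concatenation
  expect_equal(scr$gene, c(genes, "concat"))
  expect_true(all(scr$two_dlnl >= 0))
  expect_true(all(scr$p >= 0 & scr$p <= 1))
  # direction rule: rapid requires foreground > background
  flagged <- scr[which(scr$rapid), ]
  if (nrow(flagged))
    expect_true(all(flagged$omega_foreground > flagged$omega_background))
})
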