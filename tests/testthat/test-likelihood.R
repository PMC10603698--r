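test_that("degenerate trees reduce to stationary-frequency likelihoods", {
  pi <- uniform_codon_frequencies()
  # single tip, one codon, zero-length branch: lnL = log pi_c
  tr1 <- ape::read.tree(text = "(A:0);")
  m <- matrix(7L, 1, 1, dimnames = list("A", NULL))
  spec <- codon_model_spec("one_ratio", kappa = 2, omega = 0.5, pi = pi)
  expect_equal(pruning_loglik(tr1, codon_alignment(m), spec), log(pi[[7]]))
  # two identical sequences at zero distance: lnL = sum log pi
  tr2 <- ape::read.tree(text = "(A:0,B:0);")
  m2 <- matrix(c(1L, 12L, 55L, 1L, 12L, 55L), nrow = 2, byrow = TRUE,
               dimnames = list(c("A", "B"), NULL))
  expect_equal(pruning_loglik(tr2, codon_alignment(m2), spec),
               sum(log(pi[c(1, 12, 55)])))
})

test_that("pruning equals exhaustive enumeration on a 4-taxon instance", {
  pi <- uniform_codon_frequencies()
  cfg <- simulation_config(tree4(), omega = 0.4, kappa = 3,
                           codons = 20, seed = 11)
  aln <- simulate_codon_alignment(cfg)
  spec <- codon_model_spec("one_ratio", kappa = 3, omega = 0.4, pi = pi)
  expect_equal(pruning_loglik(tree4(), aln, spec),
               brute_loglik4(aln, 3, 0.4, pi), tolerance = 1e-8)
  # a second parameter set, non-uniform frequencies
  set.seed(2)
  x <- stats::rgamma(60, 2)
  pi2 <- stats::setNames(x / sum(x), mito_codons())
  spec2 <- codon_model_spec("one_ratio", kappa = 1.4, omega = 1.2,
                            pi = pi2)
  expect_equal(pruning_loglik(tree4(), aln, spec2),
               brute_loglik4(aln, 1.4, 1.2, pi2), tolerance = 1e-8)
})

test_that("likelihood is invariant under re-rooting (reversibility)", {
  pi <- uniform_codon_frequencies()
  cfg <- simulation_config(tree6(), omega = 0.3, kappa = 4,
                           codons = 40, seed = 5)
  aln <- simulate_codon_alignment(cfg)
  spec <- codon_model_spec("one_ratio", kappa = 4, omega = 0.3, pi = pi)
  base <- pruning_loglik(tree6(), aln, spec)
  unrooted <- ape::unroot(tree6())
  for (tip in c("A", "D", "F")) {
    rerooted <- ape::root(unrooted, outgroup = tip, resolve.root = TRUE)
    expect_equal(pruning_loglik(rerooted, aln, spec), base,
                 tolerance = 1e-8)
  }
})

test_that("site-pattern compression preserves weights and totals", {
  cfg <- simulation_config(tree4(), omega = 0.2, kappa = 4,
                           codons = 200, seed = 9)
  aln <- simulate_codon_alignment(cfg)
  pat <- mitosel:::compress_patterns(tree4(), aln)
  expect_equal(sum(pat$weights), 200L)
  expect_true(ncol(pat$states) <= 200L)
  # likelihood identical with and without precompressed patterns
  pi <- uniform_codon_frequencies()
  expect_equal(
    mitosel:::codon_loglik(tree4(), aln, 4, 0.2, pi),
    mitosel:::codon_loglik(tree4(), aln, 4, 0.2, pi, patterns = pat))
})

test_that("edge profiles reproduce the full pruning likelihood", {
  pi <- uniform_codon_frequencies()
  tr <- tree6()
  cfg <- simulation_config(tr, omega = 0.25, kappa = 3, codons = 60,
                           seed = 13)
  aln <- simulate_codon_alignment(cfg)
  plan <- mitosel:::pruning_plan(tr)
  pat <- mitosel:::compress_patterns(tr, aln)
  om_edge <- rep(0.25, nrow(tr$edge))
  pmats <- mitosel:::edge_p_matrices(tr, 3, om_edge, pi)
  full <- mitosel:::codon_loglik(tr, aln, 3, om_edge, pi,
                                 patterns = pat, plan = plan)
  for (k in seq_len(nrow(tr$edge))) {
    prof <- mitosel:::edge_profile(tr, plan, pmats, pat, pi, k)
    expect_equal(prof(pmats[[k]]), full, tolerance = 1e-9)
  }
})

test_that("branch classes route omegas to the right edges", {
  tr <- tree6()
  fg <- mark_foreground(tr, c("A", "B"), include_stem = TRUE)
  # clade A,B has 2 terminal edges + 1 stem
  expect_equal(sum(fg), 3L)
  expect_error(mark_foreground(tr, c("A", "Z")), "not in tree")
  fg_nostem <- mark_foreground(tr, c("A", "B"), include_stem = FALSE)
  expect_equal(sum(fg_nostem), 2L)
  pi <- uniform_codon_frequencies()
  cfg <- simulation_config(tr, omega = 0.2, kappa = 4, codons = 30,
                           seed = 3)
  aln <- simulate_codon_alignment(cfg)
  # two-ratio spec with equal omegas collapses to one-ratio
  s1 <- codon_model_spec("one_ratio", kappa = 4, omega = 0.2, pi = pi)
  s2 <- codon_model_spec("two_ratio", kappa = 4,
                         omega = c(background = 0.2, foreground = 0.2),
                         pi = pi, foreground_edges = fg)
  expect_equal(pruning_loglik(tr, aln, s2), pruning_loglik(tr, aln, s1))
})

test_that("taxon mismatches and invalid specs are rejected", {
  cfg <- simulation_config(tree4(), omega = 0.2, kappa = 2,
                           codons = 10, seed = 1)
  aln <- simulate_codon_alignment(cfg)
  tr_extra <- ape::read.tree(text = "((A:1,B:1):1,(C:1,Z:1):1);")
  spec <- codon_model_spec("one_ratio", kappa = 2, omega = 0.2,
                           pi = uniform_codon_frequencies())
  expect_error(pruning_loglik(tr_extra, aln, spec), "Z")
  expect_error(codon_model_spec("one_ratio", kappa = -1, omega = 0.2,
                                pi = uniform_codon_frequencies()),
               "positive")
  expect_error(codon_model_spec("two_ratio", kappa = 1, omega = 0.5,
                                pi = uniform_codon_frequencies()),
               "background")
})
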