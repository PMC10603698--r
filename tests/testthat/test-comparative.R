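test_that("exact Mann-Whitney p equals full enumeration", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  mw <- mann_whitney(a, b)
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)  # 2 / choose(6, 3)
  expect_equal(mw$p, mw_enum_oracle(a, b))
  expect_equal(mw$method, "exact")
  # random tie-free samples agree with the enumeration oracle
  set.seed(14)
  for (i in 1:5) {
    x <- sample(seq(1, 40), 5)
    y <- sample(seq(41, 80) + 0.5, 6)
    y <- y - stats::runif(6)  # interleave values, keep tie-free
    expect_equal(mann_whitney(x, y)$p, mw_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("identical samples give the symmetric null answer", {
  a <- c(2, 4, 6, 8)
  mw <- mann_whitney(a, a + 1e-9)  # same up to jitter-free ordering
  expect_gt(mw$p, 0.5)
  expect_warning(mw0 <- mann_whitney(c(1, 1), c(1, 1)), "identical")
  expect_equal(mw0$p, 1)
})

test_that("normal approximation tracks the exact path at moderate n", {
  set.seed(25)
  x <- stats::rnorm(9)
  y <- stats::rnorm(12, mean = 0.4)
  exact <- mann_whitney(x, y, exact_max = 12)$p
  approx <- mann_whitney(x, y, exact_max = 0)$p
  expect_lt(abs(exact - approx), 0.02)
})

test_that("two-tip and constant-trait contrasts follow the formula", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  pc <- pic_contrasts(tr, c(A = 3, B = 1))
  expect_equal(unname(pc$contrasts), (3 - 1) / sqrt(2))
  expect_equal(pc$expected_variances, 2)
  const <- pic_contrasts(tree6(), stats::setNames(rep(2, 6), tree6()$tip.label))
  expect_true(all(const$contrasts == 0))
})

test_that("contrasts match an independent recursive oracle and ape", {
  tr <- ape::read.tree(
    text = "((A:0.3,B:0.7):0.4,((C:0.2,D:0.5):0.3,E:0.9):0.1);")
  x <- c(A = 1.2, B = -0.5, C = 3.1, D = 0.4, E = 2.2)
  mine <- pic_contrasts(tr, x)
  oracle <- pic_oracle(tr, x)
  expect_equal(sort(abs(unname(mine$contrasts))), sort(abs(oracle)))
  theirs <- ape::pic(x[tr$tip.label], tr)
  expect_equal(mine$contrasts[names(theirs)], theirs, tolerance = 1e-12)
  expect_equal(length(mine$contrasts), length(tr$tip.label) - 1L)
})

test_that("contrasts flip sign together under child-order swaps", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  swapped <- ape::rotate(tr, node = 6L)
  x <- c(A = 1, B = 4, C = 2, D = 9)
  c1 <- pic_contrasts(tr, x)$contrasts
  c2 <- pic_contrasts(swapped, x)$contrasts
  expect_equal(abs(c1[order(names(c1))]), abs(c2[order(names(c2))]))
})

test_that("degenerate trees are handled with warnings, not crashes", {
  tr <- ape::read.tree(text = "((A:1,B:0):1,C:1);")
  expect_warning(pc <- pic_contrasts(tr, c(A = 1, B = 2, C = 3)),
                 "floored")
  expect_true(all(is.finite(pc$contrasts)))
  poly <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_message(
    suppressWarnings(pp <- pic_contrasts(poly, c(A = 1, B = 2, C = 6))),
    "polytomy")
  expect_length(pp$contrasts, 2L)
  expect_error(suppressWarnings(pic_contrasts(tr, c(A = 1, B = 2))),
               "missing")
})

test_that("regression through the origin behaves as PIC theory demands", {
  set.seed(44)
  cx <- stats::rnorm(10)
  fit <- pic_regression(cx, 2 * cx)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r, 1)
  expect_lt(fit$p, 1e-10)
  expect_equal(fit$df, 9L)
  # invariance to simultaneous sign flips
  cy <- 0.5 * cx + stats::rnorm(10, sd = 0.3)
  f1 <- pic_regression(cx, cy)
  f2 <- pic_regression(-cx, -cy)
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$p, f2$p)
  expect_error(pic_regression(rep(0, 5), stats::rnorm(5)), "zero variance")
  expect_error(pic_regression(cx[1:2], cy[1:2]), "at least 3")
})

test_that("star-tree PIC regression approaches ordinary no-intercept fit", {
  set.seed(90)
  n <- 12L
  star <- ape::read.tree(
    text = paste0("(", paste0("t", 1:n, ":1", collapse = ","), ");"))
  x <- stats::setNames(stats::rnorm(n), star$tip.label)
  y <- stats::setNames(0.8 * x + stats::rnorm(n, sd = 0.5),
                       star$tip.label)
  quiet_pic <- function(v)
    suppressWarnings(suppressMessages(pic_contrasts(star, v)$contrasts))
  cx <- quiet_pic(x)
  cy <- quiet_pic(y)
  fit <- pic_regression(cx, cy)
  lmfit <- summary(stats::lm(cy ~ cx + 0))
  expect_equal(fit$slope, unname(coef(lmfit)[1, 1]), tolerance = 1e-6)
  expect_equal(fit$p, unname(coef(lmfit)[1, 4]), tolerance = 1e-6)
})

test_that("group report compares habitats per gene with direction", {
  set.seed(33)
  taxa <- paste0("t", 1:10)
  hab <- stats::setNames(rep(c(1L, 0L), each = 5), taxa)
  omega_by_gene <- list(
    up = stats::setNames(c(stats::runif(5, 0.5, 0.9),
                           stats::runif(5, 0.1, 0.3)), taxa),
    flat = stats::setNames(stats::runif(10, 0.2, 0.25), taxa))
  rep_ <- rate_group_report(omega_by_gene, hab)
  expect_equal(nrow(rep_), 2L)
  expect_equal(rep_$direction[rep_$gene == "up"], 1)
  expect_lt(rep_$p[rep_$gene == "up"], 0.05)
  expect_gt(rep_$p[rep_$gene == "flat"], 0.05)
  expect_true(all(c("p_bh", "U") %in% names(rep_)))
  expect_error(rate_group_report(omega_by_gene, hab[1:5]), "missing")
})

test_that("permuting tip values destroys a planted PIC association", {
  set.seed(55)
  tr <- make_study_tree()
  hab <- stats::setNames(
    as.integer(tr$tip.label %in% attr(tr, "foreground")), tr$tip.label)
  noise <- ape::rTraitCont(tr, model = "BM", sigma = sqrt(0.05))
  omega <- 10^(log10(0.1) + log10(2) * hab[names(noise)] + noise)
  planted <- pic_habitat_test(tr, omega, hab)
  expect_lt(planted$p, 0.05)
  expect_gt(planted$slope, 0)
  perm_p <- replicate(50, {
    shuffled <- stats::setNames(sample(omega), names(omega))
    pic_habitat_test(tr, shuffled, hab)$p
  })
  expect_gt(mean(perm_p), 0.3)
})
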