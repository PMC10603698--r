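#' Goldman–Yang codon substitution rate matrix
#'
#' Builds the 60x60 instantaneous rate matrix of the Goldman–Yang-style
#' codon model over the sense codons of the vertebrate mitochondrial
#' code. Codon pairs differing at more than one position have rate 0;
#' single-nucleotide changes have rate proportional to the target codon
#' frequency times 1 (synonymous transversion), kappa (synonymous
#' transition), omega (nonsynonymous transversion) or omega*kappa
#' (nonsynonymous transition). The matrix is scaled so the expected
#' substitution rate at stationarity is 1, i.e. branch lengths are in
#' expected substitutions per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio dN/dS (> 0).
#' @param pi Stationary codon frequencies (length 60, positive, sums
#'   to 1).
#' @return 60x60 numeric matrix with codon dimnames.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi) {
  check_pi(pi)
  if (kappa <= 0 || omega <= 0) stop("kappa and omega must be positive")
  cls <- codon_pair_classes()
  mult <- c(0, 1, kappa, omega, omega * kappa)[cls + 1L]
  q <- matrix(mult, 60L, 60L, dimnames = dimnames(cls)) *
    rep(pi, each = 60L)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  rate <- -sum(pi * diag(q))
  q / rate
}

check_pi <- function(pi) {
  if (length(pi) != 60L || any(!is.finite(pi)) || any(pi <= 0) ||
      abs(sum(pi) - 1) > 1e-8)
    stop("pi must be 60 positive frequencies summing to 1")
  invisible(TRUE)
}

#' Empirical F3x4 codon frequencies
#'
#' Codon frequencies from the empirical nucleotide frequencies at the
#' three codon positions of an alignment, restricted and renormalized to
#' the sense codons, with a small pseudocount keeping all entries
#' positive.
#'
#' @param aln A [codon_alignment()].
#' @param pseudocount Added to each position-specific nucleotide count
#'   fraction (default 1e-6).
#' @return Numeric vector of length 60 (named by codon), summing to 1.
#' @export
f3x4_frequencies <- function(aln, pseudocount = 1e-6) {
  codons <- mito_codons()
  obs <- codons[aln$states]
  mat <- do.call(rbind, strsplit(obs, ""))
  nt <- c("A", "C", "G", "T")
  f <- vapply(1:3, function(p) {
    tab <- table(factor(mat[, p], levels = nt))
    as.numeric(tab) / sum(tab)
  }, numeric(4L))  # 4 x 3
  dimnames(f) <- list(nt, NULL)
  f <- f + pseudocount
  f <- sweep(f, 2L, colSums(f), "/")
  cm <- do.call(rbind, strsplit(codons, ""))
  idx <- function(p) cbind(match(cm[, p], nt), p)
  pi <- f[idx(1L)] * f[idx(2L)] * f[idx(3L)]
  pi <- pi / sum(pi)
  stats::setNames(pi, codons)
}

#' Uniform codon frequencies
#' @return Length-60 vector with all entries 1/60.
#' @export
uniform_codon_frequencies <- function() {
  stats::setNames(rep(1 / 60, 60L), mito_codons())
}

# Spectral decomposition of Q exploiting reversibility: with
# S = D^{1/2} Q D^{-1/2} symmetric (D = diag(pi)), exp(Qt) =
# D^{-1/2} U exp(Lambda t) U' D^{1/2}. Returns the pieces needed to
# form transition matrices cheaply for many t.
eigen_gy94 <- function(kappa, omega, pi) {
  q <- gy94_rate_matrix(kappa, omega, pi)
  sq <- sqrt(pi)
  s <- q * (sq / rep(sq, each = 60L))  # sq_i * q_ij / sq_j  (row i, col j)
  s <- (s + t(s)) / 2                  # enforce exact symmetry
  e <- eigen(s, symmetric = TRUE)
  list(values = e$values,
       left = e$vectors / sq,              # D^{-1/2} U  (rows scaled)
       right = t(e$vectors * sq))          # U' D^{1/2}
}

# Transition probability matrix P(t) = exp(Qt) from an eigen_gy94 object.
transition_prob <- function(eg, t) {
  if (t < 0) stop("negative branch length")
  p <- eg$left %*% (exp(eg$values * t) * eg$right)
  p[p < 0] <- 0  # clip eigen round-off
  p
}
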