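# Shared fixtures and independent oracles used across the suite.

# small rooted trees with branch lengths in expected substitutions/codon
tree4 <- function() ape::read.tree(text = "((A:0.2,B:0.2):0.2,(C:0.2,D:0.2):0.2);")
tree6 <- function() ape::read.tree(
  text = "(((A:0.2,B:0.2):0.2,(C:0.2,D:0.2):0.2):0.2,(E:0.2,F:0.2):0.2);")

# random toy gene layout for annotation property tests
random_layout <- function(n_genes = 8L) {
  data.frame(
    gene = paste0("g", seq_len(n_genes)),
    length = sample(60:400, n_genes, replace = TRUE),
    spacer = c(NA, sample(-20:30, n_genes - 1L, replace = TRUE)),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    category = c("PCG", sample(c("PCG", "tRNA", "rRNA"), n_genes - 1L,
                               replace = TRUE)),
    start_codon = "ATG", stop_codon = "TAA",
    stringsAsFactors = FALSE)
}

fix_layout_codons <- function(lay) {
  lay$start_codon[lay$category != "PCG"] <- NA
  lay$stop_codon[lay$category != "PCG"] <- NA
  lay
}

# exhaustive-enumeration likelihood oracle for the 4-taxon tree4()
# topology ((A,B)u,(C,D)v)root; independent of the pruning code path
brute_loglik4 <- function(aln, kappa, omega, pi,
                          bl = c(A = 0.2, B = 0.2, C = 0.2, D = 0.2,
                                 u = 0.2, v = 0.2)) {
  eg <- mitosel:::eigen_gy94(kappa, omega, pi)
  P <- lapply(bl, function(t) mitosel:::transition_prob(eg, t))
  st <- aln$states
  total <- 0
  for (s in seq_len(ncol(st))) {
    lik <- 0
    for (u in 1:60) for (v in 1:60) for (r in 1:60) {
      lik <- lik + pi[[r]] *
        P[["u"]][r, u] * P[["A"]][u, st["A", s]] * P[["B"]][u, st["B", s]] *
        P[["v"]][r, v] * P[["C"]][v, st["C", s]] * P[["D"]][v, st["D", s]]
    }
    total <- total + log(lik)
  }
  total
}

# full-enumeration Mann-Whitney oracle: exact two-sided p by listing
# every group labeling
mw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2L, function(idx) u_of(pooled[idx], pooled[-idx]))
  mu <- length(a) * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# independent recursive PIC oracle (straight transcription of the
# recursion, no shared code with pic_contrasts)
pic_oracle <- function(tree, x) {
  ntip <- length(tree$tip.label)
  val <- function(node) {
    if (node <= ntip)
      return(list(x = unname(x[tree$tip.label[node]]), b = edge_len(node)))
    ch <- tree$edge[tree$edge[, 1L] == node, 2L]
    l <- val(ch[1L]); r <- val(ch[2L])
    cc <<- c(cc, (l$x - r$x) / sqrt(l$b + r$b))
    list(x = (l$x / l$b + r$x / r$b) / (1 / l$b + 1 / r$b),
         b = edge_len(node) + l$b * r$b / (l$b + r$b))
  }
  edge_len <- function(node) {
    k <- which(tree$edge[, 2L] == node)
    if (length(k)) tree$edge.length[k] else 0
  }
  cc <- numeric(0)
  val(ntip + 1L)
  cc
}
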