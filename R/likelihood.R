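#' @importFrom ape read.tree write.tree getMRCA Ntip reorder.phylo
NULL

#' Codon model specification
#'
#' Describes a branch codon model: shared transition/transversion ratio
#' `kappa`, stationary codon frequencies `pi`, and the omega (dN/dS)
#' parameterization — a single value (`one_ratio`), a
#' background/foreground pair (`two_ratio`), or one value per branch
#' (`free_ratio`).
#'
#' @param model_class One of `"one_ratio"`, `"two_ratio"`,
#'   `"free_ratio"`.
#' @param kappa Transition/transversion ratio (> 0).
#' @param omega For `one_ratio` a single value; for `two_ratio` a named
#'   vector `c(background=, foreground=)`; for `free_ratio` one value
#'   per tree edge.
#' @param pi Codon frequencies over the 60 sense codons.
#' @param foreground_edges Logical per-edge vector (required for
#'   `two_ratio`), e.g. from [mark_foreground()].
#' @return Object of class `codon_model_spec`.
#' @export
codon_model_spec <- function(model_class = c("one_ratio", "two_ratio",
                                             "free_ratio"),
                             kappa, omega, pi, foreground_edges = NULL) {
  model_class <- match.arg(model_class)
  check_pi(pi)
  if (kappa <= 0 || any(omega <= 0)) stop("kappa and omega must be positive")
  if (model_class == "two_ratio") {
    if (length(omega) != 2L || !all(c("background", "foreground") %in% names(omega)))
      stop("two_ratio requires omega = c(background=, foreground=)")
    if (is.null(foreground_edges))
      stop("two_ratio requires foreground_edges")
  }
  structure(list(model_class = model_class, kappa = kappa, omega = omega,
                 pi = pi, foreground_edges = foreground_edges),
            class = "codon_model_spec")
}

#' Mark foreground branches from a clade-defining tip set
#'
#' Flags the edges of the clade spanned by `tips` (all internal and
#' terminal branches of the clade, plus its stem branch when
#' `include_stem = TRUE`) as foreground for two-ratio models.
#'
#' @param tree Rooted `phylo` tree.
#' @param tips Tip labels defining the foreground clade.
#' @param include_stem Include the branch leading to the clade's most
#'   recent common ancestor? Default `TRUE`.
#' @return Logical vector over `tree$edge` rows.
#' @export
mark_foreground <- function(tree, tips, include_stem = TRUE) {
  tips <- normalize_taxa(tips)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("tips not in tree: ", paste(missing, collapse = ", "))
  if (length(tips) == 1L) {
    node <- match(tips, tree$tip.label)
    return(tree$edge[, 2L] == node)
  }
  mrca <- ape::getMRCA(tree, tips)
  desc <- node_descendants(tree, mrca)
  fg <- tree$edge[, 2L] %in% desc
  if (include_stem) fg <- fg | tree$edge[, 2L] == mrca
  fg
}

# all descendant node ids (internal + tips) below `node`, excluding it
node_descendants <- function(tree, node) {
  out <- integer(0)
  stack <- tree$edge[tree$edge[, 1L] == node, 2L]
  while (length(stack)) {
    n <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, n)
    stack <- c(stack, tree$edge[tree$edge[, 1L] == n, 2L])
  }
  out
}

# Compress alignment columns into unique site patterns for the tips of
# a tree. Returns integer matrix (tips x patterns) and pattern weights.
compress_patterns <- function(tree, aln) {
  miss <- setdiff(tree$tip.label, aln$taxa)
  if (length(miss))
    stop("tree tips absent from alignment: ", paste(miss, collapse = ", "))
  m <- aln$states[tree$tip.label, , drop = FALSE]
  key <- apply(m, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(states = m[, first, drop = FALSE], weights = w)
}

# Static traversal plan for a tree: postorder edge order plus the map
# back to the original tree$edge rows. Branch lengths and omegas stay
# indexed by the original rows so the plan survives their updates.
pruning_plan <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  map <- match(paste(tr$edge[, 1L], tr$edge[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  list(edge = tr$edge, map = map, ntip = length(tree$tip.label),
       nnode = tree$Nnode, root = length(tree$tip.label) + 1L)
}

# Per-edge transition matrices for the current parameters, indexed by
# original tree$edge rows.
edge_p_matrices <- function(tree, kappa, omega_edge, pi, egs = NULL) {
  if (is.null(egs)) {
    egs <- lapply(unique(omega_edge),
                  function(om) eigen_gy94(kappa, om, pi))
    names(egs) <- as.character(unique(omega_edge))
  }
  lapply(seq_len(nrow(tree$edge)), function(e)
    transition_prob(egs[[as.character(omega_edge[e])]],
                    tree$edge.length[e]))
}

# Core pruning likelihood. omega_edge: numeric vector of dN/dS per row
# of tree$edge. Eigen-decompositions are shared across edges with equal
# omega. Per-edge column scaling guards against underflow.
codon_loglik <- function(tree, aln, kappa, omega_edge, pi,
                         patterns = NULL, egs = NULL, plan = NULL,
                         pmats = NULL) {
  if (is.null(patterns)) patterns <- compress_patterns(tree, aln)
  if (is.null(plan)) plan <- pruning_plan(tree)
  nedge <- nrow(tree$edge)
  if (length(omega_edge) == 1L) omega_edge <- rep(omega_edge, nedge)
  if (length(omega_edge) != nedge)
    stop("omega_edge must have one value per edge")
  if (is.null(pmats))
    pmats <- edge_p_matrices(tree, kappa, omega_edge, pi, egs)
  dn <- down_pass(plan, pmats, patterns)
  lik <- colSums(pi * dn$partial[[plan$root]])
  if (any(lik <= 0) || any(!is.finite(lik)))
    stop("non-finite site likelihood at pattern ",
         which(lik <= 0 | !is.finite(lik))[1L])
  sum(patterns$weights * (log(lik) + dn$logscale[[plan$root]]))
}

# Postorder (tips-to-root) pass: conditional partials per internal node
# with per-pattern log scaling, plus each edge's scaled contribution
# (needed by the edge-profile machinery).
down_pass <- function(plan, pmats, patterns, keep_m = FALSE) {
  states <- patterns$states
  npat <- ncol(states)
  ntip <- plan$ntip
  partial <- vector("list", ntip + plan$nnode)
  logscale <- vector("list", ntip + plan$nnode)
  m_edge <- if (keep_m) vector("list", nrow(plan$edge)) else NULL
  mls_edge <- if (keep_m) vector("list", nrow(plan$edge)) else NULL
  for (k in seq_len(nrow(plan$edge))) {
    par <- plan$edge[k, 1L]
    chd <- plan$edge[k, 2L]
    p <- pmats[[plan$map[k]]]
    if (chd <= ntip) {
      m <- p[, states[chd, ], drop = FALSE]
      ls <- numeric(npat)
    } else {
      m <- p %*% partial[[chd]]
      ls <- logscale[[chd]]
    }
    s <- colSums(m)
    if (any(s <= 0) || any(!is.finite(s))) {
      bad <- which(s <= 0 | !is.finite(s))[1L]
      stop("non-finite site likelihood at pattern ", bad)
    }
    m <- m / rep(s, each = nrow(m))
    ls <- ls + log(s)
    if (keep_m) {
      m_edge[[plan$map[k]]] <- m
      mls_edge[[plan$map[k]]] <- ls
    }
    if (is.null(partial[[par]])) {
      partial[[par]] <- m
      logscale[[par]] <- ls
    } else {
      partial[[par]] <- partial[[par]] * m
      logscale[[par]] <- logscale[[par]] + ls
    }
  }
  list(partial = partial, logscale = logscale, m_edge = m_edge,
       mls_edge = mls_edge)
}

# Likelihood profile of a single branch: everything except this edge's
# transition matrix is folded into a "proximal" matrix F (flow from the
# rest of the tree, root frequencies included) and the child's own
# "distal" partial, so the likelihood at any candidate length t costs
# one matrix product. Returns a function lnL(P_edge).
edge_profile <- function(tree, plan, pmats, patterns, pi, k_orig) {
  dn <- down_pass(plan, pmats, patterns, keep_m = TRUE)
  npat <- ncol(patterns$states)
  ntip <- plan$ntip
  child <- tree$edge[k_orig, 2L]
  # path of original-edge indices from the root down to this edge
  parent_of <- stats::setNames(tree$edge[, 1L], tree$edge[, 2L])
  edge_of <- stats::setNames(seq_len(nrow(tree$edge)), tree$edge[, 2L])
  path <- integer(0)
  node <- child
  while (node != plan$root) {
    path <- c(edge_of[[as.character(node)]], path)
    node <- parent_of[[as.character(node)]]
  }
  f <- matrix(pi, 60L, npat)
  fls <- numeric(npat)
  for (e in path) {
    par <- tree$edge[e, 1L]
    sibs <- setdiff(which(tree$edge[, 1L] == par), e)
    for (s in sibs) {
      f <- f * dn$m_edge[[s]]
      fls <- fls + dn$mls_edge[[s]]
    }
    if (e == k_orig) break
    f <- crossprod(pmats[[e]], f)
    sc <- colSums(f)
    f <- f / rep(sc, each = 60L)
    fls <- fls + log(sc)
  }
  d_child <- if (child <= ntip) NULL else dn$partial[[child]]
  dls <- if (child <= ntip) numeric(npat) else dn$logscale[[child]]
  tip_states <- if (child <= ntip) patterns$states[child, ] else NULL
  w <- patterns$weights
  function(p_edge) {
    g <- crossprod(p_edge, f)
    lik <- if (is.null(d_child))
      g[cbind(tip_states, seq_len(npat))]
    else colSums(g * d_child)
    if (any(lik <= 0) || any(!is.finite(lik))) return(-Inf)
    sum(w * (log(lik) + fls + dls))
  }
}

#' Log-likelihood of a codon alignment under a branch codon model
#'
#' Felsenstein pruning over the 60 sense-codon states with per-branch
#' transition matrices `exp(Q_b t_b)`, where each branch's rate matrix
#' uses the omega of its branch class. Site patterns are compressed
#' before the pass.
#'
#' @param tree Rooted `phylo` with branch lengths in expected
#'   substitutions per codon.
#' @param aln A [codon_alignment()] containing all tree tips.
#' @param spec A [codon_model_spec()].
#' @return Log-likelihood (numeric scalar).
#' @export
pruning_loglik <- function(tree, aln, spec) {
  stopifnot(inherits(spec, "codon_model_spec"))
  omega_edge <- spec_omega_edge(tree, spec)
  codon_loglik(tree, aln, spec$kappa, omega_edge, spec$pi)
}

# expand a model spec into a per-edge omega vector
spec_omega_edge <- function(tree, spec) {
  nedge <- nrow(tree$edge)
  switch(spec$model_class,
    one_ratio = rep(unname(spec$omega[1L]), nedge),
    two_ratio = {
      fg <- spec$foreground_edges
      if (length(fg) != nedge) stop("foreground_edges length mismatch")
      ifelse(fg, spec$omega[["foreground"]], spec$omega[["background"]])
    },
    free_ratio = {
      if (length(spec$omega) != nedge)
        stop("free_ratio omega must have one value per edge")
      unname(spec$omega)
    })
}
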