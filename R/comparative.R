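#' Mann–Whitney–Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two samples, reporting the U
#' statistic for the first sample. The exact null distribution is used
#' when the smaller sample has at most 10 observations and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_max Largest min(n) for which the exact distribution is
#'   enumerated (default 10).
#' @return List with `U`, `p`, `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 10L) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical across groups; p = 1")
    return(list(U = length(a) * length(b) / 2, p = 1,
                method = "degenerate"))
  }
  exact <- !ties && min(length(a), length(b)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Phylogenetic independent contrasts
#'
#' Felsenstein's standardized independent contrasts of one tip trait on
#' a rooted tree: a post-order pass replaces each internal node by the
#' branch-length-weighted average of its children, emits the contrast
#' `(x_i - x_j) / sqrt(b_i + b_j)` and lengthens the parent branch by
#' `b_i b_j / (b_i + b_j)`. Zero branch lengths are floored at 1e-8
#' with a warning; polytomies are resolved arbitrarily into
#' zero-length bifurcations (reported).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param tip_values Named numeric vector covering every tip.
#' @return List with `contrasts` (length tips − 1, named by internal
#'   node id) and `expected_variances` (the sums of adjusted branch
#'   lengths).
#' @export
pic_contrasts <- function(tree, tip_values) {
  miss <- setdiff(tree$tip.label, names(tip_values))
  if (length(miss))
    stop("tip values missing for: ", paste(miss, collapse = ", "))
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    message("polytomy resolved into zero-length bifurcations")
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length <= 0)) {
    warning("non-positive branch lengths floored at 1e-8")
    tree$edge.length[tree$edge.length <= 0] <- 1e-8
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  x <- numeric(nnode)
  x[seq_len(ntip)] <- tip_values[tree$tip.label]
  blen <- numeric(nnode)  # working branch length above each node
  blen[tree$edge[, 2L]] <- tree$edge.length

  contrasts <- numeric(0)
  variances <- numeric(0)
  # post-order recursion: each internal node contrasts its two children
  visit <- function(node) {
    if (node <= ntip) return(invisible(NULL))
    children <- tree$edge[tree$edge[, 1L] == node, 2L]
    for (ch in children) visit(ch)
    i <- children[1L]; j <- children[2L]
    bi <- blen[i]; bj <- blen[j]
    v <- bi + bj
    contrasts[[as.character(node)]] <<- (x[i] - x[j]) / sqrt(v)
    variances <<- c(variances, v)
    x[node] <<- (x[i] / bi + x[j] / bj) / (1 / bi + 1 / bj)
    blen[node] <<- blen[node] + bi * bj / (bi + bj)
    invisible(NULL)
  }
  visit(ntip + 1L)
  list(contrasts = unlist(contrasts), expected_variances = variances)
}

#' Regression through the origin of paired contrasts
#'
#' Regresses one contrast set on another with no intercept, the
#' standard test of trait association under independent contrasts.
#' Degrees of freedom are (number of contrasts − 1); the p-value is the
#' two-sided t probability.
#'
#' @param cx,cy Equal-length contrast vectors (length >= 3); `cy` is
#'   regressed on `cx`.
#' @return Object of class `pic_fit`: list with `slope`, `r`, `t`,
#'   `df`, `p`, `n`.
#' @export
pic_regression <- function(cx, cy) {
  if (length(cx) != length(cy)) stop("contrast vectors differ in length")
  n <- length(cx)
  if (n < 3L) stop("need at least 3 contrasts")
  sxx <- sum(cx^2)
  if (sxx == 0) stop("zero variance in predictor contrasts")
  slope <- sum(cx * cy) / sxx
  syy <- sum(cy^2)
  r <- if (syy == 0) 0 else sum(cx * cy) / sqrt(sxx * syy)
  df <- n - 1L
  tstat <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  structure(list(slope = slope, r = r, t = tstat, df = df, p = p,
                 n = n),
            class = "pic_fit")
}

#' @export
print.pic_fit <- function(x, ...) {
  cat(sprintf(
    "PIC regression through the origin (%d contrasts)\n", x$n))
  cat(sprintf("  slope = %.4f   r = %.4f   t = %.4f (df %d)   p = %.4f\n",
              x$slope, x$r, x$t, x$df, x$p))
  invisible(x)
}

#' @export
coef.pic_fit <- function(object, ...) c(slope = object$slope)

#' @export
summary.pic_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' PIC test of habitat against evolutionary rate
#'
#' Computes independent contrasts of the binary habitat code (treated
#' as a continuous 0/1 trait) and of log10 root-to-tip omega on the
#' same tree, then regresses the rate contrasts on the habitat
#' contrasts through the origin. Omega values of 0 are floored at 1e-6
#' before the log transform (with a warning).
#'
#' @param tree Rooted `phylo`.
#' @param omega Named per-taxon root-to-tip omega values.
#' @param habitat Named per-taxon habitat codes (1 = semi-aquatic,
#'   0 = terrestrial).
#' @return A [pic_regression()] `pic_fit` with the contrast sets in
#'   attribute `"contrasts"`.
#' @export
pic_habitat_test <- function(tree, omega, habitat) {
  if (any(omega <= 0)) {
    warning("omega values <= 0 floored at 1e-6 before log10")
    omega[omega <= 0] <- 1e-6
  }
  cx <- pic_contrasts(tree, habitat)
  cy <- pic_contrasts(tree, log10(omega))
  fit <- pic_regression(cx$contrasts, cy$contrasts)
  attr(fit, "contrasts") <- list(habitat = cx$contrasts,
                                 log10_omega = cy$contrasts)
  fit
}

#' Read a habitat coding file
#'
#' TSV with columns `taxon` and `code` (1 = semi-aquatic,
#' 0 = terrestrial). Taxon labels are normalized to the shared
#' underscore convention.
#'
#' @param path File path.
#' @return Named integer vector of 0/1 codes.
#' @export
read_habitat_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "code") %in% names(d)))
    stop("habitat table needs columns 'taxon' and 'code'")
  if (!all(d$code %in% c(0L, 1L)))
    stop("habitat codes must be 0 or 1")
  stats::setNames(as.integer(d$code), normalize_taxa(d$taxon))
}

#' Per-gene habitat-group comparison of root-to-tip omega
#'
#' For each gene (and the concatenated dataset), compares root-to-tip
#' omega between the semi-aquatic (code 1) and terrestrial (code 0)
#' groups with the Mann–Whitney–Wilcoxon test. Direction is the sign
#' of (semi-aquatic median − terrestrial median). A Benjamini–Hochberg
#' adjusted column is added as supplementary output.
#'
#' @param omega_by_gene Named list: gene -> named per-taxon
#'   root-to-tip omega vector.
#' @param habitat Named 0/1 vector (e.g. from [read_habitat_table()]).
#' @return data.frame with one row per gene: `gene`,
#'   `median_semiaquatic`, `median_terrestrial`, `U`, `p`, `direction`,
#'   `p_bh`.
#' @export
rate_group_report <- function(omega_by_gene, habitat) {
  rows <- lapply(names(omega_by_gene), function(g) {
    v <- omega_by_gene[[g]]
    miss <- setdiff(names(v), names(habitat))
    if (length(miss))
      stop("taxa missing from habitat file: ",
           paste(miss, collapse = ", "))
    grp <- habitat[names(v)]
    a <- v[grp == 1L]  # semi-aquatic
    b <- v[grp == 0L]  # terrestrial
    if (!length(a) || !length(b)) stop("both habitat groups must be non-empty")
    mw <- mann_whitney(a, b)
    data.frame(gene = g,
               median_semiaquatic = stats::median(a),
               median_terrestrial = stats::median(b),
               U = mw$U, p = mw$p,
               direction = sign(stats::median(a) - stats::median(b)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
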