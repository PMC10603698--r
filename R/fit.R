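#' Fit a branch codon model by maximum likelihood
#'
#' Fits a Goldman–Yang-style codon substitution model with
#' branch-specific dN/dS to a codon alignment on a fixed rooted
#' topology. Three branch-model classes are supported:
#' `one_ratio` (a single omega shared by all branches), `two_ratio`
#' (distinct background and foreground omega, the foreground being a
#' marked clade), and `free_ratio` (one omega per branch).
#'
#' Branch lengths (expected substitutions per codon) are co-estimated
#' under the one-ratio model and then held fixed for the two-ratio and
#' free-ratio fits, which reuse the one-ratio fit passed as `null_fit`
#' (or run one internally). Optimization uses bounded quasi-Newton
#' (L-BFGS-B) on log-transformed parameters with multiple omega starts;
#' free-ratio omegas are refined branch-wise after the shared-omega
#' pass.
#'
#' @param aln A [codon_alignment()].
#' @param tree Rooted `phylo`; its branch lengths seed the co-estimation
#'   (absent or zero lengths start from 0.1).
#' @param model `"one_ratio"`, `"two_ratio"` or `"free_ratio"`.
#' @param foreground Tip labels defining the foreground clade
#'   (two-ratio only).
#' @param include_stem Include the clade's stem branch in the
#'   foreground? Default `TRUE`.
#' @param frequencies `"f3x4"` (empirical, the default) or `"uniform"`,
#'   or a numeric vector of 60 codon frequencies.
#' @param null_fit A one-ratio `branch_fit` on the same data whose
#'   branch lengths (and starting values) are reused; if `NULL`,
#'   two-ratio and free-ratio fits run the one-ratio pass internally.
#' @param estimate_branch_lengths Co-estimate branch lengths in the
#'   one-ratio fit? Default `TRUE`; set `FALSE` to keep `tree`'s.
#' @param omega_starts Multi-start values for omega.
#' @param kappa_start Starting transition/transversion ratio.
#' @param jitter Relative log-scale jitter applied to the starts
#'   (seed-controlled via the caller's RNG); 0 disables.
#' @param control List: `tol` (lnL convergence tolerance between
#'   branch-length sweeps, default 1e-3), `max_sweeps` (default 5),
#'   `free_rounds` (branch-wise refinement rounds, default 2).
#' @return Object of class `branch_fit`.
#' @export
fit_branch_model <- function(aln, tree,
                             model = c("one_ratio", "two_ratio",
                                       "free_ratio"),
                             foreground = NULL, include_stem = TRUE,
                             frequencies = "f3x4", null_fit = NULL,
                             estimate_branch_lengths = TRUE,
                             omega_starts = c(0.1, 0.5, 1.5),
                             kappa_start = 2, jitter = 0,
                             control = list()) {
  model <- match.arg(model)
  ctl <- utils::modifyList(list(tol = 1e-3, max_sweeps = 5L,
                                free_rounds = 2L), control)
  pi <- resolve_frequencies(frequencies, aln)
  tree$tip.label <- normalize_taxa(tree$tip.label)
  patterns <- compress_patterns(tree, aln)

  if (model != "one_ratio" && is.null(null_fit)) {
    null_fit <- fit_branch_model(aln, tree, "one_ratio",
                                 frequencies = pi,
                                 estimate_branch_lengths = estimate_branch_lengths,
                                 omega_starts = omega_starts,
                                 kappa_start = kappa_start,
                                 jitter = jitter, control = control)
  }

  fit <- switch(model,
    one_ratio = fit_one_ratio(tree, aln, pi, patterns,
                              estimate_branch_lengths, omega_starts,
                              kappa_start, jitter, ctl),
    two_ratio = fit_two_ratio(null_fit, aln, pi, foreground,
                              include_stem, omega_starts, jitter),
    free_ratio = fit_free_ratio(null_fit, aln, pi, ctl))
  fit$gene_label <- aln$gene_label
  fit$nsites <- ncol(aln$states)
  fit$npatterns <- ncol(patterns$states)
  fit$call <- match.call()
  class(fit) <- "branch_fit"
  fit
}

resolve_frequencies <- function(frequencies, aln) {
  if (is.numeric(frequencies)) {
    check_pi(frequencies)
    return(frequencies)
  }
  switch(match.arg(frequencies, c("f3x4", "uniform")),
         f3x4 = f3x4_frequencies(aln),
         uniform = uniform_codon_frequencies())
}

# bounds on the log scale
.LOGK <- log(c(0.05, 100))
.LOGW <- log(c(1e-4, 50))
.BL <- c(1e-8, 10)

safe_nll <- function(f) {
  function(par) {
    v <- tryCatch(f(par), error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else -v
  }
}

jitter_starts <- function(x, jitter) {
  if (jitter <= 0) return(x)
  x * exp(stats::runif(length(x), -jitter, jitter))
}

fit_one_ratio <- function(tree, aln, pi, patterns, estimate_bl,
                          omega_starts, kappa_start, jitter, ctl) {
  nedge <- nrow(tree$edge)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nedge)
  tree$edge.length[tree$edge.length < .BL[1L]] <- 0.1
  omega_starts <- jitter_starts(omega_starts, jitter)
  kappa_start <- jitter_starts(kappa_start, jitter)
  plan <- pruning_plan(tree)

  kw_obj <- function(tr) safe_nll(function(par)
    codon_loglik(tr, aln, exp(par[1L]), exp(par[2L]), pi,
                 patterns = patterns, plan = plan))
  opt_kw <- function(tr, k0, w0) {
    stats::optim(c(log(k0), log(w0)), kw_obj(tr), method = "L-BFGS-B",
                 lower = c(.LOGK[1L], .LOGW[1L]),
                 upper = c(.LOGK[2L], .LOGW[2L]),
                 control = list(factr = 1e8))
  }
  # multi-start on omega for the shared (kappa, omega) stage; starts
  # are screened by objective value, then fully optimized from the best
  nll <- kw_obj(tree)
  vals <- vapply(omega_starts, function(w0)
    nll(c(log(kappa_start), log(w0))), 0)
  best <- opt_kw(tree, kappa_start, omega_starts[which.min(vals)])
  iterations <- length(omega_starts)
  lnl <- -best$value

  if (estimate_bl) {
    for (sweep in seq_len(ctl$max_sweeps)) {
      kap <- exp(best$par[1L]); om <- exp(best$par[2L])
      eg <- eigen_gy94(kap, om, pi)
      egs <- stats::setNames(list(eg), as.character(om))
      pmats <- edge_p_matrices(tree, kap, rep(om, nedge), pi, egs)
      for (k in seq_len(nedge)) {
        prof <- edge_profile(tree, plan, pmats, patterns, pi, k)
        cur_t <- tree$edge.length[k]
        cur_ll <- prof(pmats[[k]])
        f <- function(t) -prof(transition_prob(eg, t))
        lo <- max(.BL[1L], cur_t / 8)
        hi <- min(.BL[2L], max(cur_t * 8, 0.05))
        opt <- stats::optimize(f, interval = c(lo, hi), tol = 1e-6)
        if (-opt$objective > cur_ll) {
          tree$edge.length[k] <- opt$minimum
          pmats[[k]] <- transition_prob(eg, opt$minimum)
        }
      }
      best <- opt_kw(tree, kap, om)
      iterations <- iterations + 1L
      if (-best$value - lnl < ctl$tol) { lnl <- -best$value; break }
      lnl <- -best$value
    }
  }
  kap <- exp(best$par[1L]); om <- exp(best$par[2L])
  gnorm <- grad_norm(function(par)
    codon_loglik(tree, aln, exp(par[1L]), exp(par[2L]), pi,
                 patterns = patterns, plan = plan), best$par)
  list(model_class = "one_ratio", tree = tree, kappa = kap,
       omega = c(omega = om), lnL = lnl, pi = pi,
       foreground_edges = NULL,
       branch_lengths_estimated = estimate_bl,
       convergence = list(iterations = iterations,
                          gradient_norm = gnorm,
                          code = best$convergence))
}

fit_two_ratio <- function(null_fit, aln, pi, foreground, include_stem,
                          omega_starts, jitter) {
  if (is.null(foreground))
    stop("two_ratio requires a foreground tip set")
  tree <- null_fit$tree
  fg <- mark_foreground(tree, foreground, include_stem = include_stem)
  if (!any(fg) || all(fg))
    stop("foreground must be a proper subset of branches")
  patterns <- compress_patterns(tree, aln)
  plan <- pruning_plan(tree)
  obj <- safe_nll(function(par) {
    om_edge <- ifelse(fg, exp(par[3L]), exp(par[2L]))
    codon_loglik(tree, aln, exp(par[1L]), om_edge, pi,
                 patterns = patterns, plan = plan)
  })
  k0 <- null_fit$kappa; w0 <- unname(null_fit$omega[1L])
  starts <- unname(rbind(c(k0, w0, w0),
                         cbind(k0, w0,
                               jitter_starts(omega_starts, jitter))))
  # screen the omega-start candidates, then optimize from the best one
  # and from the null point (which guarantees lnL(alt) >= lnL(null))
  vals <- vapply(seq_len(nrow(starts)), function(i)
    obj(log(starts[i, ])), 0)
  run_from <- unique(c(1L, which.min(vals)))
  best <- NULL
  for (i in run_from) {
    o <- stats::optim(log(starts[i, ]), obj, method = "L-BFGS-B",
                      lower = c(.LOGK[1L], .LOGW[1L], .LOGW[1L]),
                      upper = c(.LOGK[2L], .LOGW[2L], .LOGW[2L]),
                      control = list(factr = 1e8))
    if (is.null(best) || o$value < best$value) best <- o
  }
  gnorm <- grad_norm(function(par) -obj(par), best$par)
  list(model_class = "two_ratio", tree = tree,
       kappa = exp(best$par[1L]),
       omega = c(background = exp(best$par[2L]),
                 foreground = exp(best$par[3L])),
       lnL = -best$value, pi = pi, foreground_edges = fg,
       branch_lengths_estimated = FALSE,
       convergence = list(iterations = nrow(starts),
                          gradient_norm = gnorm,
                          code = best$convergence))
}

fit_free_ratio <- function(null_fit, aln, pi, ctl) {
  tree <- null_fit$tree
  nedge <- nrow(tree$edge)
  patterns <- compress_patterns(tree, aln)
  plan <- pruning_plan(tree)
  kap <- null_fit$kappa
  om <- rep(unname(null_fit$omega[1L]), nedge)
  lnl <- codon_loglik(tree, aln, kap, om, pi, patterns = patterns,
                      plan = plan)
  for (round in seq_len(ctl$free_rounds)) {
    pmats <- edge_p_matrices(tree, kap, om, pi)
    for (k in seq_len(nedge)) {
      prof <- edge_profile(tree, plan, pmats, patterns, pi, k)
      f <- function(lw)
        -prof(transition_prob(eigen_gy94(kap, exp(lw), pi),
                              tree$edge.length[k]))
      opt <- stats::optimize(f, interval = .LOGW, tol = 1e-4)
      if (-opt$objective > prof(pmats[[k]])) {
        om[k] <- exp(opt$minimum)
        pmats[[k]] <- transition_prob(eigen_gy94(kap, om[k], pi),
                                      tree$edge.length[k])
      }
    }
    fk <- function(lk) -codon_loglik(tree, aln, exp(lk), om, pi,
                                     patterns = patterns, plan = plan)
    optk <- stats::optimize(fk, interval = .LOGK, tol = 1e-4)
    lnl_k <- -optk$objective
    lnl_cur <- -fk(log(kap))
    if (lnl_k > lnl_cur) kap <- exp(optk$minimum)
    lnl <- codon_loglik(tree, aln, kap, om, pi, patterns = patterns,
                        plan = plan)
  }
  names(om) <- paste(tree$edge[, 1L], tree$edge[, 2L], sep = "->")
  list(model_class = "free_ratio", tree = tree, kappa = kap,
       omega = om, lnL = lnl, pi = pi, foreground_edges = NULL,
       branch_lengths_estimated = FALSE,
       convergence = list(iterations = ctl$free_rounds,
                          gradient_norm = NA_real_, code = 0L))
}

# central-difference gradient norm of a log-likelihood surface
grad_norm <- function(f, par, h = 1e-5) {
  g <- vapply(seq_along(par), function(i) {
    p1 <- par; p2 <- par
    p1[i] <- p1[i] + h; p2[i] <- p2[i] - h
    (f(p1) - f(p2)) / (2 * h)
  }, 0)
  sqrt(sum(g^2))
}

#' @export
print.branch_fit <- function(x, ...) {
  cat(sprintf("Branch codon model (%s) on '%s'\n", x$model_class,
              x$gene_label))
  cat(sprintf("  lnL = %.4f   kappa = %.4f\n", x$lnL, x$kappa))
  if (x$model_class == "free_ratio") {
    cat(sprintf("  omega: %d per-branch values in [%.4f, %.4f]\n",
                length(x$omega), min(x$omega), max(x$omega)))
  } else {
    cat("  omega:", paste(sprintf("%s = %.4f", names(x$omega), x$omega),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.branch_fit <- function(object, ...) {
  cat(sprintf("Branch codon model fit: %s\n", object$model_class))
  cat(sprintf("  gene: %s (%d codon sites, %d patterns)\n",
              object$gene_label, object$nsites, object$npatterns))
  cat(sprintf("  tips: %d   branches: %d (lengths %s)\n",
              length(object$tree$tip.label), nrow(object$tree$edge),
              if (object$branch_lengths_estimated) "co-estimated"
              else "fixed"))
  cat(sprintf("  lnL = %.4f\n  kappa = %.4f\n", object$lnL, object$kappa))
  if (object$model_class == "free_ratio") {
    cat("  per-branch omega:\n")
    print(round(object$omega, 4))
  } else {
    for (nm in names(object$omega))
      cat(sprintf("  omega (%s) = %.4f\n", nm, object$omega[[nm]]))
  }
  cat(sprintf("  convergence: %d optimizer passes, |grad| = %.2e\n",
              object$convergence$iterations,
              object$convergence$gradient_norm))
  invisible(object)
}

#' @export
coef.branch_fit <- function(object, ...) {
  c(kappa = object$kappa, object$omega)
}

#' @export
logLik.branch_fit <- function(object, ...) {
  npar <- 1L + length(object$omega) +
    if (object$branch_lengths_estimated) nrow(object$tree$edge) else 0L
  structure(object$lnL, df = npar, nobs = object$nsites,
            class = "logLik")
}

#' Likelihood-ratio test of nested branch models
#'
#' Twice the log-likelihood difference of two nested fits on the same
#' data, compared to a chi-square upper tail. The statistic is clamped
#' at 0 (sampling/optimization can leave it marginally negative); a
#' substantially negative value signals a nesting violation and is an
#' error.
#'
#' @param null,alt `branch_fit` objects (null nested in alt), or the
#'   two log-likelihoods as numerics.
#' @param df Degrees of freedom; defaults to the difference in the
#'   number of omega parameters (1 for two-ratio vs one-ratio).
#' @param tol Tolerance for the nesting check (default 1e-3).
#' @return Object of class `lrt_result`: list with `statistic`, `df`,
#'   `p`.
#' @export
lrt <- function(null, alt, df = NULL, tol = 1e-3) {
  l0 <- if (inherits(null, "branch_fit")) null$lnL else as.numeric(null)
  l1 <- if (inherits(alt, "branch_fit")) alt$lnL else as.numeric(alt)
  if (is.null(df)) {
    if (inherits(null, "branch_fit") && inherits(alt, "branch_fit"))
      df <- length(alt$omega) - length(null$omega)
    else stop("df required when fits are given as log-likelihoods")
  }
  if (df < 1L) stop("df must be a positive integer")
  stat <- 2 * (l1 - l0)
  if (stat < -tol)
    stop("nesting violated: lnL(alt) < lnL(null) by ",
         format(-stat / 2))
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = as.integer(df),
                 p = stats::pchisq(stat, df = df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2*dlnL = %.4f, df = %d, p = %.4f\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Root-to-tip omega per tip
#'
#' For each tip, aggregates the free-ratio branch omega estimates along
#' the path from the root to that tip. The root has no stem branch, so
#' a path contains only descendant branches. The default is the
#' unweighted arithmetic mean; `weighted = TRUE` weights branches by
#' their lengths.
#'
#' @param fit A free-ratio `branch_fit` (or any fit; class omegas are
#'   expanded per branch).
#' @param weighted Weight by branch length? Default `FALSE`.
#' @return Named numeric vector, one value per tip.
#' @export
root_to_tip_omega <- function(fit, weighted = FALSE) {
  tree <- fit$tree
  om_edge <- fit_omega_edge(fit)
  if (any(is.na(om_edge))) stop("missing branch omega estimate")
  ntip <- length(tree$tip.label)
  parent_of <- stats::setNames(tree$edge[, 1L], tree$edge[, 2L])
  edge_of <- stats::setNames(seq_len(nrow(tree$edge)), tree$edge[, 2L])
  root <- ntip + 1L
  out <- vapply(seq_len(ntip), function(tip) {
    node <- tip
    oms <- numeric(0)
    lens <- numeric(0)
    while (node != root) {
      e <- edge_of[[as.character(node)]]
      oms <- c(oms, om_edge[e])
      lens <- c(lens, tree$edge.length[e])
      node <- parent_of[[as.character(node)]]
    }
    if (weighted) sum(oms * lens) / sum(lens) else mean(oms)
  }, 0)
  stats::setNames(out, tree$tip.label)
}

# per-edge omega vector of any branch_fit
fit_omega_edge <- function(fit) {
  nedge <- nrow(fit$tree$edge)
  switch(fit$model_class,
    one_ratio = rep(unname(fit$omega[1L]), nedge),
    two_ratio = ifelse(fit$foreground_edges,
                       fit$omega[["foreground"]],
                       fit$omega[["background"]]),
    free_ratio = unname(fit$omega))
}

#' Screen genes for rapid evolution on foreground branches
#'
#' For each gene, fits the one-ratio (null) and two-ratio (alternative)
#' branch models and performs the likelihood-ratio test (df = 1). A
#' gene is flagged as rapidly evolving on the foreground when p <
#' `alpha` and the foreground omega exceeds the background omega. A
#' concatenated dataset ("13PCG" when 13 genes are given) is appended
#' unless `add_concatenated = FALSE`, yielding one row per dataset.
#' A failing gene is reported as an NA row; it does not abort the
#' screen.
#'
#' @param alignments Named list of [codon_alignment()] objects.
#' @param tree Rooted `phylo`.
#' @param foreground Tip labels of the foreground clade.
#' @param include_stem Include the clade stem branch? Default `TRUE`.
#' @param alpha Significance threshold (default 0.05).
#' @param add_concatenated Append the concatenation row? Default `TRUE`.
#' @param ... Passed to [fit_branch_model()].
#' @return data.frame of class `selection_screen` with columns `gene`,
#'   `omega_background`, `omega_foreground`, `lnl_null`, `lnl_alt`,
#'   `two_dlnl`, `p`, `rapid`.
#' @export
rapid_evolution_screen <- function(alignments, tree, foreground,
                                   include_stem = TRUE, alpha = 0.05,
                                   add_concatenated = TRUE, ...) {
  if (is.null(names(alignments)))
    names(alignments) <- vapply(alignments, function(a) a$gene_label, "")
  if (add_concatenated)
    alignments <- c(alignments,
                    stats::setNames(list(concatenate(alignments)),
                                    if (length(alignments) == 13L)
                                      "13PCG" else "concat"))
  rows <- lapply(names(alignments), function(g) {
    res <- tryCatch({
      null <- fit_branch_model(alignments[[g]], tree, "one_ratio", ...)
      alt <- fit_branch_model(alignments[[g]], tree, "two_ratio",
                              foreground = foreground,
                              include_stem = include_stem,
                              null_fit = null, ...)
      lr <- lrt(null, alt, df = 1L)
      data.frame(gene = g,
                 omega_background = alt$omega[["background"]],
                 omega_foreground = alt$omega[["foreground"]],
                 lnl_null = null$lnL, lnl_alt = alt$lnL,
                 two_dlnl = lr$statistic, p = lr$p,
                 rapid = lr$p < alpha &&
                   alt$omega[["foreground"]] > alt$omega[["background"]],
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("screen failed for ", g, ": ", conditionMessage(e))
      data.frame(gene = g, omega_background = NA_real_,
                 omega_foreground = NA_real_, lnl_null = NA_real_,
                 lnl_alt = NA_real_, two_dlnl = NA_real_, p = NA_real_,
                 rapid = NA, stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("selection_screen", "data.frame")
  out
}

#' @export
print.selection_screen <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
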