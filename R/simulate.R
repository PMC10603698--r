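#' Simulation configuration for codon-evolution experiments
#'
#' Bundles everything a simulation needs — tree, branch-specific dN/dS
#' assignment, kappa, codon frequencies, alignment size, gene list and
#' seed — so a run is fully determined by its config.
#'
#' @param tree Rooted `phylo` with branch lengths in expected
#'   substitutions per codon.
#' @param omega Scalar (all branches), a named vector
#'   `c(background=, foreground=)` used with `foreground` tips, or a
#'   per-edge vector over `tree$edge` rows.
#' @param kappa Transition/transversion ratio.
#' @param pi `"uniform"`, a numeric vector of 60 frequencies, or a
#'   [codon_alignment()] whose F3x4 frequencies are used.
#' @param codons Codon columns per gene.
#' @param genes Character vector of gene labels (one alignment each).
#' @param foreground Tip labels of the foreground clade (when `omega`
#'   is a background/foreground pair).
#' @param include_stem Include the foreground clade's stem branch?
#' @param seed Integer seed; fully determines the output.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(tree, omega = 0.2, kappa = 4,
                              pi = "uniform", codons = 500L,
                              genes = "gene1", foreground = NULL,
                              include_stem = TRUE, seed = 1L) {
  if (codons < 1L) stop("codons must be >= 1")
  if (kappa <= 0 || any(omega <= 0)) stop("kappa and omega must be positive")
  if (!length(genes)) stop("gene list must be non-empty")
  structure(list(tree = tree, omega = omega, kappa = kappa, pi = pi,
                 codons = as.integer(codons), genes = genes,
                 foreground = foreground, include_stem = include_stem,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

resolve_sim_pi <- function(pi) {
  if (inherits(pi, "codon_alignment")) return(f3x4_frequencies(pi))
  if (is.character(pi) && identical(pi, "uniform"))
    return(uniform_codon_frequencies())
  check_pi(pi)
  pi
}

resolve_sim_omega <- function(tree, omega, foreground, include_stem) {
  nedge <- nrow(tree$edge)
  if (length(omega) == 1L) return(rep(unname(omega), nedge))
  if (!is.null(names(omega)) &&
      all(c("background", "foreground") %in% names(omega))) {
    if (is.null(foreground))
      stop("background/foreground omega requires foreground tips")
    fg <- mark_foreground(tree, foreground, include_stem = include_stem)
    return(ifelse(fg, omega[["foreground"]], omega[["background"]]))
  }
  if (length(omega) == nedge) return(unname(omega))
  stop("omega must be scalar, background/foreground pair, or per-edge")
}

#' Simulate a codon alignment along a tree
#'
#' Evolves codon sequences under the Goldman–Yang-style model with
#' branch-specific dN/dS: the root sequence is drawn from the
#' stationary frequencies and each branch applies the exact
#' matrix-exponential transition kernel of its (kappa, omega) rate
#' matrix — equivalent in distribution to event-by-event simulation.
#' The returned alignment carries the complete ground truth as
#' attribute `"truth"`.
#'
#' @param cfg A [simulation_config()]; alternatively pass the fields
#'   via `...` to build one (see [simulation_config()]).
#' @param ... Fields forwarded to [simulation_config()] when `cfg` is a
#'   `phylo` tree.
#' @return A [codon_alignment()] with attribute `truth` (list with the
#'   per-edge omega, kappa, pi, seed and tree used).
#' @export
simulate_codon_alignment <- function(cfg, ...) {
  if (inherits(cfg, "phylo")) cfg <- simulation_config(cfg, ...)
  stopifnot(inherits(cfg, "simulation_config"))
  tree <- cfg$tree
  pi <- resolve_sim_pi(cfg$pi)
  omega_edge <- resolve_sim_omega(tree, cfg$omega, cfg$foreground,
                                  cfg$include_stem)
  set.seed(cfg$seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  npat <- cfg$codons
  egs <- lapply(unique(omega_edge),
                function(om) eigen_gy94(cfg$kappa, om, pi))
  names(egs) <- as.character(unique(omega_edge))

  states <- matrix(NA_integer_, nnode, npat)
  root <- ntip + 1L
  states[root, ] <- sample.int(60L, npat, replace = TRUE, prob = pi)
  # preorder: parents before children
  tr_edges <- ape::reorder.phylo(tree, "postorder")$edge
  ord <- rev(seq_len(nrow(tr_edges)))
  key0 <- paste(tree$edge[, 1L], tree$edge[, 2L])
  for (k in ord) {
    par <- tr_edges[k, 1L]
    chd <- tr_edges[k, 2L]
    e0 <- match(paste(par, chd), key0)
    p <- transition_prob(egs[[as.character(omega_edge[e0])]],
                         tree$edge.length[e0])
    parent_states <- states[par, ]
    child <- integer(npat)
    for (s in unique(parent_states)) {
      idx <- which(parent_states == s)
      child[idx] <- sample.int(60L, length(idx), replace = TRUE,
                               prob = p[s, ])
    }
    states[chd, ] <- child
  }
  tips <- states[seq_len(ntip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  aln <- codon_alignment(tips, gene_label = cfg$genes[1L])
  attr(aln, "truth") <- list(kappa = cfg$kappa, omega_edge = omega_edge,
                             pi = pi, seed = cfg$seed, tree = tree)
  aln
}

#' Simulate a set of gene alignments from one config
#'
#' One alignment per entry of the config's gene list, with per-gene
#' seeds derived deterministically from the config seed. Per-gene
#' omega overrides allow planting elevated foreground rates in chosen
#' genes.
#'
#' @param cfg A [simulation_config()].
#' @param omega_overrides Optional named list: gene -> omega spec
#'   replacing the config's for that gene.
#' @return Named list of [codon_alignment()] objects.
#' @export
simulate_gene_set <- function(cfg, omega_overrides = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  out <- lapply(seq_along(cfg$genes), function(i) {
    g <- cfg$genes[i]
    cfg_i <- cfg
    cfg_i$genes <- g
    cfg_i$seed <- cfg$seed + i
    if (!is.null(omega_overrides) && g %in% names(omega_overrides))
      cfg_i$omega <- omega_overrides[[g]]
    simulate_codon_alignment(cfg_i)
  })
  stats::setNames(out, cfg$genes)
}

#' Simulate alignments from a fitted branch model
#'
#' Draws new codon alignments from the generating process implied by a
#' [fit_branch_model()] fit (its tree, kappa, per-branch omega and
#' codon frequencies).
#'
#' @param object A `branch_fit`.
#' @param nsim Number of alignments.
#' @param seed Integer seed.
#' @param codons Codon columns per alignment (default: the fitted
#'   alignment's size).
#' @param ... Unused.
#' @return List of [codon_alignment()] objects (length `nsim`).
#' @export
simulate.branch_fit <- function(object, nsim = 1, seed = 1L,
                                codons = object$nsites, ...) {
  lapply(seq_len(nsim), function(i) {
    cfg <- simulation_config(object$tree,
                             omega = fit_omega_edge(object),
                             kappa = object$kappa, pi = object$pi,
                             codons = codons,
                             genes = object$gene_label,
                             seed = seed + i - 1L)
    simulate_codon_alignment(cfg)
  })
}

#' Write / read a simulation config as JSON
#'
#' The tree is serialized as Newick; everything else as plain JSON, so
#' a config (and with it the simulation truth) round-trips exactly.
#'
#' @param cfg A [simulation_config()].
#' @param path File path.
#' @return `write_simulation_config()`: the path, invisibly;
#'   `read_simulation_config()`: the config.
#' @export
write_simulation_config <- function(cfg, path) {
  x <- cfg
  x$tree <- ape::write.tree(cfg$tree)
  if (inherits(x$pi, "codon_alignment"))
    stop("serialize configs with resolved numeric pi, not an alignment")
  # JSON arrays drop names; keep named omega vectors as objects
  if (!is.null(names(x$omega))) x$omega <- as.list(x$omega)
  writeLines(jsonlite::toJSON(unclass(x), auto_unbox = TRUE,
                              digits = NA), path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- jsonlite::fromJSON(paste(readLines(path), collapse = ""))
  x$tree <- ape::read.tree(text = x$tree)
  if (!is.null(names(x$omega))) x$omega <- unlist(x$omega)
  simulation_config(tree = x$tree, omega = x$omega, kappa = x$kappa,
                    pi = if (is.character(x$pi)) x$pi else unlist(x$pi),
                    codons = x$codons, genes = x$genes,
                    foreground = x$foreground,
                    include_stem = x$include_stem, seed = x$seed)
}

#' Toy annotation with analytically known statistics
#'
#' Builds a consistent circular annotation from a compact layout —
#' per-gene lengths, signed spacer to the previous gene (negative =
#' overlap), strand, category and codons — tiling genes from position 1
#' and closing the circle with a control region. The expected
#' structural statistics (spacers, overlap totals, codon tallies,
#' strand partition, genome length) are computed analytically from the
#' layout and returned alongside, so annotation-level code can be
#' checked against them.
#'
#' @param layout data.frame with columns `gene`, `length`, `spacer`
#'   (ignored for the first gene), `strand`, `category`, `start_codon`,
#'   `stop_codon`.
#' @param control_length Control-region length appended after the last
#'   gene (default 500).
#' @param taxon Species label.
#' @return List with `annotation` (a [mito_annotation()]) and
#'   `expected` (list of analytically derived statistics).
#' @export
make_toy_annotation <- function(layout, control_length = 500L,
                                taxon = "toy") {
  need <- c("gene", "length", "spacer", "strand", "category",
            "start_codon", "stop_codon")
  miss <- setdiff(need, names(layout))
  if (length(miss))
    stop("layout lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(layout)
  if (n == 0L) stop("empty layout")
  if (any(layout$length < 1L)) stop("inconsistent layout: gene length < 1")
  start <- integer(n); end <- integer(n)
  start[1L] <- 1L
  end[1L] <- layout$length[1L]
  for (i in seq_len(n)[-1L]) {
    start[i] <- end[i - 1L] + layout$spacer[i] + 1L
    if (start[i] < 1L) stop("inconsistent layout: gene ", layout$gene[i],
                            " starts before position 1")
    end[i] <- start[i] + layout$length[i] - 1L
  }
  if (is.unsorted(start))
    stop("inconsistent layout: gene starts not increasing")
  genome_length <- end[n] + as.integer(control_length)
  genes <- data.frame(gene = layout$gene, start = start, end = end,
                      strand = layout$strand,
                      category = layout$category,
                      start_codon = layout$start_codon,
                      stop_codon = layout$stop_codon,
                      stringsAsFactors = FALSE)
  if (control_length > 0L)
    genes <- rbind(genes, data.frame(
      gene = "D-loop", start = end[n] + 1L, end = genome_length,
      strand = "+", category = "control", start_codon = NA_character_,
      stop_codon = NA_character_, stringsAsFactors = FALSE))
  ann <- mito_annotation(genes, genome_length, taxon = taxon)

  sp <- layout$spacer[-1L]
  neg <- which(sp < 0)
  pcg <- layout$category == "PCG"
  expected <- list(
    spacers = sp,
    total_overlap = sum(-sp[neg]),
    longest_overlap = if (length(neg)) max(-sp[neg]) else 0L,
    longest_pair = if (length(neg)) {
      k <- neg[which.max(-sp[neg])]
      paste(layout$gene[k], layout$gene[k + 1L], sep = "|")
    } else NA_character_,
    start_tally = table(layout$start_codon[pcg]),
    stop_tally = table(layout$stop_codon[pcg]),
    heavy = sum(layout$strand == "+"),
    light = sum(layout$strand == "-"),
    genome_length = genome_length,
    control_length = as.integer(control_length))
  list(annotation = ann, expected = expected)
}

#' Fixture tree of the 21-species comparative study
#'
#' A hard-coded, rooted, fully bifurcating 21-taxon Mustelidae tree:
#' the nine otter species (subfamily Lutrinae) form a monophyletic
#' clade with *Pteronura brasiliensis* basal, *Lontra canadensis* next,
#' and *Lutra lutra* + *Lutra sumatrana* sisters; the ten *Mustela*
#' species form the sister clade; *Vormela peregusna* and *Galictis
#' vittata* are the outgroups. Branch lengths are arbitrary positive
#' values (the published source prints none); the otter tips are
#' attached as attribute `"foreground"`.
#'
#' @param branch_length Length assigned to every edge (default 0.05
#'   expected substitutions per codon).
#' @return A rooted `phylo` with 21 tips.
#' @export
make_study_tree <- function(branch_length = 0.05) {
  otters <- paste0(
    "(Pteronura_brasiliensis,(Lontra_canadensis,(Enhydra_lutris,",
    "(Hydrictis_maculicollis,((Lutra_lutra,Lutra_sumatrana),",
    "((Lutrogale_perspicillata,Aonyx_cinerea),Aonyx_capensis))))))")
  mustela <- paste0(
    "(Mustela_frenata,(Mustela_eversmannii,(Mustela_itatsi,",
    "(Mustela_nigripes,(Mustela_putorius,(Mustela_erminea,",
    "(Mustela_kathiah,(Mustela_nivalis,(Mustela_sibirica,",
    "Mustela_altaica)))))))))")
  txt <- paste0("((Vormela_peregusna,Galictis_vittata),(", otters, ",",
                mustela, "));")
  tree <- ape::read.tree(text = txt)
  tree$edge.length <- rep(branch_length, nrow(tree$edge))
  attr(tree, "foreground") <- c(
    "Pteronura_brasiliensis", "Lontra_canadensis", "Enhydra_lutris",
    "Hydrictis_maculicollis", "Lutra_lutra", "Lutra_sumatrana",
    "Lutrogale_perspicillata", "Aonyx_cinerea", "Aonyx_capensis")
  tree
}
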