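---
title: "Models and methods behind mitosel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitosel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosel)
library(ape)
```

## What the package computes

`mitosel` analyses the evolution of mitochondrial protein-coding genes
(PCGs) across a clade whose members occupy contrasting ecological
niches — the motivating system is the Mustelidae, where the otters
(Lutrinae) are semi-aquatic and the weasels are terrestrial. It covers
four layers of analysis:

1. **Structural statistics** of an annotated circular mitogenome:
   gene sizes, intergenic spacers and overlaps, start/stop codon
   tallies, heavy/light strand partition, AT/GC skew and relative
   synonymous codon usage (RSCU).
2. **Selection-pressure inference** with branch codon models:
   maximum-likelihood estimates of dN/dS (ω) under one-ratio,
   two-ratio (background vs foreground clade) and free-ratio (one ω
   per branch) parameterizations, with likelihood-ratio tests between
   nested models.
3. **Root-to-tip ω aggregation** from the free-ratio model, and
   Mann–Whitney–Wilcoxon comparison of those per-species values
   between habitat groups.
4. **Phylogenetic independent contrasts (PIC)** regressing log10
   root-to-tip ω on a binary habitat coding, removing phylogenetic
   non-independence.

A codon-evolution simulator with branch-specific ω generates every
input the pipeline consumes, with known ground truth, so each layer is
testable without any sequence downloads.

## The codon substitution model

The substitution process follows the Goldman–Yang codon model on the
60 sense codons of the vertebrate mitochondrial genetic code
(translation table 2; TAA, TAG, AGA and AGG are stops). The
instantaneous rate from codon $i$ to codon $j$ is

$$ q_{ij} = \begin{cases}
0 & \text{more than one position differs} \\
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\omega \kappa \pi_j & \text{nonsynonymous transition,}
\end{cases} $$

where $\kappa$ is the transition/transversion rate ratio, $\omega =
dN/dS$, and $\pi$ the stationary codon frequencies. The matrix is
rescaled so that the expected substitution rate at stationarity is 1:
branch lengths are expected substitutions **per codon**. The model is
time-reversible ($\pi_i q_{ij} = \pi_j q_{ji}$), which the test suite
asserts, and which makes the likelihood invariant to re-rooting.

Codon frequencies default to **F3x4** — products of empirical
nucleotide frequencies at the three codon positions, restricted and
renormalized to the sense codons — with a pseudocount of $10^{-6}$ so
every frequency stays positive. Uniform frequencies are available and
are used throughout the simulation studies so that ω recovery is not
confounded with frequency estimation.

Likelihood computation is Felsenstein pruning over codon states with
site-pattern compression and per-node column rescaling (log-scale
bookkeeping) against underflow. Transition matrices $e^{Qt}$ come from
the spectral decomposition of the symmetrized rate matrix
$D_\pi^{1/2} Q D_\pi^{-1/2}$, which is numerically stable and lets one
decomposition serve every branch length; negative entries from
round-off (order $10^{-16}$) are clipped to zero.

## Fitting branch models

`fit_branch_model()` maximizes the likelihood over log-transformed
parameters with bounded quasi-Newton (L-BFGS-B), bounds
$\kappa \in [0.05, 100]$, $\omega \in [10^{-4}, 50]$, branch lengths
$\in [10^{-8}, 10]$.

* **One-ratio** (`model = "one_ratio"`): a single ω. Branch lengths
  are co-estimated by alternating a joint $(\kappa, \omega)$ pass with
  Brent line searches per branch. Each branch search uses an *edge
  profile*: the flow of conditional likelihoods from the rest of the
  tree is folded into one matrix per edge, so evaluating a candidate
  length costs a single matrix product rather than a full pruning
  pass. Sweeps stop when the log-likelihood improves by less than
  `tol` (default $10^{-3}$).
* **Two-ratio** (`model = "two_ratio"`): background and foreground ω,
  the foreground being a clade named by its tips; by default the
  clade's stem branch and all its internal branches are foreground
  (`include_stem = TRUE` — whether the stem belongs to the foreground
  is genuinely ambiguous in comparative practice, so it is exposed as
  an option).
* **Free-ratio** (`model = "free_ratio"`): one ω per branch,
  initialized from the one-ratio fit and refined branch-wise (again
  via edge profiles) with a κ refresh after each round; two rounds by
  default. Per-branch ω on small trees is noisy — this is inherent to
  the model, not the optimizer — which is why downstream summaries
  aggregate over root-to-tip paths.

Branch lengths are **co-estimated once under the one-ratio model and
then held fixed** for the two-ratio and free-ratio fits (the one-ratio
fit is passed as `null_fit`, or run internally). This deviates from
re-estimating lengths under every model; it makes a 14-dataset screen
tractable at desk scale, and because the null model's lengths are used
for both members of each nested pair, the likelihood-ratio test
remains internally consistent (the alternative always contains the
null). The cost is a slightly conservative test, which the null
calibration below quantifies empirically.

Multi-start policy: candidate ω starts $\{0.1, 0.5, 1.5\}$ are
screened by their objective value and the best is optimized fully; the
two-ratio fit additionally always optimizes from the null fit's
parameters, which guarantees $\ln L_{\text{alt}} \ge
\ln L_{\text{null}}$. An optional seed-controlled jitter perturbs the
starts for robustness studies.

The LRT statistic $2\Delta\ln L$ is clamped at zero (a marginally
negative value can arise from finite optimizer tolerance; a
substantially negative one raises an error) and referred to the
chi-square upper tail, df = 1 for two-ratio vs one-ratio.

## Root-to-tip ω and group comparison

For each tip, the root-to-tip ω is the **unweighted arithmetic mean**
of the free-ratio ω estimates over the branches on the path from the
root to that tip; the root itself has no stem branch, so paths contain
only descendant branches. Branch-length weighting is available
(`weighted = TRUE`) but is not the default — the plain average is the
conventional summary in comparative mitogenomics reports.

Habitat groups (semi-aquatic = 1, terrestrial = 0) are compared per
gene with the Mann–Whitney–Wilcoxon test: exact enumeration when the
smaller sample has ≤ 10 observations and there are no ties, otherwise
the normal approximation with tie and continuity corrections. Tests
are two-sided. No multiple-testing correction is applied across the
14 datasets in the headline output, matching common practice in this
literature; a Benjamini–Hochberg column (`p_bh`) is appended as
clearly supplementary output.

## Phylogenetic independent contrasts

`pic_contrasts()` implements the Felsenstein post-order recursion:
each internal node is replaced by the branch-length-weighted average
of its children, the standardized contrast $(x_i - x_j)/\sqrt{b_i +
b_j}$ is emitted, and the parent branch is lengthened by $b_i b_j /
(b_i + b_j)$. Zero or negative branch lengths are floored at
$10^{-8}$ with a warning; polytomies are resolved arbitrarily into
zero-length bifurcations (reported). The implementation is checked
against an independent recursive transcription and against
`ape::pic()` in the test suite.

The habitat test regresses the contrasts of log10 root-to-tip ω on the
contrasts of the 0/1 habitat code **through the origin**, as PIC
theory requires; df = (number of contrasts − 1) and the p-value is
two-sided. Two caveats are deliberate design choices rather than
oversights: the binary habitat indicator is treated as a continuous
trait (standard in this literature, statistically awkward —
threshold models are out of scope), and ω values of 0 are floored at
$10^{-6}$ before the log transform, with a warning.

## The simulator and what it does (not) emulate

`simulate_codon_alignment()` draws the root sequence from $\pi$ and
evolves it along each branch with the exact matrix-exponential
transition kernel of that branch's $(\kappa, \omega)$ matrix. This is
equivalent in distribution to event-by-event (Gillespie) simulation
but much faster at desk scale. A `simulation_config` — tree, ω
assignment (scalar, background/foreground, or per-edge), κ, π source,
codons, gene list, seed — fully determines the output, and round-trips
through a JSON writer so simulation truth is archivable.

Simulated data are gap-free, indel-free, recombination-free and
rate-homogeneous across sites within a branch class. Real
mitochondrial alignments violate several of these (indels near gene
boundaries, among-site rate variation, saturation at deep
divergences), so passing the calibration studies demonstrates the
*inference machinery* is correct and well calibrated, not that the
model captures every feature of real mitogenomes.

Default simulation conditions, chosen once: $\kappa = 4$ (a typical
mammalian mitochondrial transition/transversion ratio), uniform π
(isolating ω recovery from frequency estimation), and balanced
fixture trees with branch lengths of 0.2 substitutions/codon.

## Validation studies and their problem sizes

The acceptance-level checks in `tests/testthat/test-acceptance.R` use
deliberately chosen desk-scale problem sizes:

* Pruning vs exhaustive enumeration: 4 taxa, 20 codons, agreement to
  $10^{-8}$ (the enumeration sums all $60^3$ internal-state
  assignments per site).
* ω recovery: 6-taxon tree, 2,000 codons, 20 replicates per
  generating ω ∈ {0.05, 0.2, 1.0}; the median relative error must stay
  below 15%.
* Null calibration: 4-taxon tree, 500 codons, 200 replicates
  simulated under the one-ratio null and fitted with both models; the
  empirical rate of $2\Delta\ln L > 3.84$ must lie in [0.01, 0.10].
* Power: a 2× foreground elevation (0.2 → 0.4) on a two-tip clade
  plus stem, 2,000 codons, 50 replicates; detection (p < 0.05 with the
  correct direction) must reach 80%.
* PIC power: the 21-taxon fixture tree, a 2× (0.30 in log10 units)
  habitat effect on ω with Brownian noise of variance 0.05 per unit
  branch length — a within-group spread of roughly ±40% in ω, a
  realistic interspecific scatter; detection must reach 80% over 100
  replicates.

Tree sizes in these studies are the package's own choice; generating
parameters, replicate counts and alignment lengths are part of the
study design and are never tuned against observed outcomes.

## Annotation conventions and numerical choices

* Coordinates are 1-based inclusive on the heavy strand, the
  convention of published mitogenome annotation tables; light-strand
  genes keep heavy-strand coordinates.
* A gene with start > end wraps across the origin of the circular
  genome; its length is `genome_length - start + 1 + end`.
* If no control region is listed, it is inferred as the largest
  unannotated gap on the circle and the inference is logged.
* Intergenic spacers are `start[i+1] - end[i] - 1` over genes ordered
  by start; negative values are overlaps. Ties for the longest
  overlap break by genome order.
* Ambiguity codes are excluded from composition counts and reported
  separately, keeping skews well defined; percentages are printed to
  1 decimal and skews to 3, full precision retained internally. When
  verifying skews from a *printed* percentage table, the formula is
  applied to the table's percentages as given — the table is treated
  as the authoritative input even where accompanying text rounds
  differently.
* RSCU families follow the vertebrate mitochondrial code with leucine
  and serine split by codon box (Leu1 = CTN, Leu2 = TTR; Ser1 = TCN,
  Ser2 = AGY), the layout of standard RSCU bar charts; stop codons are
  excluded and AGR does not exist as serine here.
* Alignment preparation is complete deletion: a trailing codon column
  containing a stop or a 3'-partial codon is stripped, then every
  column containing a gap or ambiguity in any row is dropped and the
  count logged. Any in-frame stop surviving preparation is an error
  naming taxon and site. Incomplete stops (TA-, T--), completed by
  polyadenylation in vivo, are trimmed, never padded.

## A worked example

```{r example, eval = FALSE}
library(mitosel)
library(ape)

tree <- read.tree(text =
  "(((A:0.15,B:0.15):0.15,C:0.2):0.1,(D:0.2,E:0.2):0.1);")
cfg <- simulation_config(tree,
                         omega = c(background = 0.2, foreground = 0.5),
                         foreground = c("A", "B"),
                         kappa = 4, codons = 300,
                         genes = c("gA", "gB"), seed = 7)
alns <- simulate_gene_set(cfg)
habitat <- setNames(c(1L, 1L, 0L, 0L, 0L), tree$tip.label)

rc <- run_config(alignments = alns, tree = tree, habitat = habitat,
                 out_dir = "results", seed = 7)
res <- run_pipeline(rc, frequencies = "uniform")
res$screen
```

## Known limitations

* No site models or branch-site models (all sites share one ω within
  a branch class), no codon-frequency models beyond F3x4/equal, no
  dS-saturation diagnostics.
* Free-ratio fits use coordinate-wise refinement rather than a full
  joint Newton pass; with ~40 parameters on a 21-taxon tree the
  per-branch estimates are stable but not guaranteed to be the global
  joint optimum.
* Alignment (e.g. MUSCLE/MAFFT), annotation transfer, tree inference
  and model selection are out of scope: the tree and the aligned
  sequences are inputs.
* The binary-habitat PIC is a pragmatic, convention-following test;
  for serious inference on binary traits a threshold or generalized
  least squares model would be preferable.
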