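---
title: "Modeling the evolution of gene expression presence/absence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the evolution of gene expression presence/absence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprevo)
```

## The problem

Cross-species comparisons of transcript abundance are dominated by batch
effects: tissues are collected at different times, by different labs, with
different protocols. `exprevo` follows the strategy of discarding the
quantitative scale altogether and treating gene expression as a heritable
binary character — a gene is either expressed in a tissue or it is not —
so that standard phylogenetic machinery for discrete characters can
reconstruct ancestral transcriptomes and date expression gains and losses
on a species tree. The motivating application is the evolution of the
pregnant endometrium across vertebrates, where genes recruited into
endometrial expression on particular lineages are then interrogated in
single-cell data from the maternal–fetal interface, but every stage is
generic.

## Binarization and the TPM cutoff

Log-scale transcript abundances in a bulk RNA-Seq sample are bimodal: a
main, roughly Gaussian mass of actively transcribed genes and a
lower-abundance shoulder of transcriptionally silent ones. `exprevo`
models positive TPM values on the log2 scale as a two-component Gaussian
mixture fitted by EM (`fit_expression_mixture()`); the posterior
responsibility of the higher-mean component (`expression_probability()`)
is an explicit probability-of-expression curve. Exact zeros are excluded
from the fit and reported as a point mass — a zero is an observed absence
of reads, not a draw from the log-scale mixture. Components are ordered by
ascending mean so "low" and "high" are deterministic; the EM is restarted
five times (k-means and quantile initializations) and the best
log-likelihood kept, with a nondecreasing log-likelihood trace asserted at
every iteration.

`binarize()` codes a gene as expressed (1) when TPM ≥ 2.0, not expressed
(0) below, and unknown (`?`) when a gene has no data in any of a taxon's
samples. The cutoff default of 2.0 sits where the two mixture components
cross for typical bulk data; it is a flag, not a constant, and the
monotonicity property (raising the cutoff can only turn 1s into 0s) is
tested. When a taxon has replicate samples they are collapsed before
thresholding; the default rule is the mean TPM across replicates, because
a single-number summary is less sensitive to the threshold than voting
rules, but `any` and `all` are selectable.

## The substitution model

The evolutionary model is the general time-reversible Markov process on
two states with stationary frequencies $(\pi_0, \pi_1)$ estimated by
maximum likelihood, combined with free-rate among-gene rate heterogeneity
over $K = 4$ categories: category $k$ has weight $w_k$ and rate
multiplier $r_k$, constrained to mean rate $\sum_k w_k r_k = 1$ so branch
lengths stay in expected changes per gene. The generator is normalized
with $\mu = 1/(2\pi_0\pi_1)$, giving the closed-form transition matrix

$$P_{00}(t) = \pi_0 + \pi_1 e^{-\mu t r}, \quad
  P_{01}(t) = \pi_1 (1 - e^{-\mu t r}),$$

and symmetrically for the second row. Detailed balance and the
Chapman–Kolmogorov property are asserted against a matrix-exponential
oracle in the tests.

Per-gene likelihoods come from Felsenstein's pruning algorithm over the
rooted species tree, with unknown tips contributing the uninformative
partial vector $(1, 1)$ and the root weighted by the stationary
frequencies. The model is reversible, so the likelihood does not depend
on the root position; the rooted tree is nevertheless retained because
the polarity of gains versus losses requires it. Conditional likelihood
vectors are kept on the natural scale with per-node rescaling and
accumulated log scalers; because two-state partials are bounded by 1,
rescaling triggers only near underflow, which keeps the inner loops (in
C++, as in other phylogenetics packages) cheap while remaining exact.

## Fitting

The tree topology is fixed — only branch lengths and model parameters are
optimized. `optimize_parameters()` cycles three coordinate blocks:
(a) the free-rate category weights, maximized exactly by iterating the
mixture EM update at fixed category likelihoods (the mean-rate-1
constraint is then restored by rescaling rates and branch lengths
jointly, which leaves every branch-length-times-rate product — hence the
likelihood — unchanged); (b) bounded quasi-Newton (L-BFGS-B) over the
logit of $\pi_1$ and the log rate multipliers, together with two free
branch-length scales (internal and terminal edges) that absorb the
strongly correlated tree-scale-versus-rates directions; and (c) Brent
line searches on each branch length over $[10^{-8}, 10]$, on profiles
built from cached inside/outside partials that are refreshed whenever
accumulated length movement makes them stale, with every candidate set
of lengths re-scored exactly before acceptance. The alternation stops
when a full cycle improves the total log-likelihood by less than
$10^{-6}$, or after `max_rounds` cycles (default 15): parameter
estimates stabilize within the first handful of cycles and the tail is
branch-length micro-refinement, so the cap bounds runtime on large
matrices without moving any estimate at reporting precision. Identical
gene columns are collapsed to patterns with multiplicities before any
likelihood work.

Free-rate categories are canonicalized by ascending rate; two categories
converging to the same rate is reported, not an error. Degenerate inputs
(no variable characters) yield a warning and branch lengths at the lower
bound. The model family is fixed at the four-category free-rate form with
ML frequencies — there is no model search — but `n_categories = 1` gives
the homogeneous-rate special case, which the tests use to confirm the
mixture collapses correctly.

## Ancestral reconstruction and event tracing

`marginal_posteriors()` computes, for every internal node and gene, the
posterior probability of the expressed state (BPP) under the plug-in ML
parameters — empirical Bayes, with no integration over parameter
uncertainty. Posteriors marginalize over rate categories with per-gene
empirical weights $w_k L_k$, and all nodes are obtained in one
inside–outside pass per gene rather than by clamping each node
separately; the two routes are proven equal on small trees by an
exhaustive enumeration oracle in the tests.

Calls are made by `map_states()` at an inclusive threshold, 0.80 by
default. `trace_events()` emits a gain when a branch's parent is
confidently 0 and its child confidently 1, and a loss for the reverse;
requiring *both* endpoints to pass the threshold is the strictest
consistent reading of a single-threshold rule and prevents phantom events
through ambiguous nodes. A tip coded `?` blocks event calling on its own
pendant branch only. Per-branch rates divide gains + losses by the number
of genes scoreable on that branch, which is the quantity a tree drawn in
units of expression changes per gene displays.

## Ordination and grouping

Extant transcriptomes (binary) and ancestral ones (MAP states at 0.5,
ties to 1 — deliberately independent of the stricter event threshold, so
ancestral points are not riddled with unknowns) are compared with the
Hamming proportion over pairwise-complete genes by default; Jaccard is
offered where presence/absence asymmetry is preferred. The distance
matrix is embedded by classical multidimensional scaling
(double-centered squared distances, eigendecomposition; negative axes
dropped) in four dimensions, and grouped by K-means for K = 2–6 with 50
seeded restarts per K. The within-cluster sum of squares and mean
silhouette width are reported per K; the choice of K is left to
inspection rather than automated, since cluster counts in comparative
data are an interpretive decision.

## Single-cell enrichment

Cell-level quality control keeps cells with 1000–5000 detected genes
(count ≥ 1, bounds inclusive) and at most 5% of counts on mitochondrial
genes (identified by the `MT-` name prefix by default). Counts are
normalized per cell to 10,000, log-transformed (`ln(1 + x)`), and
averaged within cell types into a pseudobulk matrix. For a recruited gene
set, each cell type's Observed is the expressed fraction among recruited
genes and Expected the expressed fraction among all other pseudobulk
genes ("expressed" meaning a pseudobulk mean above 0 by default — a
pseudobulk mean is exactly zero precisely when no cell expresses the
gene); the enrichment ratio is Observed/Expected and significance comes
from a two-sided Fisher exact test with Bonferroni correction across cell
types (Benjamini–Hochberg selectable). Over-representation analysis
against GMT collections uses the hypergeometric upper tail within the
supplied universe and flags terms at FDR ≤ 0.10.

## The synthetic-data generators

Every input the pipeline consumes can be generated with recorded ground
truth: `simulate_binary_evolution()` runs the inference model forward
(per-gene category from the weights, root state from the stationary
frequencies, closed-form transitions down each branch) and records all
node states and endpoint-difference events; `simulate_tpm_matrix()` draws
log2 TPM from a two-component mixture whose defaults straddle the TPM = 2
cutoff (component means near 0.11 and 19 TPM) with a configurable
point mass at zero; `simulate_single_cell()` draws an on/off state per
(gene, cell type) with a planted recruitment effect and Poisson counts
for expressed genes; `inject_missingness()` masks entries per taxon. One
master seed fans out to per-stage child seeds (`split_seed()`), so stages
are independently reproducible and identical seeds give byte-identical
outputs.

What the generators deliberately do not emulate: compositional coupling
between genes in TPM space, phylogenetic correlation of missingness,
overdispersion and dropout structure of real single-cell counts (a
Poisson suffices for a presence/absence statistic; a negative-binomial
flag would be the natural extension), and any form of orthology error.
Passing tests therefore demonstrate correctness of the inference
machinery under its own assumptions, and calibration under the simulated
conditions — not robustness to everything real data can do.

## Problem sizes and numerical choices

The bundled studies use a 20-tip tree with 10,000 characters for
parameter recovery and posterior calibration, 2,000 genes for the
end-to-end pipeline fixture, and a few hundred to a few thousand genes
elsewhere; these sizes make every property measurable with comfortable
statistical resolution while keeping a full run on a laptop-class single
core in minutes. Branch lengths are bounded to $[10^{-8}, 10]$ (a branch
at the upper bound is effectively saturated for a mean-rate-1 binary
character). EM convergence uses an absolute log-likelihood change of
$10^{-8}$, the fit alternation $10^{-6}$. Ties: `map_states()` treats
BPP exactly at the threshold as called (inclusive ≥), and ordination MAP
states send BPP = 0.5 to state 1, both documented and tested.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
tree <- read_newick("((((human:0.1,macaque:0.1)catarrhine:0.2,mouse:0.3)euarchontoglires:0.1,cow:0.35)eutheria:0.15,opossum:0.5)theria;")
params <- model_params(pi1 = 0.35, weights = c(.4, .3, .2, .1),
                       rates = c(.25, .7, 1.4, 2.8))
sim <- simulate_binary_evolution(tree, params, 2000L, seed = 42L)

fit <- optimize_parameters(tree, sim$states, seed = 1L)
bpp <- marginal_posteriors(fit$tree, fit$params, sim$states)
events <- trace_events(fit$tree, bpp, sim$states, bpp_threshold = 0.80)
gained <- lineage_gene_sets(events, "catarrhine->human")$gained
head(branch_rates(events))
```

## Known limitations

* The two-state model ignores expression level once a gene is called
  expressed; genes hovering near the cutoff can flip state for technical
  reasons, which the posterior threshold mitigates but cannot remove.
* Per-branch gain/loss rates are thresholded-event counts. On branches
  long enough to approach saturation (tens of percent of genes changing),
  endpoint posteriors lose confidence and events are suppressed, which
  distorts the ranking of branch rates; the estimator is faithful in the
  empirically observed regime of a few percent of genes changing per
  branch, and the rate-tracking test runs in that regime.
* Gains and losses are endpoint comparisons; multiple hits within one
  branch are invisible, and no stochastic mapping is attempted.
* The enrichment test conditions on the pseudobulk universe; genes absent
  from the single-cell annotation are silently outside the test.
* Fixed topology: uncertainty in the species tree is not propagated.
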