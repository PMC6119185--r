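---
title: "Methods: dynamic modeling of transcriptional regulatory networks from time-course expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic modeling of transcriptional regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senescnet)
```

# Overview

`senescnet` implements a network-science pipeline for ordered time-course
expression data, of the kind collected across the onset of leaf senescence:

1. per-time-point differential expression and *emergent-gene* dating
   (`call_degs()`, `find_emergent()`);
2. weighted co-expression network construction with soft thresholding,
   topological overlap, module detection and eigengenes
   (`correlation_similarity()`, `pick_soft_threshold()`, `compute_tom()`,
   `detect_modules()`, `module_eigengene()`, `export_network()`);
3. structural topology: degree and hubs, local clustering, shortest paths,
   information centrality, module-versus-network comparisons and
   hypergeometric regulator enrichment (`topology_report()`,
   `information_centrality()`, `hypergeom_enrichment()`, ...);
4. overlay of TF→target and miRNA→target relationships into a directed
   signed gene regulatory network (`build_grn()`);
5. mining of dynamic bifurcation paths — time points at which a subset of
   genes diverges from its group, annotated with the regulators whose
   targets are branch-enriched (`mine_paths()`, `summarize_paths()`);
6. hybrid Boolean/continuous simulation of the regulatory logic with
   clamping perturbations (`squad_system()`, `squad_integrate()`,
   `boolean_attractors()`, `perturbation_scan()`);
7. Cy0 quantification of qPCR amplification curves (`fit_richards()`,
   `compute_cy0()`, `cy0_table()`).

A synthetic-data generator with planted ground truth (`synth_config()`,
`generate_dataset()`, `generate_qpcr_curves()`) makes every stage testable
without external expression data, and `run_pipeline()` orchestrates the
stages end to end with a reproducibility manifest.

# Differential and emergent genes

Each gene's replicate values at a time point are compared by Welch's
two-sample *t*-test — against a reference time point for DEG calling, or
against the previous time point for the expression *gradient*. p-values are
Benjamini–Hochberg adjusted across genes within each comparison (tests at
different time points answer different questions; a global adjustment is
available by adjusting the returned raw p-values). A gene is a DEG when its
adjusted p-value falls below `alpha` (default 0.05) and its |log2 fold
change| reaches `lfc_min` (default 1). A gene's *emergent time* is the first
time point whose gradient test is significant; each gene is counted once, so
emergent counts over time partition the ever-significant genes. The test,
threshold and gradient-versus-baseline interpretation are all configurable;
moderated-variance models are deliberately out of scope.

# Co-expression network

Similarity is |Pearson correlation| over all samples (unsigned, the
default) or `(1 + r)/2` (signed). The soft threshold β raises similarity
elementwise to a power so that weighted connectivity
$k_i = \sum_{j \ne i} s_{ij}^\beta$ approximates scale-free topology. The
fit index bins $k$ into 10 equal-width bins and regresses
$\log_{10}(\text{frequency})$ on $\log_{10}(\bar k)$ over non-empty bins;
its sign is flipped when frequency *increases* with connectivity. β is the
smallest candidate reaching `r2_goal` (default 0.8); if none qualifies the
argmax is used with a warning.

Topological overlap is
$\mathrm{TOM}_{ij} = (L_{ij} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$ with
$L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}$, and modules are detected by
average-linkage clustering of $1 - \mathrm{TOM}$ with a **static** cut at
99.5% of the merge-height range. This is simpler and fully deterministic
compared with dynamic tree cutting, and recovers planted blocks cleanly; its
known limitations are (i) background noise genes adjacent to a module tend
to be absorbed into it rather than left unassigned, and (ii) at low powers
(β ≤ 4) adjacent modules can merge. Clusters below `min_module_size` are
pooled into `"grey"`; retained modules take WGCNA-style color labels in
decreasing size order. Module eigengenes are the first principal component
of the per-gene standardized module submatrix, oriented to correlate
positively with mean module expression.

Network export applies an inclusive weight threshold (default 0.75) to the
TOM by default — the standard export practice — and is configurable to raw
adjacency.

# Topology

Degree, hubs (degree ≥ k, inclusive; k = 500 at full scale), local
clustering coefficients and per-component mean shortest paths are standard.
Information centrality (current-flow closeness) is computed per connected
component from $C = (L + J)^{-1}$ with $L$ the component Laplacian and $J$
the all-ones matrix:
$\mathrm{IC}(i) = n \big/ \sum_j (C_{ii} + C_{jj} - 2C_{ij})$. The pairwise
term equals the effective resistance between $i$ and $j$, which is the basis
of the independent test oracle (Moore–Penrose pseudoinverse of $L$). Modules
are compared against the whole network by Welch *t*-tests on their members'
centralities. Regulator enrichment (e.g. of TFs among hubs) uses the exact
hypergeometric upper tail with universe = network nodes.

# Regulatory overlay

TF→target edges are retained when both endpoints are network genes and the
retention policy holds: a direct co-expression edge (`co_edge`), shared
non-grey module membership (`co_module`, default), or membership alone
(`all`); the three policies are nested. TF edges default to activating
(+1; an input `sign` column overrides), miRNA edges are always repressive
(−1) and require only the target to be a network gene. Duplicates are
removed keeping the first evidence tag.

# Bifurcation-path mining

The dynamic regulatory model is a deterministic divisive state tree over
the time axis, in the spirit of dynamic regulatory event mining. All genes
start in one state at the first (baseline-referenced) time point. At each
subsequent time point every active group is tested for a two-way split of
its members' current values: a two-component Gaussian mixture (means
initialized at the 10th/90th percentiles) is fitted by EM and compared with
a single Gaussian by BIC. A split is accepted when the mixture improves BIC
by at least `delta_bic_min` (default 10, "very strong" evidence on the
conventional scale) *and* both posterior-assigned children have at least
`min_path_size` genes (default 20). A classification (hard-assignment)
likelihood is deliberately not used: splitting a single Gaussian at a
threshold inflates the two-group likelihood enormously, and calibration on
pure noise shows it would split essentially every group, whereas the
mixture criterion leaves noise unsplit.

At an accepted split, every regulator with targets in the parent group is
scored by the exact hypergeometric tail (universe = parent group, category
= the regulator's targets in it, sample = upper branch, i.e. the child with
the larger mean — activator semantics). miRNAs are additionally tested
against the lower branch (repression) and the smaller p is kept. Regulators
annotate the split when p ≤ 0.032 (TFs) or p ≤ 0.10 (miRNAs); these raw
class-specific thresholds follow the source methodology, and a BH-adjusted
variant can be applied to the returned enrichment tables. This module is a
methodological substitution: the original input–output hidden-Markov
formulation is not reproduced; the interface contract (splits, branch
memberships, regulator annotations at the class thresholds) is.

# Hybrid logical/continuous simulation

The standardized qualitative dynamical-systems form turns the signed
regulatory graph into ODEs on $[0,1]$ per node:
$\dot x_i = f(\omega_i) - \gamma_i x_i$, where the regulatory input
$\omega_i$ saturates the summed activator and inhibitor activations
($\mathrm{act} = \frac{1+N_A}{N_A}\frac{S_A}{1+S_A}$, analogously
$\mathrm{inh}$, $\omega = \mathrm{act}(1-\mathrm{inh})$) and

$$f(\omega) = \frac{-e^{0.5h} + e^{-h(\omega-0.5)}}{(1-e^{0.5h})(1+e^{-h(\omega-0.5)})}$$

is anchored at $f(0)=0$, $f(0.5)=0.5$, $f(1)=1$ for every gain $h$
(default 10). Unregulated, unclamped input nodes decay to 0, which makes
"activation 0 → 1" clamping scans well-posed; clamped nodes are held fixed.
Integration is fixed-step RK4 (dt = 0.05, horizon 60, steady when
$\max_i |\dot x_i| < 10^{-6}$); trajectories are forward-invariant in the
unit hypercube, and halving the step changes fixtures' steady states by
less than $10^{-6}$. Boolean fixed points of the underlying synchronous
logic (OR over activators AND NOT OR over inhibitors; inputs hold) are
enumerated exhaustively up to 20 free nodes and can seed the continuous
relaxation. Edge weights are unitary — the source connectivity carries no
weights — with a weighted generalization left out of scope.

# Cy0 quantification

Amplification curves are fitted with the 5-parameter Richards sigmoid
$F(x) = F_b + F_{\max}(1 + e^{-(x-c)/b})^{-d}$ by Levenberg–Marquardt least
squares, initialized from the data. Cy0 is the $x$-intercept of the tangent
at the inflection point $x^* = c + b\ln d$, measured from the baseline
$F_b$; baseline-referencing makes Cy0 invariant to offsets and linear
rescaling of fluorescence. In the logistic case ($d = 1$), Cy0 reduces to
$c - 2b$. Note that $c$ and $d$ alias each other along the cycle axis, so
individual parameters are recovered far less precisely than Cy0 itself
under noise; Cy0 is the quantity to compare across samples. Curves whose
max/min fluorescence ratio is below 5 are rejected as non-amplifying.

# The synthetic generator

`generate_dataset()` plants every structure the pipeline is meant to find:

* **modules** — each gene is `loading × latent(t) + noise` with module
  latent trajectories built as cumulative Gaussian steps smoothed by a
  3-point moving average and standardized. Because a 12-point axis makes
  chance collinearity between independent random walks common (enough to
  blur planted boundaries), each new latent is Gram–Schmidt-orthogonalized
  against the previous ones and against planted split-ramp directions; the
  result is still a smooth random curve.
* **connectivity heterogeneity** — module sizes follow a geometric
  (heavy-tailed) sequence (400, 300, 225, ... by default) and loadings are
  drawn right-skewed (`lo + (hi−lo)·U³`): many weakly and few strongly
  connected genes, as in real co-expression data, which is what lets the
  soft-thresholded network approximate a power-law degree distribution.
* **regulators** — TFs are designated module genes whose profile leads the
  module trajectory by `tf_lag` steps; their targets are module co-members.
  miRNA targets (drawn from the background pool) receive a negative
  coupling to the miRNA trajectory.
* **bifurcations** — after `split_time` (the last time point at which the
  branches coincide), the two branches of a split module drift apart at
  `split_offset` log2 units per step, half per branch, with
  `split_enrich_frac` of the split regulator's targets in the upper branch.
  Splits are planted in large modules while sparing the single largest,
  whose degree profile dominates the connectivity distribution.
* **qPCR** — Richards curves with known parameters plus Gaussian noise; the
  true Cy0 is computed analytically before noise.

The default configuration (2,000 genes, 12 time points, 3 replicates,
8 modules, noise SD 0.5, seed 42) carries no planted split: bifurcation
experiments use explicit split-bearing configurations (one tightly loaded
400-gene module, 10 time points, split after time 5, offset 1.5, no
miRNAs), where the divergence is the only planted dynamic event. Background
genes are pure noise and supply the downstream "grey" pool.

What the generator does **not** emulate: count-based sequencing noise,
mean–variance coupling, batch effects, probe artifacts, or antisense
transcription mechanics. Tests passing on this generator demonstrate the
algorithms' correctness on data satisfying their assumptions, not
performance on any particular real dataset.

# Problem sizes and numerical choices

The test suite and the acceptance script work at desk scale: the default
bundle (2,000 genes × 36 samples) for network construction and module
recovery; 50-node matrices for TOM oracles; all ≤7-vertex connected graphs
(via the graph atlas, exhaustive up to isomorphism — information centrality
is relabeling-invariant) plus 30-node random graphs for the centrality
oracle; 20 seeded 400-gene simulations plus 50 pure-noise runs for path
mining; 40-cycle curves for Cy0. Degenerate inputs are handled explicitly:
constant genes are dropped from similarity with a warning, singleton
components yield missing centrality, degenerate (single-bin) connectivity
distributions are an error rather than a fit, EM component collapse vetoes
a split, and non-amplifying qPCR curves are rejected by name.

# Reproducibility

All randomness in a pipeline run flows from one seed; `run_pipeline()`
writes a manifest with the package version, full configuration and MD5
hashes of every output, and reruns with the same configuration are
bit-identical. `scripts/acceptance.R` regenerates the default bundle and
reports the signed scale-free fit index attained by soft-threshold
selection.
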