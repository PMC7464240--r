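---
title: "Methods: micro- and macro-level prioritization of communicative genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micro- and macro-level prioritization of communicative genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commnet)
```

# Overview

`commnet` implements a two-scale network workflow for finding
*communicative genes* in a disease transcriptome: genes that both change
expression between paired conditions (lesional vs non-lesional tissue in
the motivating psoriasis setting) and occupy communication hot-spots of the
protein–protein interaction (PPI) network induced on the differentially
expressed genes. The micro level scores individual nodes with five
centrality metrics; the macro level decomposes the prioritized subnetwork
into modules by modularity optimisation and repeats the metric-threshold
selection within each module. This vignette records the model, its
assumptions, the tunable parameters, and the numerical and design choices
made where the procedure leaves room.

# Differential expression: empirical-Bayes moderated paired t

For probe $g$ with $n$ patient pairs, the paired differences
$d_{gi} = \mathrm{LL}_{gi} - \mathrm{NL}_{gi}$ give
$\widehat{\mathrm{logFC}}_g = \bar d_g$ and sample variance $s_g^2$ on
$d = n - 1$ degrees of freedom. We assume, per the usual hierarchical
model, $s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \chi^2_d / d$ with a scaled
inverse-chi-square prior $\sigma_g^2 \sim d_0 s_0^2 / \chi^2_{d_0}$, so
that marginally $s_g^2 \sim s_0^2 F(d, d_0)$. The hyperparameters are
estimated by the method of moments on $z_g = \log s_g^2$, using the exact
mean and variance of $\log F$ in terms of digamma/trigamma functions; the
trigamma inverse is computed by a Newton iteration on $1/\psi_1$
(convergence threshold $10^{-8}$ on the relative step, at most 50
iterations). The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ yields
$t_g = \bar d_g / (\tilde s_g / \sqrt n)$ on $d_0 + d$ df (capped at the
pooled residual df across probes).

Degenerate inputs are handled explicitly:

* probes with $s_g^2 = 0$ enter the hyperparameter fit offset to
  $10^{-5}\times$ the median variance, but keep the shrunk posterior
  variance, so their $t$ is finite and large whenever $d_0 > 0$;
* if the log-variances show no excess dispersion, the moment estimator
  returns $d_0 = \infty$ (complete shrinkage). We then take
  $s_0^2 = \overline{s^2}$, the arithmetic mean of the sample variances.
  This choice makes the equal-variance case exact: when all $s_g^2$ are
  equal, the moderated statistic coincides with the classical paired $t$
  identically, which is the behaviour the shrinkage limit should have;
* a data set in which *every* probe has zero variance is rejected: the
  prior is unidentifiable there.

Forcing `priorDf = 0` turns shrinkage off and reproduces the classical
paired $t$ exactly — a useful diagnostic and the basis of one of the test
oracles. The independent reference implementation in `limma` is used only
as a cross-check in the test suite, never as the computation path.

DEG selection applies the replication cutoffs `p < 0.01` and BH-FDR
`< 0.01` (both strict) and `|logFC| >= 1` (inclusive), exactly as printed,
then truncates to the top 2000. The ranking statistic behind "top 2000" is
not specified by the original procedure; we declare it as ascending
adjusted p, ties by descending `|logFC|`, then lexicographic identifier —
chosen for determinism, not inferred. Probe-to-gene collapse keeps the
probe with maximal `|logFC|` *with its sign* (needed downstream for up/down
classification) and that probe's p and FDR; `|logFC|` ties go to the
lexicographically smallest probe ID.

# Centrality: conventions and numerics

All shortest paths are unweighted (BFS). A single Brandes-style pass
(implemented in C++) accumulates, per source:

* **betweenness** via the standard dependency recursion
  $\delta(v) \mathrel{+}= \frac{\sigma_{sv}}{\sigma_{sw}}(1 + \delta(w))$,
* **stress** via a parallel counter
  $\phi(v) = \sum_{w \in \mathrm{succ}(v)} (1 + \phi(w))$, giving
  $\sigma_{sv}\,\phi(v)$ shortest paths through $v$ from source $s$,
* the geodesic distance sums used for closeness.

Both pair-based metrics count unordered pairs once (ordered totals are
halved). Path counts are kept as doubles, exact up to $2^{53}$ — far beyond
any count reachable at the graph sizes this workflow touches.

Normalisation conventions are fixed by the value ranges the original
analysis prints (raw degree up to 182, stress in the millions, betweenness
and eigenvector well below 1): degree and stress are reported **raw**;
betweenness is normalised by $(n-1)(n-2)/2$ with $n$ the node's component
size (0 when $n < 3$); closeness uses the within-component convention
$(n_c - 1)/\sum_u d(v, u)$ with isolated nodes at 0; eigenvector centrality
has unit Euclidean norm per connected component. These conventions are
reverse-engineered, declared choices — the original network is not
available to verify them bit-for-bit.

Eigenvector centrality is computed by power iteration per component,
started from the uniform vector. The iteration actually runs on $A + I$:
this leaves the eigenvectors unchanged but makes the leading eigenvalue
strictly dominant, so bipartite components (where $\pm\lambda_1$ would
otherwise tie) converge too. Convergence is declared when successive
iterates differ by less than `tol` ($10^{-12}$ by default) in max-norm;
exceeding `maxIter` (default 10 000) is an error reporting the residual
rather than a silent approximation.

# Modularity optimisation

The quality function is Newman modularity
$Q = \sum_c \left[ e_c/m - \gamma (d_c/2m)^2 \right]$ with resolution
$\gamma = 1$ by default ($\gamma$ is exposed but the replication setting
reports two modules at default resolution). The optimiser is the two-phase
greedy Louvain heuristic: single-node moves to the neighbouring module with
the largest positive gain until a full sweep makes no move, then module
aggregation into supernodes (self-loops carry the internal weight), until a
level produces no move. The node sweep order is shuffled by an explicit
seed, so runs are exactly reproducible; ties among equal-gain candidate
modules go to the lowest module id (numerical tolerance $10^{-12}$ on the
gain comparison). Module ids in the returned partition are contiguous from
0, numbered by decreasing size with ties broken by the lexicographically
smallest member.

Greedy ascent from singletons guarantees monotone non-decreasing $Q$ across
levels but not $Q \ge 0$ in pathological local optima; if a converged
partition scores below the all-in-one partition, the all-in-one partition
($Q = 0$ at $\gamma = 1$) is returned instead, so the documented
post-condition holds unconditionally. The recorded per-move gains equal the
from-scratch modularity difference (a tested invariant), and recovery of
planted two-module graphs is part of the acceptance suite.

# Selection logic

Per-metric threshold selections use **inclusive** comparisons (`>=`),
matching the printed "degree ≥ 26"-style notation, and are combined by
**union**. The union is a deliberate reading: the published module-1
outcome (six genes) equals the union of the three printed per-metric
groups, while their intersection would contain only two genes, despite
wording that suggests intersection; we implement the behaviour that
reproduces the printed outcome.

When no explicit thresholds are supplied, `tuneThresholds` places all
metrics at a common quantile $q$, lowering $q$ from 0.99 in steps of 0.005
until the union strictly exceeds the target fraction of nodes (default
10 %, the ">10 percent of nodes" rule). A single shared quantile keeps the
tuned spec interpretable; explicitly supplied per-metric thresholds always
take precedence. Quantiles use R's default (type 7) definition.

Within modules, a metric whose coefficient of variation $\mathrm{sd}/\mu$
(requiring $\mu > 0$) falls below `relVarMin`, or whose values are all
equal, is excluded as non-discriminating. The original analysis reports
such exclusions qualitatively ("very low variance") without a numeric
criterion; `relVarMin = 0.05` is our declared default.

# Over-representation

Gene-set enrichment is a hypergeometric upper-tail test per GMT set,
intersected with the background before testing and BH-adjusted. The
background defaults to the node set of the analyzed network rather than the
genome: the tested study sets are themselves drawn from network nodes, and
a genomic background would overstate significance. Rows are ranked by p;
the web-tool "combined score" ranking of the original analysis depends on
that tool's internal permutation z-scores and is deliberately not
reproduced.

# The synthetic-data generator

The generator supplies the study conditions the pipeline assumes, plus
ground truth, so every stage is testable offline.

**Expression** (`generateExpression`): per-gene baselines
$\mathcal N(8, 2^2)$ on the log2 scale (mimicking normalized microarray
intensities without modelling the vendor normalization chain), small
probe-specific offsets ($\mathrm{sd} = 0.25$) so probe collapse is
nontrivial, a per-patient effect ($\mathrm{sd} = 1$) shared by the NL and
LL samples (this is what makes the paired design informative), i.i.d.
Gaussian noise ($\mathrm{sd} = 0.5$), and true effects drawn uniformly from
1–3 log2 units with random sign on 20 % of genes. Defaults mirror the
emulated study: 85 patient pairs (170 arrays), 2000 measured genes, 1–3
probes per gene (70/20/10 %).

**Network** (`generatePPI`): a planted-partition graph with two dense
modules (default sizes 86 and 63, within-module edge probability 0.3), a
sparse background completing a 1445-node main part (cross/background
probability 0.005), hub nodes sampled from module members with 50 extra
random attachments each, and 17 appended small components (15 two-node
edges, 2 three-node paths) — at these defaults the graph reproduces the
emulated component profile: 18 components, 1481 connected nodes.
`generateStudy` couples the two so every network gene is measured and
differential (effect signs per module mirror a mostly-upregulated
cell-cycle-like module, 81/86 positive, and a mixed immune-like module,
43/63 positive).

All randomness flows through explicit integer seeds; the caller's RNG
state is saved and restored around every draw.

What the generator does **not** emulate: probe-level vendor preprocessing
(MAS 5.0/CEL data), batch effects, array QC artifacts, heavy-tailed or
correlated noise, degree-dependent edge confidence, and identifier
ambiguity between probe/symbol namespaces. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
model, not robustness to every pathology of real microarray or interaction
data.

# Pipeline conventions

Only the largest connected component enters centrality-based selection;
smaller components are summarized but not analyzed. Nodes isolated by the
re-induction of the primary-gene network are excluded from modularity
detection but retained in reports. Per-module threshold specs are matched
to modules by id (size order); supplied thresholds on metrics that were
excluded as low-variance are dropped with a message. All artifacts are
plain TSV/JSON/GraphML, and the run manifest records seed, parameters and
per-stage counts but no timestamps, so a fixed seed gives byte-identical
manifests.

# Problem sizes and verification

The test and acceptance suites run at desk scale, chosen to keep the whole
verification cycle fast while remaining statistically meaningful: oracle
equivalence of the centrality implementation against exhaustive
all-shortest-path enumeration and dense eigendecomposition on 200+ random
graphs of up to 9 nodes (tolerance $10^{-9}$) and against igraph on graphs
of up to 30 nodes; null calibration of the moderated t on 50 simulated
2000-probe, 30-pair studies; planted two-module recovery (75+75 nodes,
$p_{in} = 0.3$, $p_{out} = 0.01$) over 20 seeds; and an end-to-end run on a
constructed 90-node two-module network with 6 + 11 planted super-hubs wired
to dominate every metric, which the pipeline must recover exactly. The
full-scale synthetic demonstration (1481-node network, 2000 genes, 170
arrays) completes in well under a minute on one CPU.

# Known limitations

* The exact replication targets of the emulated study (its 152-gene
  primary set, the specific 17 genes) depend on proprietary-versioned
  external databases and are out of reach by construction; the package
  reproduces the printed worked examples and the method's statistical
  behaviour instead.
* Stress and betweenness assume unweighted edges; STRING confidence scores
  are used only as a pre-filter, never as weights.
* The Louvain heuristic is seed-dependent near degenerate optima; module
  *structure* is stable in the tested regimes but module numbering is only
  made deterministic by the size/lexicographic renumbering rule.
* `tuneThresholds` assumes the metrics are meaningfully graded; on
  constant columns it can only terminate by selecting everything at
  $q = 0$.
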