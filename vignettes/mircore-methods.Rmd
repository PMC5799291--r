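---
title: "Methods: miRNA-induced gene networks, their core, and prognostic signatures"
author: "mircore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-induced gene networks, their core, and prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircore)
```

# The network model

Intragenic miRNAs sit inside introns or exons of protein-coding host genes;
most are intronic and transcribed in the sense orientation, so they are
co-transcribed with their hosts and released during splicing. Since miRNAs
post-transcriptionally repress their targets, every validated
(miRNA, target) pair whose precursor lies in a host gene induces a directed
intergenic interaction: an edge from the host gene to the target gene.
`buildNetwork()` constructs this graph from three tables — host
annotations, the mature↔precursor map, and the validated-target set — and
simplifies it in a fixed order:

1. self-loops (a gene targeted by its own intragenic miRNA) are recorded in
   a side table and removed — a loop is meaningful self-regulation, but the
   downstream graph analyses are defined on loop-free graphs;
2. parallel edges are merged, unioning the mediating mature-miRNA labels;
3. isolated nodes are dropped.

This order makes the degenerate case well-defined: a host gene whose only
interaction is a self-loop disappears from the network entirely. Two
network variants are supported: the full network over all intragenic
miRNAs, and the intronic-sense restriction (`filterMirnaClass()`), whose
edge set is always a subset of the full network's.

**Validated targets.** An interaction counts only when present in both
configured target databases (`intersectValidatedTargets()`, a symmetric
set intersection). Database exports vary by release, so column names and
delimiters are configurable; gene identifiers are normalized to upper-case
official symbols with an optional synonym map, and mature-miRNA ids are
matched case-insensitively but otherwise exactly — no -3p/-5p collapsing,
because mature miRNAs are counted distinctly from their precursors. A
mature miRNA deriving from several precursors in different host genes is
attributed to *every* such host: the mapping is genuinely many-to-many and
any single-attribution rule would silently drop edges.

# The core

The core is the union of nontrivial strongly connected components — node
sets of size ≥ 2 in which every gene reaches every other along directed
edges, i.e. groups of genes mutually regulated through chains of
intragenic miRNAs. The ≥ 2 threshold is part of the definition and is not
configurable. Components are reported by decreasing size with a
lexicographic tie-break so reports are reproducible. `coreSubgraph()`
induces the subgraph on the core (keeping edges that run between
components), and `coreDegreeRanking()` ranks core genes by total degree.
SCCs are computed by igraph's strong-components routine; the package's
test suite checks it against an independent pairwise-reachability oracle,
and a monotonicity property (adding edges never shrinks the core) that
also implies the intronic-sense core is contained in the full network's
core.

# Triad census and motif enrichment

All unordered node triples are classified into the 16 isomorphism classes
of loop-free 3-node directed graphs (standard 003…300 nomenclature). The
counting convention is the *induced* census — each triple is assigned to
exactly one class, so counts sum to $\binom{n}{3}$ — because exhaustive
enumeration of non-isomorphic three-node sub-networks is the induced
classification. A secondary non-induced counter
(`countMotifEmbeddings()`) is provided for sensitivity checks.

The efficient path is igraph's edge-based census, which completes on a
graph of ~8,500 nodes without enumerating the ~10^11 triples;
`bruteForceCensus()` is an independent exhaustive oracle (guarded to
≤ 300 nodes) classifying every triple from first principles via the dyad
census, against which the efficient path is tested on hundreds of random
graphs.

Motif shapes highlighted in figures are registered as named constants
(`figureMotifs()`): `FULL_MUTUAL` is class 300 (the fully bidirectional
triple, absent from the real networks). The figure-bound shapes default to
mutual-dyad-containing classes — `FIG2C = "102"` (a mutually connected
gene pair plus a spectator), whose position in the standard census order
matches the published "sub-network type 3" indexing and whose counts are
consistent with the published values, with `FIG2A = "201"` and
`FIG2B = "111U"` as documented defaults. Because these constants encode a
reading of figures rather than a computation, they are overridable in one
place rather than hard-wired into any analysis.

# Null models and Monte Carlo testing

Both null models match the observed network in node and edge counts:

* **Erdős–Rényi G(n,m)**: exactly `m` loop-free directed edges, uniform
  over ordered pairs (igraph's `gnm` sampler — the same construction used
  in the original analyses).
* **Fixed out-degree**: each node keeps its out-degree $N_g$ and its
  target set is uniform over all $\binom{n-1}{N_g}$ loop-free choices.
  This is equivalent to randomizing every miRNA's target list while
  preserving its length. The sampler follows the classical construction:
  a Fisher–Yates permutation of $\{1,\dots,n-1\}$, take the first $N_g$
  elements, and shift indices $l \ge g$ to $l+1$ to exclude the self-loop.
  Samples preserve the out-degree vector *exactly*, which gives a free
  degenerate check: the edge count statistic yields p = 1 under this
  model.

`monteCarloTest()` uses the conventional add-one estimator
$p = (r+1)/(N+1)$, whose floor at the conventional $N = 10{,}000$ is
$1/10{,}001 \approx 9.999\times10^{-5}$ — which is why strong enrichments
are reported as "p ≤ 10⁻⁴" rather than zero. The tail is explicit per
test: motif over-representation uses the upper tail; core size versus
random graphs uses the lower tail, since the relevant finding is a core
*smaller* than random (random graphs of the same density typically have a
giant strongly connected component). Replicate seeds are drawn up front
from the user seed, so replicate *j* is reproducible independently of
execution order and results are bit-identical across runs. The default of
10,000 replicates is overridable; the test suite and the acceptance
script use 200 for the enrichment demonstrations, which already resolves
p-values down to 1/201.

# Expression levels and variance

Transcripts are summarized by median, Q1 and Q3 across samples
(RPKM-like values). The quantile convention is linear interpolation
between order statistics (R type 7, the common default of mainstream
numeric stacks); it is recorded in reports because no convention is
universal, though stratum membership of well-separated genes is
insensitive to it. Expression variance is quantified as the Q3/Q1 ratio,
defined only when Q1 > 0; for such transcripts it is ranking-equivalent to
the interquartile range of log-scaled values (the equivalence is exact
when the quartiles fall on order statistics, which is how the test suite
checks it). Before variance ranking, `varianceHalfFilter()` retains the
upper half of transcripts by Q1 — which guarantees Q1 > 0 for everything
retained — mirroring the exclusion of low-expression transcripts whose
variance ratio is unstable or undefined.

Enrichment of a gene set in a rank stratum is tested with the exact
binomial upper tail $\sum_{j\ge k}\binom{n}{j}p^j(1-p)^{n-j}$: under the
null, each set member falls into a stratum holding fraction *p* of
transcripts independently with probability *p*. Stratum cutoffs use
`floor(fraction × total)` (floor rather than ceiling: conservative for
membership counts; on 26,000-odd transcripts the choice is immaterial),
and ties get average ranks. Genes absent from the expression matrix are
dropped from *n* with a warning, matching cohorts in which only part of a
gene set was measured.

# Prognostic signature search

Cohorts are dichotomized by outcome windows: events are recurrences within
the horizon (3 years for the colorectal scheme, 5 for breast), controls
are recurrence-free patients with sufficient follow-up (4 and 7 years
respectively); the remainder — the grey zone — plus unknown-status
patients and first-month recurrences (colorectal) are excluded. Windows
live in a `dichotomizationScheme` object, so other cohorts just supply
their horizons.

For every candidate gene subset (lexicographic enumeration,
`exhaustiveSearch()`), a linear-kernel SVM is fitted on the training
cohort with class weights inversely proportional to class sizes
(`n/(2 n_class)`; duplicating a class leaves the weighted problem
balanced). Expression is (0,1)-scaled with means and SDs estimated on the
training cohort *only*; the scaler is frozen inside the
`LinearSignature`, so filtration and validation cohorts can never leak
into it. The decision function is re-expressed as the explicit risk score
$R(e) = \sum_i w_i e_i - \rho$, oriented so $R \ge 0$ assigns the
high-risk group (the boundary itself is high-risk). Candidates are
discarded when training sensitivity *or* specificity falls below 0.60,
or when either metric falls below 0.50 on *any* filtration cohort — the
per-dataset conjunctive reading, since a classifier failing one filtration
cohort is filtered out. Survivors are ranked by the arithmetic mean of
the AUCs over the training and filtration cohorts (AUC by rank comparison
with mid-rank tie correction, so constant scores give exactly 0.5).
Validation metrics are computed on the dichotomized (non-grey) part of
the validation cohort; Kaplan–Meier curves and the two-tailed log-rank
test use *all* validation patients with follow-up, because survival
curves extend beyond the dichotomization horizon. The SVM cost parameter
is not identifiable from published summaries; the default C = 1 is
exposed as configuration, and correctness is assessed by planted-signal
recovery rather than weight reproduction. Cross-validation
(`crossValidate()`) is class-stratified and seeded; leave-one-out is
supported as the special case `folds = n`.

# Synthetic data: what it emulates, and what it does not

The generators produce inputs with the statistical structure each stage
assumes, with ground truth recorded:

* `simulateAnnotations()` plants core cycles by wiring each cycle gene's
  hosted miRNA to the next gene; background host→target records follow a
  random topological order over non-core genes (core genes ordered last),
  so no unplanned nontrivial SCC can arise and core-recovery tests are
  exact rather than probabilistic. Both target tables contain every
  emitted interaction; a few extras in one table only exercise the
  intersection.
* `simulateExpression()` uses a log-normal model — per-transcript location
  `Normal(1, 0.8)` and scale `Uniform(0.4, 1)` on the log scale — rather
  than a count-level model, because the analyzed quantities are quantile
  ranks of RPKM-like values, insensitive to count noise. Planted genes
  draw their location from the same distribution shifted by the effect
  size, so a zero shift makes them exchangeable with the background and
  the stratum count is exactly Binomial(n, fraction) — the null
  calibration the tests verify. At the stated 2-log-unit shift, ≥ 10 of
  12 planted genes land in the top quartile in ≥ 95% of replicates.
* `simulateCohorts()` emits one training, two filtration and one
  validation cohort. Expression is standard normal per gene with the
  planted triple shifted between classes (±1.5 SD by default, signs may
  differ, mirroring oppositely directed expression changes); event times
  follow a truncated exponential within the event window, controls get
  follow-up beyond the control minimum, and a configurable fraction is
  emitted into the grey zone. At 1.5-SD shifts the planted triple ranks
  first in ≥ 95% of search replicates; with zero shift it passes the
  filtration cascade in ≤ 5%.

What passing these tests does *not* show: real annotation databases have
correlated errors and shared evidence between sources, real expression
data have heavier tails and batch structure, and real cohorts have
informative censoring and platform effects — none of which the generators
model. The synthetic results validate the *algorithms*, not the
biological conclusions drawn from any particular snapshot.

# Numerical choices and degenerate inputs

* Deterministic tie-breaks everywhere a ranking is reported (lexicographic
  gene ids; component ordering by size then smallest member).
* An empty validated-target set builds an empty network with a warning,
  not an error; an acyclic network has an empty core; a census on < 3
  nodes is all-zero.
* `monteCarloTest()` aborts with the replicate index if the statistic
  fails on a null sample; p-values can never fall below 1/(N+1).
* Binomial tails are computed at full floating precision and rounded only
  for display (two significant digits in reports).
* Zero-variance genes in a training cohort are an error at fit time —
  scaling would divide by zero — rather than silently dropped.

# Problem sizes

The test suite and acceptance script run at desk scale by design: oracle
equivalences on hundreds of random graphs of up to 60 nodes, Monte Carlo
demonstrations at 200 replicates on 300-node graphs plus one
10,000-replicate run on a 20-node toy to exhibit the estimator floor,
expression recovery at 5,000 × 50 matrices over 100 replicates, and
signature recovery over 50 cohort replicates with a 6-gene universe.
These sizes were chosen so the full suite completes in minutes while
every statistical claim still has enough replicates to be meaningful;
genome-scale runs (tens of thousands of nodes, 10,000 replicates) use the
same code paths and are supported by the edge-based census and streaming
Monte Carlo.

# Known limitations

* The figure-bound motif constants encode a documented reading of the
  published figures; analyses depending on them should state the chosen
  classes (they are printed in every census report).
* Gene-symbol history across genome builds is not resolved; the synonym
  map is the user's responsibility.
* The exhaustive search is combinatorial: universes beyond ~25 genes at
  subset size 3 become expensive; that is the regime the method was
  designed for (a small network core), not a general feature-selection
  tool.
* Published cohort-level results (specific sensitivity/specificity/AUC
  values of named gene triples) require the original cohort series and
  are out of the package's reproduction scope; the search machinery is
  validated by planted-signal recovery instead.
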