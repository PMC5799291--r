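# mircore

Analysis of the directed gene–gene network induced by intragenic
microRNAs, and of the biology encoded in its core.

## The problem

A large fraction of human miRNAs are *intragenic*: their genes sit inside
introns or exons of protein-coding *host genes* and are mostly
co-transcribed with them. Each such miRNA wires its host gene to every gene
it represses, which induces a genome-scale directed network: genes *A* and
*B* are connected by an edge *A* ⊣ *B* when *A* hosts an intragenic miRNA
with experimentally validated target *B* (an interaction counts as
validated only when two independent target databases both report it).
`mircore` is for computational biologists who want to build that network
from annotation tables, interrogate its non-random structure, and test
whether its *core* carries biological signal:

* **Network construction** — raw host→target edges are simplified
  (self-loops recorded and removed, parallel edges merged with their
  mediating miRNAs unioned, isolated nodes dropped), and summarized by node
  roles, edge counts and in-degree rankings. The network can be built from
  all intragenic miRNAs or restricted to intronic sense miRNAs.
* **Core extraction** — the core is the union of nontrivial (≥ 2 nodes)
  strongly connected components: sets of genes mutually regulated through
  chains of intragenic miRNAs.
* **Motif statistics** — a 16-class triad census (standard
  003…300 nomenclature) with Monte Carlo enrichment tests against two
  null models matched in nodes and edges: directed Erdős–Rényi *G(n,m)*
  and a fixed-out-degree model (equivalent to randomizing each miRNA's
  target list while preserving its length). P-values use the conventional
  add-one estimator *(r+1)/(N+1)*.
* **Expression statistics** — transcripts are ranked by median/quartile
  expression; expression variance is the Q3/Q1 ratio (ranking-equivalent
  to the log-scale IQR); core-gene membership in rank strata is tested
  with exact binomial upper tails.
* **Prognostic signatures** — an exhaustive search over gene subsets
  using a class-weighted linear SVM
  *R(e) = w₁e₁ + … + w_k e_k − ρ* on (0,1)-scaled expression
  (scaling estimated on the training cohort only; *R* ≥ 0 ⇒ high risk),
  with grey-zone cohort dichotomization, sensitivity/specificity
  filtration, mean-AUC ranking, and Kaplan–Meier / log-rank validation.
* **Synthetic data** — seed-reproducible generators with planted ground
  truth (core cycles, high-expression gene sets, discriminative gene
  triples) emulate every input the pipeline consumes, so all stages are
  testable without database snapshots or cohort downloads.

## Worked example

```r
library(mircore)

## synthetic inputs with two planted core cycles (sizes 4 and 2)
sim <- simulateAnnotations(nGenes = 120, nMirnas = 50,
                           plantedCycles = list(sprintf("G%04d", 1:4),
                                                sprintf("G%04d", 5:6)),
                           seed = 42)
targets <- intersectValidatedTargets(sim$targetsA, sim$targetsB)
net <- buildNetwork(sim$hosts, sim$matureMap, targets)
net
#> GeneNetwork: 85 nodes, 116 edges (0 self-loops removed)

extractCore(net)
#> CoreDecomposition: 2 nontrivial SCCs, core size 6
#>   component sizes: 4, 2

unlist(summarizeNetwork(net, sim$hosts, sim$matureMap, targets))
#>    totalN  bothdirN      outN       inN    totalE     matMi     preMi hostGenes
#>        85        26        21        38       116        56        56        47

## is the core smaller than in degree-matched random graphs?
monteCarloTest(net, coreSizeStat(),
               randomGraphSpec("fixed_outdegree",
                               outDegrees = unname(outDegreeVector(net))),
               replicates = 200, tail = "lower", seed = 1,
               statName = "core size")
#> MonteCarloResult [core size]: observed 6, 41/200 replicates as extreme
#>   (lower tail), p = 0.208955

## exact binomial enrichment: 10 of 12 core genes in the low-variance half
binomialUpperTail(10, 12, 0.5)
#> [1] 0.01928711
```

The planted cycles come back exactly as the two core components; the
Monte-Carlo test reports the add-one p-value for the observed core size
under the fixed-out-degree null; and the binomial tail is the exact
enrichment probability for 10 of 12 core genes falling into a stratum
holding half of all transcripts (prints as 0.019 at two significant
digits).

## Command line

A thin wrapper over the R API lives at `inst/scripts/mircore.R`:

```sh
Rscript inst/scripts/mircore.R simulate --seed 1 --out sim/
Rscript inst/scripts/mircore.R run --config run.yaml --stages build,core,census
```

The YAML run config is validated by `validateRunConfig()` (unknown keys
and constraint violations are errors naming the field); every run writes a
manifest of artifacts with MD5 checksums.
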