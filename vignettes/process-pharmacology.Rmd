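---
title: "Process pharmacology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process pharmacology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procpharm)
```

## The analysis

`procpharm` implements a drug-repurposing strategy that treats diseases as
bundles of biological processes rather than single targets. Starting from a
trait-associated gene set (the motivating case is the ~20 genes causing
hereditary insensitivity to pain), the pipeline has two arms:

1. **Functional arm.** The trait genes are tested for over-representation
   of Gene Ontology biological-process terms against all annotated genes,
   and the significant terms are condensed into a handful of headline
   "functional areas".
2. **Repurposing arm.** All drugs are embedded in a space of biological
   processes via the product of a binary drug-by-target-gene matrix and a
   binary gene-by-process matrix. A *virtual drug* — the vector counting,
   for each process, how many trait genes are annotated to it — is added
   as an extra row. After restricting to processes addressed by both the
   drugs and the virtual drug, Euclidean distances to the virtual drug are
   computed, their reciprocals are pruned by nested computed ABC analysis,
   and an emergent self-organizing map (ESOM) with U-matrix watershed
   clustering is trained on the survivors. The cluster (U-matrix basin)
   containing the virtual drug is the candidate list.

## Over-representation analysis

For a term annotating $K$ of $N$ background genes, observing $k$ annotated
genes in a query of size $n$ is scored with the one-sided Fisher exact
test, i.e. the hypergeometric upper tail
$P(X \ge k),\; X \sim \mathrm{Hyp}(N, K, n)$, computed via
`stats::phyper`. Only over-representation is tested; terms with $K = 0$
are skipped. Multiple testing uses Benjamini–Hochberg FDR by default
(`t_p = 0.05`, the setting for small trait gene sets) or Bonferroni; a
term is significant when the adjusted p-value is $\le t_p$ (inclusive
comparison). Query genes missing from the annotation background are
dropped with a warning so that $N$ stays consistent; the background
universe defaults to all genes with at least one annotation and can be
overridden.

Annotation tables are propagated before testing (true-path rule): a gene
annotated to a term is annotated to all its `is_a` and `part_of`
ancestors. `regulates` edges remain traversable in the graph but do not
transmit annotations, following the usual GO closure convention — the
source procedure names all three relations without stating closure rules,
so the conservative convention was adopted. Propagation is idempotent and
monotone, and the parser rejects cyclic or dangling ontologies outright.

The significant terms are re-assembled into a DAG by transitive reduction
over the significant node set: a significant term connects to its nearest
significant ancestors (over all three relations), skipping non-significant
intermediates.

## Functional abstraction

The published functional-abstraction algorithm is only cited, not
reproduced, in the source; this package implements a stated, testable
surrogate with the same objectives (coverage, precision, information
value, conciseness): greedy weighted set cover over the significant terms.
A candidate headline covers itself and its propagating descendants within
the significant set, and is scored by
$(\text{newly covered terms}) \times \mathrm{IC}$, where
$\mathrm{IC} = -\log_2(K/N)$ is the term's information content in bits.
After a headline is chosen, its ancestors and descendants leave the
candidate pool, so headlines are never redundant. Ties break by higher
information content, then lexicographic term id, making the algorithm
fully deterministic. Defaults `max_headlines = 10`, `min_cover = 0.95`
aim at the regime of roughly ten areas summarizing on the order of a
hundred significant terms; when the coverage target is unreachable the
best-effort set is returned with a warning. How far this surrogate
diverges from the original algorithm on real GO data cannot be bounded
here; its contract is its own stated objective function.

## The process matrices and the virtual drug

`build_drug_gene()` and `build_gene_process()` produce binary incidence
matrices; their label-aligned product counts, per (drug, process), how
many of the drug's targets are annotated to the process. For the
gene-by-process matrix the ORA is used purely as a *filter* selecting a
process vocabulary; the reference setting for genome-scale backgrounds is
the very conservative `t_p = 1e-15` with Bonferroni correction, chosen
there to cut tens of thousands of GO terms down to hundreds. With
`t_p = 1` the filter is disabled and every annotated term is kept.

The virtual drug's entries count trait genes per process; it errors if
all-zero (no overlap between trait biology and drug-addressable
processes). `restrict_shared()` keeps the processes positive in **both**
the virtual drug and at least one drug, drops drugs left without support,
and appends the virtual drug as the final row. Distances are plain
Euclidean on the raw counts — the reference procedure describes no
standardization, and the virtual drug is explicitly count-valued; a
`scale_columns` switch exists but is off by default.

## Nested ABC analysis

The reciprocal distances (larger = more similar) are pruned by computed
ABC analysis. The ABC curve plots, for values sorted in decreasing order,
the cumulative fraction of items against the cumulative fraction of the
total. Set A ends where the curve's slope first comes down to 1;
evaluated on the discrete curve segments this is parameter-free and
exactly testable: segment $i$ has slope $n v_{(i)} / \sum v$, so A is the
set of values above the mean, with the boundary segment itself included
when its slope equals 1. An all-equal input degenerates to a single-item
A so that nested application terminates. The B/C boundary (the curve
point nearest $(1,1)$ among the remaining items) is computed for report
completeness only — nothing downstream uses it, and for strictly
increasing curves it places every remaining item in B. Nesting at depth 2
(A of A) mirrors the reference pipeline. A drug at distance zero from the
virtual drug would have an infinite reciprocal; such items bypass the
analysis and are force-retained with a message.

## ESOM and U-matrix clustering

The surviving drugs plus the virtual drug (a training row like any other)
are projected by an online Kohonen SOM on a toroid grid. Defaults follow
emergent-SOM conventions for a 50 × 80 lattice: 50 epochs, Gaussian
neighborhood $h = \exp(-g^2 / 2r^2)$ in toroidal grid distance $g$,
radius decaying linearly 24 → 1 and learning rate 0.5 → 0.1 per epoch,
weights initialized uniformly within each data column's range. The
neighborhood kernel and both schedules are unspecified in the source and
are therefore exposed in `esom_config()`. Presentation order is
re-shuffled every epoch from a seeded stream; for a fixed seed, training
is bitwise reproducible (the update loop is compiled; all randomness
stays in R). At radius 0 only the best-matching unit (BMU) moves. BMU
ties resolve to the smallest (row, col) coordinate.

The U-matrix assigns each neuron the mean Euclidean distance between its
weight vector and its 8 toroidal neighbors' weights; valleys are clusters
and ridges are borders. Cluster extraction runs a steepest-descent
watershed: every neuron follows its lowest neighbor (ties by lower
height, then lexicographic coordinate — a rule that merges plateaus and
guarantees termination) to a local minimum; neurons draining to the same
minimum form a basin, and the candidate list is the set of labels whose
BMU shares the virtual drug's basin.

Two pre-processing steps control watershed granularity:

* a single 3 × 3 mean smoothing pass (default on) suppresses single-neuron
  noise;
* basins whose pit rises less than `min_depth_frac` (default 0.5) of the
  height range above their lowest saddle are dissolved into the neighbor
  across that saddle (h-minima suppression).

The second step is this package's own addition to the plain watershed.
An emergent map deliberately has many more neurons than data rows, and
with a few dozen training rows every data point carves its own shallow
dip into the weight field — plain watershed then returns roughly one
basin per point and the notion of a "cluster containing the virtual
drug" collapses. Dissolving low-dynamics basins is the standard
morphological remedy; the default threshold of half the height range
means that only ridges reaching at least half the map's dynamic range
count as cluster borders. Plain behavior is available via
`min_depth_frac = 0` (and `watershed_basins()` itself defaults to no
merging).

## The synthetic benchmark

`generate_synthetic()` emits the four input files the pipeline consumes
(OBO ontology, annotation TSV, drug-target TSV, trait gene list) plus a
ground-truth JSON, deterministically per seed (one RNG substream per
artifact). Defaults: 150 terms in a 6-layer random DAG (each non-root
term takes 1–2 parents from the previous layer, the first via a
propagating relation, so the graph is acyclic by construction and every
term has a propagating path to the root); 400 genes with 4 uniform
background annotations each, assigned to non-root terms and left
unpropagated so the pipeline exercises its own closure; 300 drugs; a
20-gene trait set; 10 planted processes drawn from the deepest layer; 30
planted drugs. Trait genes and a 60-gene signal pool are annotated to
each planted process with probability `signal_strength = 0.9`, every
other gene with `background_noise = 0.05`; setting the two equal removes
all structure and serves as the negative control.

Two design choices deserve explanation because the raw-count geometry of
the method dictates them:

* **Target multiplicity matches the trait-set size (18–22 targets per
  drug).** The virtual drug's planted-process entries are about
  $0.9 \times 20 \approx 18$. Because distances are computed on raw
  counts with no scaling, drugs with only a few targets (counts ≤ 4)
  would leave the virtual drug an extreme outlier: the trained map gives
  such an outlier an isolating U-matrix crater and no basin can ever
  join it to any drug. Multi-target drugs on the scale of the trait set
  put the virtual drug inside the drug cloud — which is also the regime
  of the real candidate lists, dominated by promiscuous compounds.
* **Background drugs overlap the signal pool.** The signal pool is a
  subset of the 150-gene druggable pool all background drugs draw from,
  so drug-to-virtual-drug similarity forms a continuum rather than two
  separated blocks. This matters for the nested ABC step: the slope-1
  boundary keeps exactly the values above the mean of the current set,
  so with a clean two-block value distribution the first pass returns
  precisely the planted block and the second pass halves it — a
  structural recall ceiling of about one half. A continuum reaching the
  planted cluster lets the second boundary land at the cluster's edge
  instead, as it evidently does in real drug repertoires.

What the generator does **not** emulate: GO's power-law term sizes and
deep multi-rooted topology, evidence codes, correlated annotation noise,
drug chemistry, or signed (agonist/antagonist) interactions. Passing the
benchmark therefore shows that the pipeline recovers a planted
process-level signal under controlled conditions, not that it reproduces
any particular real-data candidate list.

## Problem sizes and numerical choices

The benchmark runs the ESOM on a 20 × 30 toroid (600 neurons for ~30–60
training rows, preserving the neurons-per-row ratio of the full-size
50 × 80 map) with radius 10 → 1 — half the short axis, the same
convention as 24 for a 50-row map — and the gene-process filter disabled
(`t_p = 1`): a 150-term ontology needs no vocabulary pruning, and under
the signal-free control a strict filter would correctly, but
unhelpfully, abort on the zero-significant-terms error path. Recovery is
scored as recall and precision of the planted drugs in the virtual
drug's basin, with the median over 10 seeds reported;
`scripts/acceptance.R` recomputes these from scratch together with a
label-permutation baseline context for the control.

Other numerical details: slope comparisons in the ABC boundary use a
relative tolerance of $10^{-9}$ so exactly-uniform inputs take the
equality branch; ABC sorting is stable (ties keep input order); ORA
results order by raw p then term id; the SOM update skips neighborhood
weights below $10^{-12}$ (a deterministic cutoff); U-matrix heights on a
planar (non-toroid) map average over the neighbors that exist.

## Limitations

The functional-abstraction surrogate and the watershed dynamics threshold
are this package's own design where the source is silent; both are
deterministic, parameterized, and documented above rather than hidden.
Counts from any real GO/DrugBank snapshot (numbers of significant terms,
shared processes, cluster sizes) depend on the snapshot and the exact SOM
schedule and are not reproduced or asserted here. The drug-target
representation is unsigned: an antagonist and an agonist of the same
target are indistinguishable, a limitation the source analysis itself
notes.
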