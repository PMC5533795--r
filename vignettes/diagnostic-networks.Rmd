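---
title: "Integrated diagnostic networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated diagnostic networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagnet)
```

# The problem

Breast tumors are routinely stratified by the status of three
immunohistochemistry markers — the estrogen receptor (ER), the progesterone
receptor (PR) and HER2 — into four clinically used classes:
[ER+|PR+]HER2−, [ER+|PR+]HER2+, [ER−|PR−]HER2+ and the triple-negative
group (TNG).  A recurring question in diagnostic biomarker work is whether
a *small* panel of genes, chosen not only for differential expression but
for their position in the protein-interaction network, can carry most of
the subtyping signal of much larger signatures.

`diagnet` implements one complete route to such a panel:

1. **Per-cohort differential scoring.**  For each candidate gene $g$ in
   each case/control cohort, a Welch-type two-sample statistic
   $$t_g = \frac{\bar X_{g1} - \bar X_{g2}}
   {\sqrt{S^2_{g1}/n_1 + S^2_{g2}/n_2}}$$
   contrasts tumor (group 1) against normal (group 2) expression, with
   sample variances on the $n-1$ denominator.  Two-sided p-values use the
   $t$ reference distribution with Welch–Satterthwaite degrees of freedom
   and are Benjamini–Hochberg adjusted *within the candidate universe*;
   genes below the adjusted-p cutoff (default 0.05) are the cohort's
   diagnostic genes.
2. **Active-subnetwork search.**  On the interaction subgraph induced by a
   cohort's diagnostic genes, a greedy seed-expansion search grows a module
   from every node and merges the ten best modules; iterating the search on
   the shrinking induced subgraph until roughly 50 nodes remain yields the
   cohort's *diagnostic network*.
3. **Consensus integration.**  Genes and edges present in at least three
   per-cohort diagnostic networks form the *integrated diagnostic network*.
4. **Pivotal-gene selection.**  Each consensus gene's *connectivity
   enrichment* $EC_j = C_{s,j} / C_{D,j}$ — its consensus-network degree
   over its degree in the full background graph — ranks genes by how
   concentrated their interactions are in the consensus network.  Break
   points in the ranked EC profile propose candidate panel sizes; a
   degree-quantile representation analysis with a permutation null checks
   that the consensus network is not simply an artifact of hub degree.
5. **Panel evaluation.**  Candidate panels are scored by cross-validated
   subtype classification (a k-nearest-neighbour reference classifier),
   panel-growth trajectories, per-gene stratification t-tests and
   hierarchical clustering.

Every stage is exercisable end to end on synthetic data with planted
ground truth, which is how the package's tests establish that the
machinery recovers what it is supposed to recover.

# Differential scoring

The statistic above is a two-sample Welch statistic and is implemented
exactly as written, even for cohorts with paired designs: the formula
ignores pairing, and a paired test would change the reference
distribution.  Ranking and selection use $|t|$, so strongly down-regulated
genes are ranked alongside up-regulated ones; the sign convention (group 1
= tumor) is only a direction label.

Genes with zero variance in both groups and unequal means have no defined
statistic; they are flagged (`flag = "zero_variance"`) and excluded from
adjustment rather than silently dropped.  The BH adjustment universe is
deliberately the candidate set, not the genome: the scoring step answers
"which of *these* candidates respond", and a genome-wide universe would
make the adjusted values depend on genes the pipeline never uses.

# The module score and the greedy search

The search needs a set function over node scores.  Three are provided:

* `sum`: $\sum_i |t_i|$.  Monotone in the node set, so a greedy search
  can never prefer a smaller module — it absorbs whole connected
  components.  Kept as a variant because it makes the absorption behavior
  explicit, but it cannot produce a succinct module.
* `norm_agg` (default): $\sum_i |t_i| / \sqrt{k}$ for a $k$-node module,
  the classic size-penalized aggregate used by active-module methods.
  Adding a node pays a $\sqrt{k}$ cost, so expansion stops where the
  frontier's scores no longer justify growth.
* `mi`: an operational mutual-information score.  A per-node scalar does
  not define the joint density a textbook mutual information needs, so the
  package defines `mi` as the mutual information between (a) equal-width
  bin membership of $|t|$ values and (b) module-vs-frontier membership,
  over the union of module and frontier.  It is provided for
  experimentation and is not used by the default pipeline.

`greedy_expand` adds, at each step, the frontier node with the largest
*strict* score increase; ties in gain are broken by lexicographic gene
symbol, and the search is therefore fully deterministic.  One expansion is
run from every node as seed (enumerating seeds removes the only potential
source of randomness in the search); the union of the ten best modules
(ties again lexicographic) is the next round's search space.  Because each
round searches the subgraph induced by the previous union, the node count
is non-increasing; iteration stops at `stop_size + stop_slack` nodes
(default 50 + 5, i.e. "approximately 50") or when the count stops
shrinking.  The final set need not be connected — it is the union of
top-ranked connected modules.

# Consensus integration and the overlap statistic

The overlap of a combination of $n$ networks is
$$\mathrm{rate} = \frac{G^{1\ldots n}}{\sum_i G^i - G^{1\ldots n}}
\times 100\%$$
with $G^{1\ldots n}$ the number of genes common to all $n$.  The
denominator is implemented in this literal sum-minus-common form.  Note
that for $n > 2$ it is *not* the union size: $n$ identical networks score
$100/(n-1)$, and only identical pairs score exactly 100.  Disjoint
networks score 0 for any $n$.

Consensus keeps a gene supported by at least $k$ networks (default 3) and
an edge supported by at least $k$ networks *whose endpoints are both
kept*; support counts are attached to the result.  Genes that survive by
support but lose all their edges are dropped by default (a connected
consensus graph), retained only on request.  Boundary cases are exact
identities: $k = 1$ is the union graph and $k = n$ the intersection graph,
and the $k+1$ consensus is always a subgraph of the $k$ consensus.

# Pivotal genes

**Degree quantiles.**  The four degree levels are the quartile intervals
of the background degrees of the selected (consensus) genes, computed with
type-1 (order-statistic) quantiles so that cutoffs are attained integer
degrees; degrees $\{1..8\}$ give $[1,2],[3,4],[5,6],[7,\infty)$.  A
selected set whose degrees cannot be split into four levels (e.g. all
equal) is a degenerate input and errors rather than returning arbitrary
bins.  `Per_i` is the fraction of background genes in level $i$ that
belong to the selected set.

**Permutation null.**  Whether the top-quartile representation could arise
by chance is tested by drawing `B` (default 1000) random gene sets of the
same size from the background without replacement and recomputing the
top-level `Per`; the p-value uses the add-one estimator
$(1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(B+1)$, which can never return
exactly 0.  The statistic depends only on the degree multiset, so the test
is invariant to gene relabelling.

**Connectivity enrichment and break points.**  $EC_j \le 1$ always, since
the consensus network is a restriction of the background.  The ranked EC
profile is scanned with a relative drop score
$(EC_i - EC_{i+1})/EC_i$; the positions of the largest drops (default
two) are candidate panel boundaries.  Genes tied in EC cannot be separated
by a break, so when a boundary gene ties with its predecessor the next
shorter panel is also proposed.  The drop score is a pragmatic
operationalization — "significant drop" has no canonical definition — and
its positions should be read as candidates to be confirmed by the
evaluation stage, not as a test.

# Gene-set enrichment

Fisher's exact over-representation p-value is the hypergeometric upper
tail $P(X \ge \mathrm{overlap})$.  The rank-deviation Z compares a term's
rank (by Fisher p) under the observed query with its rank distribution
under random queries of the same size (default 200, seeded); enriched
terms rank better than their null mean, giving negative Z.  The combined
score is $C = \log_{10}(p) \times Z$, so enrichment makes both factors
negative and $C$ large and positive; $p = 1$ gives $C = 0$ exactly.  $C$
uses the *unadjusted* p (the convention of the Enrichr family of tools);
BH-adjusted p-values across the library's terms are reported alongside.
Published tables that list adjusted p, Z and C side by side generally
cannot be reproduced from one another, which is why the package treats $C$
as an internal ranking score rather than a cross-study comparable.

The background defaults to the number of distinct genes in the library;
query genes outside that universe cannot overlap any term and are excluded
from the draw size.

# Panel evaluation

The reference classifier is a hand-specified k-nearest-neighbour vote
(k = 10 by default) with deterministic tie handling: vote ties go to the
tied class owning the single nearest neighbour, and exact distance ties
are broken by training-sample order.  The classifier interface
(`fit`/`predict`) accepts any other model — an SVM wrapper is included
when `e1071` is installed — but the package's own guarantees are stated
for KNN only.

Cross-validation classifies tumor samples into the four subtype classes.
Stratified 10-fold splits preserve class proportions within one sample per
fold and are reshuffled each repeat; leave-one-out with a deterministic
classifier has no source of variation, so requested repeats collapse to a
single run and the report says so.  A repeated-LOO spread is only
meaningful for stochastic classifiers.  Samples with discordant ER/PR
status would be assigned by ER; the synthetic generator produces
concordant ER/PR by design, so this rule is exercised only by user data.

# The synthetic-data generator

The generator is the package's instrument for making recovery claims
testable; its defaults are the reference study conditions used throughout
the tests.

* **Graph**: a preferential-attachment graph (400 genes, 2 edges per new
  node), giving the hub-dominated, heavy-tailed degree structure of
  curated interaction databases.
* **Planted module**: 40 genes grown by breadth-first search from a random
  node, hence connected by construction.  All members receive a
  tumor-vs-normal shift of `effect_size` (default 2) noise standard
  deviations, as do a random 5% of outside genes — the module is enriched
  for, not exclusive of, differential genes.  Shifts default to upward
  (`down_frac = 0`) so the generator's moment contract (mean tumor−normal
  difference equals `effect_size × noise_sd` for differential genes) is
  directly checkable; mixed-sign signatures are available via `down_frac`.
* **Pivotal genes**: 4 low-degree module members rewired so that *all*
  their interactions stay inside the module (about 8 each) — high
  within-module connectivity at modest global degree, the configuration
  the EC statistic is designed to surface.  Every other module member is
  guaranteed at least one interaction outside the module, so ordinary
  members cannot reach EC = 1.
* **Subtype structure**: tumors draw one of the four classes with
  probabilities (0.45, 0.20, 0.15, 0.20), an ER-positive-skewed mix in the
  range reported for clinical cohorts.  The four pivotal genes carry the
  patterns ER-axis, HER2-axis, TNG-marker and ER-negative-marker at 2.5
  noise-SD — magnitudes in line with strong clinical markers, and jointly
  sufficient to separate all four classes (each class pair differs in at
  least one pivotal gene).
* **Noise model**: i.i.d. Gaussian noise (sd 1) per entry plus a per-gene,
  per-cohort Gaussian batch offset (sd 0.3) shared by tumors and normals,
  emulating between-cohort platform differences without confounding the
  within-cohort contrast.

What the generator does **not** emulate: probe-to-gene mapping, missing
values, platform-specific intensity distributions, correlated noise
between genes, copy-number or methylation structure, and
cohort-confounded effects.  A pass on synthetic data therefore shows the
machinery is correct and calibrated under the stated model — it does not
by itself certify performance on any real cohort.

# Numerical and design choices

* Gene symbols are upper-cased at every ingest point; joins across
  expression, network and gene-set files use normalized symbols.
* All ties in the search (candidate gains, module ranking) break
  lexicographically; ties in EC rank by descending consensus degree first
  (among equally enriched genes, the one with more consensus interactions
  is the more central candidate), then lexicographically.  The whole
  pipeline is deterministic given its seeds.
* A single master seed drives a pipeline run, split per stage with fixed
  offsets; reruns are bit-identical (the manifest records MD5 checksums).
* Degenerate inputs error loudly: fewer than 2 samples per group, all-equal
  degrees at the quantile step, zero-variance genes (flagged), empty
  queries, background degree 0.
* A consensus network with fewer than 4 genes cannot support the quantile
  analysis; the pipeline reports `no_signal` and skips downstream stages
  instead of failing — a weak-signal run is an outcome, not a crash.
* Test problem sizes are the reference conditions (400 genes, 6 cohorts of
  30+30) for recovery checks, and a single 250-tumor cohort — the scale of
  typical public subtyping cohorts — for classifier evaluation; oracle
  comparisons run on graphs of at most 12 nodes where exhaustive
  enumeration of connected subgraphs is exact.

# Limitations

* The greedy search is a heuristic: it is bounded by, but does not attain,
  the connected-subgraph optimum in general.  The exhaustive-enumeration
  oracle in the tests verifies the bound, not optimality.
* The `mi` scoring method is an operational interpretation of a
  mutual-information module score that is not well defined for scalar
  per-node statistics; conclusions should rest on `norm_agg`.
* EC break-point positions depend on a heuristic drop score; panel sizes
  should be confirmed by cross-validation, as the pipeline's evaluation
  stage does.
* Moderated (empirical-Bayes) test statistics, paired-design tests,
  normalization and probe collapsing are out of scope; inputs are assumed
  to be processed expression matrices on a roughly log scale.
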