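---
title: "Methods: bipartite networks of regime shifts and their drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bipartite networks of regime shifts and their drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Ecological regime shifts -- large, persistent reorganizations of ecosystem
structure and function such as lake eutrophication, coral transitions, or
the collapse of ice sheets -- are driven by sets of anthropogenic and
natural variables documented in the literature. `rsdnet` analyses the
bipartite network linking generic regime shift types (rows) to their
documented drivers (columns): a cell is 1 when at least one academic
reference attributes causal influence to the driver. Three families of
questions are addressed:

1. **Co-occurrence structure.** Do drivers co-occur across regime shifts
   more than their frequencies alone would force? This is answered by
   comparing observed statistics to degree-preserving (fixed-margin) null
   ensembles.
2. **Managerial leverage.** At what scale (local, regional/national,
   international) can each driver be managed, and do co-occurring drivers
   share a scale (attribute homophily)?
3. **Similarity structure.** Which regime shifts share drivers, and which
   drivers share regime shifts (binary distances, average-linkage
   clustering, classical multidimensional scaling with permutation vector
   fitting)?

## Statistics on the bipartite network

For incidence matrix $A \in \{0,1\}^{m \times n}$ with row sums $r_i$
(shift degrees) and column sums $c_j$ (driver degrees):

* **One-mode projections.** Driver projection weight
  $w_{jk} = \sum_i A_{ij} A_{ik}$ (number of regime shifts jointly driven);
  the shift projection is the transpose construction. The projection
  **mean degree** is computed on the binarized projection: the average
  number of partners a node co-occurs with at least once.
* **Co-occurrence (open triangles).** Two same-class nodes attached to a
  common opposite-class node form one co-occurrence event; the total count
  on the driver side is $\sum_i \binom{r_i}{2}$. Three normalizations are
  returned: the raw count, the count per node pair, and the count per
  *connected* pair. The first two are fully determined by the degree
  sequences, hence constant across fixed-margin nulls; only the
  per-connected-pair form (equivalently, the mean weight of realized
  projection edges) can deviate from such a null, and it is the one used in
  null comparisons.
* **Bipartite clustering.** $cc = 4 \cdot \text{squares} / \text{three-paths}$,
  where squares are four-cycles (the bipartite analogue of closed
  triangles) and three-paths are three-link paths, both counted as
  unlabelled, non-induced subgraphs. $cc = 1$ for complete bipartite
  graphs and is undefined (flagged `NA`) when no three-path exists.
* **NODF nestedness.** For each ordered node pair with strictly greater
  degree, the paired overlap is the percentage of the smaller node's links
  shared with the larger; pairs with equal degrees contribute 0
  ("decreasing fill"). Row, column and pooled means are on the 0--100
  scale, and each node's mean overlap across its pairs is exposed for
  ordering nodes by nestedness.
* **Summaries.** Idiosyncratic drivers are those of degree 1. The
  half-coverage set is the smallest degree-sorted prefix of drivers
  (ties broken alphabetically) whose links exceed half of all links.
  Percentages are reported with integer truncation, matching the
  "~24%", "~22%" convention of narrative summaries (14/57 and 13/57).

## Fixed-margin null models

The null hypothesis is that links are reshuffled while every node keeps its
number of links. Two samplers are provided:

* **Curveball (default).** From the observed matrix, repeated trades
  between random row pairs exchange the drivers unique to each row. Each
  sample restarts from the observed matrix and applies `5 * min(m, n)`
  trades (a documented, configurable count). The trade kernel is in
  compiled code; uniformity over the margin class is verified in the tests
  by total-variation distance to the enumerated class on small matrices.
* **Sequential importance sampling (SIS).** The matrix is rebuilt column by
  column (largest column sums first); within a column, rows receive a 1
  with drafting probabilities proportional to residual row demand,
  restricted to choices that keep the residual problem Gale--Ryser
  feasible (greedy realizability: placing remaining 1s on the largest
  residual rows is feasibility-optimal). Every matrix in the class has
  positive support, and each sample carries a log importance weight
  (minus the log of its unique decision-path probability). Unweighted SIS
  summaries are approximate; the tests use self-normalized weights.

Comparisons report the standardized effect size
$z = (\text{obs} - \bar{x}_{null})/s_{null}$, an empirical p-value with the
add-one convention $(1 + \#\{\text{at least as extreme}\})/(B + 1)$ (never
exactly zero), and a two-sided one-sample t-test of the null sample against
the observed value with the direction annotated. The default direction is
chosen by the sign of the observed deviation; for calibration studies the
tail must be fixed in advance (`alternative = "greater"` or `"less"`),
because the folded automatic tail is by construction not uniform under the
null.

## Permutation tests in place of model-based terms

Model-based homophily terms (exponential random graph "node-match"
coefficients) are deliberately out of scope; the same qualitative question
-- do co-occurring drivers share management scales? -- is answered by a
label-permutation test on the weighted projection: the observed share of
total projection weight on same-label pairs is compared with the
distribution obtained by permuting labels over nodes (one-sided, add-one
convention). The test is exact under exchangeability and its calibration is
verified by simulation. Vector fitting on ordinations follows the same
logic: each variable is regressed on the ordination coordinates, $r^2$ and
the normalized coefficient direction are reported, and significance comes
from permuting the variable's values.

## Distances, clustering, ordination

Sorensen--Dice ($1 - 2|A \cap B|/(|A|+|B|)$) is used between regime shifts
and Jaccard ($1 - |A \cap B|/|A \cup B|$) between drivers; both reward
shared presences rather than shared absences, appropriate for co-occurrence
data. Average-linkage (UPGMA) clustering is implemented in the package with
a documented deterministic tie rule -- clusters are represented by their
lexicographically smallest leaf and tied merges take the lexically smallest
representative pair -- because binary distances on small networks are full
of exact ties, and a tie policy left to a library would make trees depend
on input order. The implementation agrees with `stats::hclust` on tie-free
matrices and with an independent naive implementation (same tie rule) on
random instances. The ordination is classical (metric) scaling: squared
distances are double-centred and eigendecomposed, axes with nonnegative
eigenvalues are kept, negative eigenvalues are reported unused. Non-metric
MDS is out of scope; the literature being followed says only
"multidimensional scaling", and the metric form is deterministic and
testable. Whether the "average method" of that literature is UPGMA or
WPGMA is likewise unstated; UPGMA is used and documented.

Categorical variables describing regime shifts come in thematic blocks
(ecosystem processes, 5 variables; provisioning services, 8; regulating
services, 8; cultural services, 4; drivers, 10; land use, 11; scales, 8;
reversibility, 3). Block distances drop all-zero columns first and use
Sorensen--Dice on the binary profiles.

## The worked example

The packaged fixture transcribes a published summary table of 25 generic
regime shift types with three *selected* drivers each (75 links) and the
ecosystem type of each shift. It is a strict subnetwork of the public
regime shifts database (which averages around 11 drivers per shift), so it
serves as a worked example and regression anchor -- 25 shifts, every shift
of degree 3, and canonical "climate change" linked to 9 shifts -- not as
the full dataset. A curated synonym map (case folding, ENSO/NSO, spelling
variants) ships alongside the raw transcription and is applied only on
request, keeping the transcription auditable. Headline numbers that depend
on the full database (57 drivers, mean degree 11.2, driver frequencies
19/17/15, the 62%/38% split of management scales) are not reproducible
from the fixture; they are used as synthetic-generator targets instead.

## What the synthetic generator emulates

`generate_rsdb_like()` produces a dataset with the full database's
statistical shape: 25 shifts x 57 drivers, mean shift degree 11.2, exactly
14 idiosyncratic (degree-1) drivers, 15 mutually exclusive detailed driver
categories aggregated into 5 broad ones, three management scales with
planted homophily, ecosystem types, and binary categorical blocks of the
sizes listed above.

The bipartite generator works in two stages. Shift degrees are drawn from
a link-probability surface logistic in the product of scaled row and
column ranks, with the intercept calibrated by root finding so the
expected mean shift degree hits its target at any nestedness strength.
Link *selection* then uses weights `(surface x group affinity)^sharpness`,
where shifts and drivers belong round-robin to three groups, the affinity
multiplier is `1 + 1.4 s` and the sharpness exponent `1 + 0.4 s` for
nestedness strength `s`. This yields a shared core of generalist drivers
plus group-specific nested driver pools. The design is deliberate: an
independent-cell surface alone, conditioned on the margins, can tilt the
margin class only towards specialist--generalist alignment -- it raises
NODF but *lowers* four-cycle clustering and spreads co-occurrence over
more pairs, the opposite of what real driver networks show. Redundant
driver pools (regime shifts sharing driver sets, as ecosystem groups do in
the real database) are what elevate clustering and concentrate
co-occurrence, and they require dependence between cells. At `s = 0` both
knobs are inactive and filling is independent and uniform (no planted
order). Idiosyncratic drivers are planted by pruning the lowest-degree
columns to degree 1, keeping one of their existing links (attachment
elsewhere would misalign them relative to the null and depress NODF);
other columns are kept at degree at least 2, and links are topped up
towards the target count outside the idiosyncratic columns. The degree
distribution beyond these constraints is an assumption of the generator,
not an estimate from data.

Homophily planting is two-level. A latent scale field is laid over the
regime shifts by breadth-first copying on the shift projection with
probability $h^4$ (innovations draw the currently least-used scale --
balancing innovations are independent of adjacency, so the $h = 0$ null
remains exchangeable); each driver then adopts the majority latent scale
among its own shifts with probability $h$, else uniform. At $h = 1$ every
projection component is label-pure; at $h = 0$ labels are iid uniform; at
intermediate strengths labels stay balanced while label agreement
concentrates on strongly co-occurring pairs. Single-level "copy a
neighbour's label" schemes were rejected: on a dense, nested projection
they collapse to one global label, which a count-conditioned permutation
test cannot distinguish from chance regardless of the true copying rate.

The synthetic *shift* categorical blocks are unstructured noise: vector
fitting on synthetic ordinations therefore finds only false-positive-rate
alignments, which demonstrates calibration, not effect recovery. Passing
tests on synthetic data show that the machinery detects the structures the
generator plants at the study's scale; they do not show that the real
database contains those structures, nor that real driver degree
distributions follow the generator's rank surface.

## Numerical choices and degenerate inputs

* Problem sizes in the test-suite: null ensembles of 49--200 samples for
  calibration (Kolmogorov--Smirnov over 200 replicates), 100 samples per
  seed and 100 seeds for planted-structure recovery, 10,000--100,000
  draws for sampler uniformity on enumerable margin classes, and full
  enumeration of all binary matrices up to 4 x 4 for oracle equivalence.
  Study-scale defaults (10,000 null samples, 999 permutations) remain the
  function defaults.
* Empirical and permutation p-values use the add-one convention
  throughout, so they are never zero and are valid (slightly
  conservative) under ties.
* Clustering is flagged `NA` (attribute `undefined`) when no three-path
  exists; SES is `NA` when the null standard deviation is zero, with the
  empirical p still reported.
* Duplicate edge-list records collapse to one link and are counted in an
  attribute; networks with empty rows/columns load with a warning naming
  the nodes, since downstream distance functions must refuse them
  explicitly.
* Canonicalization requires an idempotent synonym map (no chains or
  cycles); merging into an existing driver name is allowed -- it is the
  operation's purpose.
* The master seed of `run_full_analysis()` derives per-stage seeds by a
  stable hash of the stage name, so disabling one stage does not shift
  another stage's random stream.

## Known limitations

* The per-pair co-occurrence index is margin-determined; against
  fixed-margin nulls only the per-connected-pair variant is informative.
  Fig-1-style comparisons in other software may use yet another
  normalization; the raw count is always returned so any monotone variant
  can be recomputed.
* SIS importance weights are exposed but default summaries are unweighted;
  for strongly heterogeneous margins the weighted form should be used.
* The homophily test conditions on label counts; it has no power against
  "homophily" that manifests purely as one global consensus label.
* Driver directedness (steps to feedback) is carried as an attribute but no
  directed analysis is performed, matching the descriptive use in the
  source literature.
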