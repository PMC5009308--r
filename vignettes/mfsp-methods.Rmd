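---
title: "MFSP: path-based miRNA functional similarity — model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MFSP: path-based miRNA functional similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsimpath)
```

## The model

`mirsimpath` scores the functional similarity of two miRNAs by how
strongly their associated disease sets are connected *through* a disease
similarity network, rather than by directly aligning the two sets.
The underlying assumption is the usual one for association-based
similarity: miRNAs with similar functions tend to be implicated in
similar diseases, and disease similarity itself is encoded by position
in a curated hierarchy.

**Disease encoding (CSD).** The ontology is given as MeSH-style dotted
tree codes; every proper prefix of a code denotes an ancestor position,
and one disease may hold several codes. A disease $d$ becomes a sparse
vector $V_d$ over the disease set: the entry for an ancestor $i$ at
shortest distance $\delta(i, d)$ is $1/(\delta + 1)$, the entry for $d$
itself is $1$ ($\delta = 0$), and non-ancestors are zero. $\delta$ is
minimized *globally* over all (descendant code, ancestor prefix)
matches; with the two hepatocellular-carcinoma codes, the upward paths
to Neoplasms have lengths 4 and 5 and the encoding takes $1/(4+1)$.
Including the disease itself at weight 1 makes identical diseases score
cosine 1 and is the $\delta = 0$ case of the same formula. Disease
semantic similarity is then the standard cosine
$\mathrm{CSD}(d_i, d_j) = V_{d_i} \cdot V_{d_j} /
(\lVert V_{d_i}\rVert \lVert V_{d_j}\rVert)$, and the matrix
$S \in [0,1]^{|D| \times |D|}$ is positive semidefinite by construction
(a Gram matrix of unit-normalized nonnegative vectors).

**Walk propagation.** The $i$-th transferring matrix is $M_i = S^i$:
its $(p, q)$ entry is the summed weight of all length-$i$ walks from
$p$ to $q$, with the weight of a walk being the product of its edge
weights. Walks (not simple paths) are used deliberately: the matrix
power is exactly the "sum of $i$-length path weights" being described,
it keeps every $M_i$ symmetric, and it is cheap; forbidding repeated
vertices would make the quantity NP-hard and break symmetry of the
accumulation. Self-loops via the unit diagonal of $S$ are retained as a
consequence of cosine self-similarity 1.

**Path matrix and score.** With the binary association matrix $R$,
$$P = \sum_{t=1}^{b} a^{t} \, R\, M_t\, R^{\top},$$
Katz-style damping with weight ratio $a \in (0, 1]$ starting at
$t = 1$: a $t = 0$ term would reduce to raw association-set overlap and
defeat the point of a path-based measure. No normalization of the
damping weights is applied; the final score
$$\mathrm{MFSP}(i, j) = \frac{2\,P(i,j)}{P(i,i) + P(j,j)}$$
is invariant to any global rescaling of $P$, so a normalizer would be
unobservable anyway. For PSD $S$ the score lies in $[0, 1]$
(by the arithmetic–geometric mean bound
$P_{ij} \le \sqrt{P_{ii} P_{jj}} \le (P_{ii} + P_{jj})/2$), is
symmetric, and has self-similarity exactly 1 whenever $P(i,i) > 0$.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `a` (weight ratio) | 0.6 | damping per extra walk step, in (0, 1]; larger values let remote disease relationships contribute more |
| `b` (max transferring times) | 5 | walk-length cap; the normalized scores stabilize around 5 (below) |
| network threshold | 0.7 | strict cutoff for adding an edge to the miRNA functional network |
| cluster cutoff | 50 kb (sweep 10–100 kb) | single-linkage genomic gap for grouping miRNA loci into clusters |
| expression threshold grid | 0 to 1, step 0.05 | MFSP cutoffs for the expression-correlation curve |

**Convergence in `b`.** Every entry of $P$ is non-decreasing in $b$
(all added terms are nonnegative). The *raw* path weights do not
converge in general: the step-$t$ increment scales like
$a^t \lambda_{\max}(S)^t$, and for realistic CSD matrices
$a\,\lambda_{\max}(S) > 1$ (on the default fixture
$\lambda_{\max} \approx 7$). What stabilizes is the normalized MFSP
score: as $S^t$ aligns with its dominant eigenvector, numerator and
denominator of the score grow at the same rate and their ratio
converges geometrically at roughly $\lambda_2/\lambda_1$ per step. On
the default fixture the mean absolute score change drops from
$\approx 0.13$ between $b = 1$ and $2$ to $\approx 0.035$ between
$b = 5$ and $6$; the test suite asserts this stabilization (bound 0.05,
and at most half the early-step change) rather than convergence of $P$
itself.

## Degenerate inputs and numerical choices

* Tree codes are validated (`dotted alphanumeric`); a code mapped to two
  disease names is an error naming both; associations to diseases
  absent from the ontology are dropped with a message listing them, and
  the affected miRNA keeps an all-zero row rather than aborting the
  pipeline (association files routinely contain ontology-orphaned
  records). Zero-row miRNAs get similarity 0 to everything, with a
  warning, and self-similarity 0 (not 1).
* A disease with no codes has a zero feature vector; cosine similarity
  raises an error rather than silently returning 0/0.
* All intermediate matrices are symmetrized as $(X + X^\top)/2$ after
  computation and symmetry/PSD assertions use a $10^{-9}$ relative
  tolerance; a negative entry in $P$ aborts (it can only arise from a
  corrupted upstream matrix).
* Similarities are kept at full double precision; 4-decimal rounding is
  display-only and never feeds back into computation.
* The power-law fit regresses $\log_{10}$ counts on $\log_{10}$ degree
  over degrees with positive count (zero counts have no logarithm); a
  probability-normalized variant is reported alongside — it changes the
  intercept, never the slope. $R^2$ is computed directly from residuals
  so an exactly power-law histogram returns $R^2 = 1$ without warnings.
* Characteristic path length averages over connected pairs only
  (disconnected pairs are excluded and counted); the local clustering
  coefficient of degree-< 2 nodes is 0. Isolated miRNAs are dropped
  when the network is built from the threshold rule.
* Genomic distance between two loci is the gap between the intervals
  (0 if they overlap), not a midpoint distance; clustering is
  single-linkage over gaps $\le$ cutoff, implemented via interval
  merging (`GenomicRanges::reduce` with `min.gapwidth = cutoff + 1`).
  Same-strand linkage is required by default (polycistronic clusters
  are co-transcribed) and exposed as a flag.
* The Wilcoxon implementation uses exact enumeration for tie-free
  samples of at most 20 observations and the tie-corrected normal
  approximation otherwise; p-values below double precision are flagged
  as underflow instead of being printed as 0.
* The random benchmark group defaults to
  $\min(|\text{intra}|, 10^4)$ pairs and requires an explicit seed.

## The synthetic-data generators

The generators exist so every stage is testable offline with known
ground truth; their defaults define the conditions under which the
package's claims are exercised: a 100-disease ontology (depth 4,
branching 4, 10% of non-root diseases holding a second code in another
subtree), 50 miRNAs with ~5 associated diseases each, 10 families, and
a 40-tissue expression panel.

* **Ontology**: a rooted multi-tree of dotted codes built breadth-first;
  second codes emulate multi-position diseases.
* **Associations**: each miRNA samples its diseases from the subtree of
  an anchor disease; same-family miRNAs share the family anchor with
  probability $e/(1+e)$ where $e$ is `planted_effect`, so intra-family
  pairs have overlapping neighborhoods in expectation. With
  `planted_effect = 0` anchors are independent of the family labels —
  the null of the benchmark tests.
* **Loci**: planted genomic clusters with within-cluster gaps < 10 kb
  and between-cluster gaps > 100 kb, so a 10–100 kb cutoff sweep
  recovers exactly the planted partition.
* **Expression**: Gaussian profiles drawn with target correlation
  `expression_coupling × MFSP`, via the eigenfactor of the PSD-clipped
  target matrix.

What the generators do *not* emulate: the code-length and branching
statistics of the real MeSH disease branch, the heavy-tailed
disease-degree distribution of curated association databases (which is
what makes real miRNA networks scale-free — the dense 50-node fixture
network is not), database-specific naming idiosyncrasies, and
measurement noise structure of real expression compendia. Passing tests
therefore demonstrate correctness of the computations and recoverability
of planted effects, not performance claims on the real databases.

## A calibration caveat

The benchmark protocol applies a two-sample rank test to *pairwise*
similarity scores, which are not independent: intra- and inter-group
scores are built from the same miRNAs, so shared row effects positively
couple the two group means. Under the pipeline null
(`planted_effect = 0`) the rank-sum test is conservative — across 200
generated datasets it rejects at about 1.5% instead of the nominal 5%
(the corresponding expectation in the test suite documents this by
failing the nominal-band check). On i.i.d. samples the same test is
correctly calibrated (verified by simulation at $n = 50$, 1000
replicates). Interpreting the benchmark p-values as exact frequentist
error rates is therefore optimistic in structure, though the direction
of the conservatism means significant results are trustworthy.

## Problem sizes used by the test suite

Unit and property tests run on ontologies of 30–100 diseases and 12–50
miRNAs; the walk-enumeration oracle checks use $|D| \le 5$, $b \le 3$
where exhaustive enumeration is exact; the null-calibration study uses
200 generated datasets. These sizes were chosen so the full matrix
algebra, network statistics and rank tests are exercised end to end
while each property remains checkable against a brute-force oracle.

## Known limitations

* MFSP depends on the association snapshot: a miRNA's score profile is
  only as informative as its curated disease list, and zero-association
  miRNAs are uninformative (scored 0 by convention).
* The measure is blind to disease-association *sign* or strength —
  associations are binary.
* Comparator disease-similarity measures (DAG semantic-contribution and
  information-content variants) are out of scope; the included
  comparator is CSD combined with best-match-average aggregation.
* Random-walk-based disease–miRNA prioritization and clique-percolation
  module discovery are downstream applications, not part of the
  package.
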