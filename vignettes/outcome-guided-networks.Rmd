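---
title: "Outcome-guided mutual information gene networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outcome-guided mutual information gene networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oginet)
```

## The problem

Most gene-level survival analyses in cancer genomics ask whether a single
gene's expression, copy number or methylation level separates patients
with poor outcome from the rest, or fit additive multi-gene models such
as penalized Cox regression.  Both miss *interaction* effects: pairs of
genes whose joint state is strongly associated with outcome even though
each gene alone shows little or no marginal association (the canonical
example being an XOR-like pattern, where each marginal is exactly
uninformative).  `oginet` scans all gene pairs of one or more genomic
profiles for such effects, controls significance with a
permutation-derived threshold, and organizes the detected pairs into
*outcome-guided networks* — graphs in which an edge does not mean
"these genes are correlated" but "this pair's joint state is informative
about the clinical outcome".

## The score

All variables are made discrete.  A profile feature partitions the
patient cohort $S$ into blocks $A_1,\dots,A_n$ (one per code value), and
entropy is computed from block proportions in bits:

$$H(X) = -\sum_i \frac{|A_i|}{|S|}\log_2\frac{|A_i|}{|S|},$$

with joint entropy defined on cell-wise intersections of partitions and
extended to any number of features.  The pair score is the extended
mutual information

$$I(X_1,X_2;Y) = H(X_1,X_2) + H(Y) - H(X_1,X_2,Y),$$

where $Y$ is the binarized outcome.  It is non-negative, bounded by
$H(Y)$ (at most 1 bit for a binary outcome), symmetric in the two genes,
and never below either single-gene mutual information — all properties
the test suite checks against a brute-force contingency oracle.
Conventions: $0\log 0 = 0$; base-2 logarithms throughout.

## Discretization

Continuous features are histogram-binned per gene into $B$ equal-width
bins over that gene's observed range (interval
$(\max V_i - \min V_i)/B$).  The default $B = 5$ matches the five GISTIC
copy-number levels $\{-2,\dots,2\}$, which pass through with an
order-preserving shift onto codes $0..4$ so every profile shares one
code space.  Two boundary choices are deliberate: the last bin is
closed (a value equal to the gene maximum belongs to bin $B-1$), and a
constant gene keeps a single bin (entropy 0) rather than being dropped.

The outcome is binarized at $C$ months of overall survival (default
36): patients who died within $C$ months are `short`, patients observed
beyond $C$ months are `long`.  Patients whose label would be ambiguous
are excluded: unknown status or follow-up, and patients alive with
follow-up at or below $C$ — a patient alive at exactly $C$ months can
be assigned to neither class, so we exclude them (the conservative
reading of the filtering rule).

## Preprocessing

Profiles are aligned on a shared, complete gene-by-patient universe by
three sequential filters: genes entirely unmeasured in a profile are
removed; patients with all values missing in any profile are removed;
and finally any gene still carrying a missing value in any profile on
the remaining patients is removed, leaving the common gene set.
Orderings are sorted, so the result does not depend on input order, and
a second pass changes nothing.  Missing cells are recognized by the
tokens `""`, `"NA"` and `"NaN"` (configurable).  No imputation is
attempted — a gene must be completely observed to be scanned.

## The permutation threshold

The null distribution of the plug-in MI is not available in closed
form, and with $\binom{P}{2}$ simultaneous pair tests a parametric
approximation would be fragile.  Instead the outcome labels are
permuted (class sizes preserved) $30$ times; one permuted vector per
run is shared by *all* pairs, and the per-pair null score is

$$I_{avg}(i,j) = \frac{1}{30}\sum_{p=1}^{30} I(g_i,g_j;Y_p),$$

with threshold $\theta = \max_{i\neq j} I_{avg}(i,j)$.  Networks at
significance level $\alpha \ge 0$ use the working threshold
$\theta(1+\alpha)$; an edge requires $I(g_i,g_j;Y) \ge \theta(1+\alpha)$
(the `>=` of the formal definition; a `strict` flag switches to `>`).
Raising $\alpha$ can only remove edges, so pair counts are
non-increasing along the $\alpha$ grid (default
$\{0, 0.1, 0.5, 0.8, 1\}$).

What does $\theta$ guarantee?  It is the largest value the *averaged*
null could produce.  Because averaging 30 permutations shrinks the
spread of the null score roughly $\sqrt{30}$-fold, $\theta$ lands high
in the bulk of the single-draw null distribution but not in its extreme
tail: on pure-null synthetic data at our reference size (60 genes,
200 patients) we measure $\theta$ near the 83rd–90th percentile of the
real-label MI values, with 10–17% of null pairs at or above
$\theta$ and under 1% above $\theta(1.5)$.  The $\alpha = 0$ network is
therefore a permissive screen; the scaled thresholds are where null
pairs are pruned, which is why the topology analyses below focus on
$\alpha > 0$.

Determinism: every permutation stream is driven by an explicit seed;
per-profile scans in the pipeline use independent sub-seeds drawn from
the master seed.  Identical seed and inputs give bit-identical
thresholds, pair lists and report files.

## Networks and integration

Per profile and per $\alpha$, selected pairs become an undirected
simple graph whose nodes are exactly the edge endpoints.  Across
profiles two integrations are formed: the co-occurrence network
(edge in *every* profile network, each at its own profile-specific
$\theta$) and the one-or-more-occurrence network (edge in at least
one).  Merged edges keep the maximum MI and the union of source tags.
By construction the intersection is contained in every profile network,
which is contained in the union — a containment the suite
property-tests on random graph triples.

Topology summaries report vertices, edges, connected components,
largest component, and a scale-freeness index: the $R^2$ of the OLS
regression of $\log_2 p(k)$ on $\log_2 k$ over observed degrees, where
$p(k)$ is the fraction of nodes with degree $k$.  Degrees that do not
occur are simply absent (no zero-frequency log terms, no degree
binning).  The log base is irrelevant to $R^2$; with fewer than two
distinct degrees the index is undefined and reported as `NA` (two
distinct degrees fit a line exactly, giving 1.0).

## Survival validation

A detected pair is validated on the patients themselves.  With
$\rho$ = cohort-wide fraction of short-term survivors, every occupied
cell of the pair's $B \times B$ code grid is called high-risk when its
own short-term fraction strictly exceeds $\rho$ (a cell exactly at
$\rho$ is low-risk), in the manner of multifactor-dimensionality
reduction.  Patients inherit their cell's label, giving two groups
whose survival curves are compared with the standard two-group log-rank
test (hypergeometric observed-vs-expected at each death time, $\chi^2$
reference with 1 df) via `survival::survdiff`; Kaplan-Meier curves come
from `survival::survfit`.  Survival records use the original follow-up
times with living patients censored; deaths beyond $C$ remain events.
Single genes are validated the same way (the single-gene stratification
is the exact degenerate case of a constant second vector), so the
report can contrast pair p-values with marginal ones.

## The synthetic generator

The generator exists so the entire pipeline — parsers included — can be
exercised and calibrated without any external data.  Its defaults are
the package's reference simulation conditions: 60 genes by 200
patients, one continuous profile, a planted XOR pair at penetrance 0.9,
$B = 5$, $C = 36$, 30 permutations.

* **Planted mechanism.** The two planted genes receive bimodal values
  around a hidden binary state assigned in *exactly balanced* quadrants
  (as close to $n/4$ patients per state combination as $n$ allows).
  The outcome label is the XOR parity of the two states, flipped with
  probability $1-\text{penetrance}$.  Balance makes each planted gene's
  marginal association exactly zero by symmetry at penetrance 1 — the
  pure-interaction structure the scan is designed to find.  `and` and
  `marginal` models are available for contrast.
* **Survival times.** Short-term patients draw an exponential death
  time (hazard 1/12 per month) truncated to $(0, C]$; long-term
  patients survive to $C$ plus an exponential residual (hazard 1/36) —
  a 3:1 hazard contrast.  Independent uniform censoring on $(0, 120]$
  months hits 20% of patients, and a censored short-term patient
  becomes exactly the kind of ambiguous record the preprocessing
  filters must drop.
* **Missing values** are injected uniformly at a configurable rate,
  but never on planted genes: the completeness filters would otherwise
  remove the planted pair by design, and the generator's job is to
  control where signal exists.

What the generator does *not* emulate: realistic gene-gene correlation
structure, copy-number segment geometry, or methylation beta-value
distributions.  Passing tests therefore demonstrate that the method
recovers the statistical structure it targets under clean conditions —
not that it will attain any particular power on real tumor cohorts.

## Problem sizes and cost

The scan is $O(P^2 N)$ per label vector with $P$ genes and $N$
patients.  The default test and acceptance workloads use 60 genes by
200 patients with 30 permutations (about 1,770 pairs by 31 label
vectors, roughly half a second per replicate), 20-seed recovery
batteries, 1,000-instance oracle sweeps, and 2,000-replicate
permutation calibration of the log-rank test.  For larger inputs the
pipeline exposes a gene cap (`max_genes`) so a desk-scale run stays in
minutes; full transcriptome scans are a matter of hours in compiled
implementations and are out of scope here.

## Known limitations

* The plug-in MI is biased upward at small cell counts; the
  permutation threshold absorbs this bias (it is present under the null
  too), but reported MI values are not bias-corrected.
* Equal-width binning is the only discretization offered; adaptive or
  density-based estimators are out of scope.
* The log-rank test uses the standard large-sample approximation with
  the usual ties handling, not an exact test.
* No multiple-profile patient weighting: integration is pure edge-set
  arithmetic.
* Cox-regression extensions and GO-enrichment of network components are
  downstream analyses outside the package; networks export to SIF and
  GraphML so such tools can consume them.
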