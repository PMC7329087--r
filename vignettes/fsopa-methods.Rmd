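---
title: "Compression phylograms, ranked subsets and survival models: the methods behind fsopa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compression phylograms, ranked subsets and survival models: the methods behind fsopa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsopa)
```

## The problem

Given a raw table of mixed-type columns — numbers, categories, dates,
administrative codes, with missing cells — and one column that scores each
sample against a goal (the *criterion*; the motivating example is hospital
length of stay, LOS, in a psychiatric-care registry), which columns carry
information about that goal? `fsopa` answers this as a *feature
sensitivity* analysis: instead of fitting a supervised model to the raw
mess, it asks which features change their *relationships to other
features* between the samples that score best and the samples that score
worst.

The pipeline has four stages:

1. **Ranked sampling.** Samples are ranked by the criterion and the head
   and tail of the rank are kept at three selection-pressure levels
   (s = 2, 4, 8), giving six subsets `B2C`, `W2C`, `B4C`, `W4C`, `B8C`,
   `W8C` of sizes floor(n/2), floor(n/4), floor(n/8).
2. **Model construction.** Each subset is summarised as a *phylogram*
   whose leaves are the table's columns: every column becomes a text
   object (its cells in subset order), pairwise dissimilarities are
   normalized compression distances (NCD), and the tree is built by
   neighbor joining, with fast greedy modularity communities attached as
   metadata.
3. **Sensitivity extraction.** For each pressure level, the best-subset
   tree and worst-subset tree are each split into two clades at the middle
   of their longest path, clades are paired by congruence, and two lists
   are read off: the clade-based list (leaves whose sibling sets changed
   between the paired clades) and the target-based list (the target
   feature plus its sibling subtrees in both models). Their union over
   categories is the selected set *r*.
4. **Evaluation.** Candidate lists are compared by Cox
   proportional-hazards models under forward-AIC selection, normalized
   AIC, and a non-dominated (Pareto) comparison over (number of features,
   normalized AIC), with an elbow heuristic to suggest a single model.

An optional resampling layer (RS1–RS6) repeats the selection on
column-constrained versions of the table (missing-value filter, role
filter, stable-clade removal) and intersects the outcomes into common,
novelty and union lists.

## Normalized compression distance and its serialization

For byte objects x and y with compressed sizes C(x), C(y) and C(xy) for
the concatenation,

NCD(x, y) = (C(xy) − min(C(x), C(y))) / max(C(x), C(y)).

NCD needs no type model: a column of diagnosis codes and a column of ages
are compared through whatever regularities the compressor can exploit.
This is the property that lets the method run on a raw table "as found",
with no imputation, encoding or scaling — which is also the package's
policy: the reader validates structure but never transforms values.

Choices that matter:

* **Serialization.** A column object is the raw cell strings over the
  subset rows, newline-joined, in subset rank order; missing cells become
  the sentinel token (`"NA"` by default). Because all columns of one
  subset share the same row order, the compressor can pick up
  co-variation between columns; row order is therefore treated as
  significant everywhere and never silently resorted.
* **Symmetry.** Compressors are not exactly symmetric in concatenation
  order, so the pair is always concatenated in lexicographic order of the
  object names, making `ncd(x, y) == ncd(y, x)` exact. The matrix
  diagonal is 0 by convention.
* **Compressor.** `gzip` (zlib) is the default, with `bzip2` and `xz` as
  pluggable alternatives; per-object compressed sizes are cached across
  the O(l²) pair loop. The gzip window (32 kB) comfortably covers the
  concatenated payloads at the subset sizes used here; for tables whose
  serialized columns are much longer than the window, `xz` is the better
  choice.

## Neighbor joining and communities

The phylogram is classical Saitou–Nei neighbor joining on the NCD matrix
(`ape::nj` behind the package's interface). Two details are added: the
two-leaf base case, and clamping of negative branch lengths to zero with
the deficit moved to the sister branch, preserving path lengths through
the parent. On additive matrices NJ is exact, which the test suite
exercises by regenerating random binary trees (4–12 leaves) and checking
entrywise path-length reconstruction to 1e-9. Branch lengths are carried
for reporting, but all downstream procedures measure the tree in *edge
counts* only, so the clamping policy cannot affect selection.

Communities are computed with fast greedy modularity maximization
(`igraph::cluster_fast_greedy`) on the unweighted tree graph and reported
as metadata, honouring the model-construction recipe; the sensitivity
procedures use the explicit middle-path split below, not the communities.
On small fixture graphs the greedy partition is verified against
brute-force enumeration of all partitions; the star and complete graphs
are kept in the suite as known cases where the greedy merge path misses
the optimum — a documented property of the greedy algorithm, not a
defect.

## The middle split, congruence pairing and sibling sets

The longest (diameter) path of each tree is found by edge count, with
ties broken by the lexicographically smallest (start, end) leaf pair —
this matters because NCD trees frequently have several equally long
paths, and reproducibility requires a canonical choice. If the diameter
has 2k+1 edges the middle edge is unique; with 2k edges both middle
candidates are carried forward and the one giving the higher downstream
congruence wins, remaining ties going to the pairing with the fewest
unshared leaves and then to a lexicographic key.

Cutting the middle edge yields two clades per tree, each *rooted at the
cut point* — the only rooting the procedure itself induces, and the
definition this package adopts for "sibling" on an otherwise unrooted
tree: the sibling set of leaf x is the set of leaves in the subtree
hanging from the other side of x's parent, looking away from the root. A
singleton clade has an empty sibling set.

For each category the best-model and worst-model clades are paired by
congruence (shared-leaf count). The clade-based procedure then selects,
within each pair, the leaves present in both clades whose sibling sets
differ; leaves present in only one clade of a pair cannot be compared and
are recorded as `unpaired` in the provenance rather than selected. The
target-based procedure reuses the same splits: in the best and worst
clade containing the target it takes the target plus the leaves of its
sibling subtree, and unions the two selections; with several targets the
per-target lists are unioned. The packaged toy examples — a rearranged
cherry giving the clade list {A, B}, and a target whose sibling subtree
grows from {B} to {B, C} giving the target list {A, B, C} — are encoded
as `toy_phylograms()` fixtures and asserted verbatim in the tests.

The criterion column itself participates as a leaf by default (it is the
natural first target for the target-based procedure); because using the
ranking key as a Cox covariate would be circular, the pipeline always
excludes the criterion, duration and event columns from the candidate
list handed to the survival stage, and `select_features(columns = ...)`
lets the user exclude it from the trees entirely.

## Resampling layer

* **RS1** drops columns whose missing fraction is *strictly* greater than
  0.85 (a column at exactly 0.85 is kept). Criterion, duration and event
  columns are never dropped by any filter — without them the pipeline
  cannot continue, so protection is built in rather than left to the
  caller.
* **RS2** drops columns by annotated role (defaults: `date`, `code`).
  Role annotations come from the configuration, not from name heuristics:
  which columns are "dates" or "codes" encodes human judgment, and making
  it explicit keeps the filter reproducible and portable.
* **RS3** removes *stable* features: never selected by the clade-based
  procedure in any dataset, and sitting in a middle-split clade whose
  leaf set (restricted to the shared features) is identical across all
  datasets and all six trees. This is the strictest checkable reading of
  "clades preserved across resamplings"; an explicit drop-list can
  override it.
* **RS4/RS5/RS6**: a feature selected in ≥ 2 of the three resamplings is
  *common* (RS4) if also selected from the full table, *novelty* (RS5)
  otherwise; RS6 is their union. The 2-of-3 threshold is fixed.

## Cox stage

The hazard model is h(t, X) = h0(t) · exp(Xβ). Fitting uses the partial
likelihood with the Efron tie correction — day-granular durations make
ties certain — through `survival::coxph`; an independent minimal Newton
maximizer of the textbook partial likelihood, written from scratch in the
test helpers, confirms the log partial likelihood to 1e-6 on untied
fixtures. AIC is −2·logPL + 2k with k the number of estimated
coefficients *after* encoding (a 3-level factor contributes 2), and
categorical covariates are one-hot encoded against their modal level.

Forward selection scans the candidate list in order (the selection
output's order by default), keeping a covariate only if AIC strictly
decreases. Two policies keep the AIC comparisons honest: all fits in one
forward pass share the complete cases of the *full* candidate set, so
steps are compared on the same sample; and models compared across lists
are refit on common rows before their AICs are compared. Normalized AIC
divides by a reference (the maximum AIC among the compared models by
default). The Pareto front over (feature count, normalized AIC) uses weak
dominance with at least one strict inequality; the elbow suggestion
normalizes both coordinates to [0, 1] over the front and takes the point
closest to the ideal corner, ties going to fewer features. The distance
rule is the package's own concretization of "the elbow of the front";
with a front containing a null model it can legitimately point at zero
features, which is a statement about the front's shape, not a
malfunction.

## Synthetic data: what it emulates and what it does not

`generate_table()` builds an EHR-like table with a known answer:
standard-normal numeric covariates stored at one decimal (the precision
of typical clinical scores), uniform 3-level categorical covariates,
date-like and ICD-style code-like distractor columns, and MCAR
missingness (5% per feature column by default). The outcome follows the
Cox law with an exponential baseline (rate 0.1/day, a 10-day mean stay at
the covariate origin), an independent exponential censoring time whose
rate is calibrated by root-finding so the expected censored fraction
matches the request (20% by default), and a length of stay recorded in
whole days (`ceiling`), which is how hospital systems record stays and
which deliberately creates the tied event times the Efron correction is
there for. Because the Cox partial likelihood depends on durations only
through their ranks, the day rounding costs a little information but
introduces no systematic bias; the recovery tests confirm coverage at
n = 2000.

Default effect sizes are β = 1 per informative numeric column and
per-level effects (0, 0.8, 1.6) for informative categorical columns —
strong signals, chosen so that the best/worst subsets genuinely differ in
their covariate distributions. The default shape (2 informative numeric +
3 informative categorical + 15 mixed noise/distractor columns, n = 2000)
is the reference condition under which the end-to-end recovery properties
are tested: the selected set contains most of the informative columns
across seeds, and the forward-AIC model built from it beats models built
from random noise columns.

What the generator does *not* emulate: informative missingness (MCAR
only), realistic LOS marginals or ICD code semantics, correlated
covariates, or repeated stays per patient (every row is an independent
record, matching the hazard model as fitted). Passing tests on this data
therefore demonstrate that the machinery extracts a planted Cox signal
from a mixed-type table; they do not certify behaviour under informative
dropout or strong feature correlation, which real registries have.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately modest,
fixed sizes chosen as the smallest that exercise each property
convincingly: 100 random trees for NJ reconstruction (tolerance 1e-9),
brute-force modularity on graphs of ≤ 8 nodes, 200 random tables for the
ranking contract, 1000 random point sets against the quadratic dominance
oracle, 200 replicates at n = 2000 for effect recovery (coverage within
3 standard errors), and 25 seeds at n = 2000 for end-to-end feature
recovery. All randomness is seeded; the full pipeline is bit-reproducible
(rerunning on the same input yields identical artifact hashes, which the
suite asserts).

Degenerate inputs are handled explicitly rather than by accident: ragged
CSV rows and duplicate headers are rejected by name, rows with missing
criterion are excluded from the rank with a recorded count, a guard
(default: the s = 8 subsets must hold ≥ 10 samples) blocks degenerate
phylograms, two-leaf trees get a dedicated NJ base case, singleton clades
have empty sibling sets, edgeless graphs get modularity 0 by convention,
and single-level covariates are dropped from Cox encodings with a
warning.

## Known limitations

* NCD on high-precision continuous text is a blunt instrument; the
  generator stores one decimal for realism, but tables of
  many-significant-digit floats will compress near-independently and
  push all distances toward 1.
* Greedy modularity is not exact (see above); communities are metadata
  only.
* Forward selection is order-dependent by construction; the candidate
  order is deterministic and overridable, but a different order can give
  a different model.
* The stable-feature criterion for RS3 is one operationalization of
  "preserved clades"; other readings are defensible and an explicit
  drop-list is supported for them.
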