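---
title: "Building and verifying cluster-heatmap documents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and verifying cluster-heatmap documents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendroheat)
```

## The model

A cluster heatmap couples three objects: a numeric matrix of data points
(rows) by features (columns); one dendrogram per clustered axis — a binary
merge tree in which each inner node records the dissimilarity (`distance`)
at which its two children were joined; and optional per-row annotations
(metadata) that are displayed but never clustered. `dendroheat` computes
these objects and fixes their exchange format: a JSON document with a
`data` block (feature names plus the row dendrogram, whose leaves carry the
displayed `features` and the `objects` — original row IDs — they
represent), an optional `metadata` block keyed by leaf IDs, and an optional
`column_dendrogram` block whose leaves are features and therefore carry no
payload.

Agglomerative clustering starts from singletons and repeatedly merges the
closest pair of clusters under a linkage rule. The package exposes single,
complete, average (UPGMA), Ward, centroid, median and weighted (WPGMA)
linkage over euclidean, manhattan, correlation (1 − Pearson r), cosine and
hamming dissimilarities. All heights follow the unsquared convention: two
singletons always merge at their plain dissimilarity. Under this convention
Ward's inter-cluster distance is
$d(A,B) = \sqrt{\tfrac{2|A||B|}{|A|+|B|}}\;\lVert \bar a - \bar b \rVert$,
which reduces to the Euclidean distance for two points. Centroid and median
linkage are obtained by clustering squared Euclidean distances and taking
square roots of the resulting heights; their height sequences may contain
inversions (a child drawn above its parent), which the package tolerates
and flags with a warning, while single, complete, average and Ward heights
are always non-decreasing.

## Dual-route verification

The production path delegates the agglomeration to `stats::hclust`, the
standard, heavily exercised implementation. Correctness is nevertheless
asserted against `naive_linkage`, an independent O(n³) agglomerator that
recomputes every inter-cluster distance from its definition (pairwise
min/max/mean over members; centroid geometry for Ward, centroid, median;
the recursive midpoint rule for WPGMA) at every step. The naive route
breaks ties deterministically — among minimal pairs, the lexicographically
smallest (smaller index, larger index) cluster pair merges first — because
an oracle must be reproducible. The tie rule cannot be imposed on
`stats::hclust`, so the agreement tests draw continuous random data, where
ties occur with probability zero, and compare hierarchies in a canonical
form (each merge as its leaf set plus height, sorted) that is insensitive
to the order of equal-height merges. The geometric linkages (Ward,
centroid, median) are compared under the Euclidean metric, the only metric
for which their from-definition forms are meaningful; the graph linkages
are additionally compared under manhattan, correlation and cosine.

## Normalization and display pairing

Min-max scaling maps feature $x$ to $x' = (x - \min x)/(\max x - \min x)$,
balancing features measured on different scales before distances are
computed; a descriptor spanning hundreds of units would otherwise dominate
one spanning three. Scaling is per feature only. A constant feature yields
0/0; the package maps it to 0, which keeps output inside [0, 1] and gives
the feature zero influence on distances — the stable choice for a
degenerate column. When the user asks for original values in the display,
the pairing contract applies: the dendrogram is always built on the
normalized matrix, and only the leaves' `features` arrays carry original
values, so the row order of both runs is identical by construction.

## Row compression

To shrink a heatmap to $k$ rows the row dendrogram is cut by undoing its
$k-1$ highest (equivalently last) merges; each resulting group is
aggregated feature-wise by mean or median, and the group's original row
IDs become the reduced row's `objects`. Cutting is by cluster count, not
height, because the desired output size is what a user states. The $k$
reduced rows are then re-clustered from scratch with the same linkage and
metric to produce the output dendrogram: reduced leaves are ordinary data
items, and no collapsed-subtree encoding exists in the format. Metadata on
a compressed leaf are aggregated with the same statistic; categorical
columns take the modal label, ties broken by the lexicographically
smallest label so the result never depends on row order. A reduced leaf
still has `count` 1 — `count` counts heatmap rows, not data points; the
multiplicity lives in `objects`.

## Serialization choices

Numbers are emitted with 17 significant digits, which reproduces any
double bit-exactly on re-parsing; a `digits` option rounds for
compactness. Node order and key order are fixed (leaves by index, then
inner nodes by index; `count`, `distance`, `features`, `parent`,
`objects`, `left_child`, `right_child`), so serialization is canonical and
byte-deterministic — equal documents produce equal files. The root is the
only node written without a `parent` key. Unknown node keys encountered
when parsing are preserved opaquely and re-emitted, so documents from
richer producers survive a round trip. Leaf and node IDs are generated as
`leaf_0..leaf_{n-1}` (input row order) and `node_0..node_{n-2}` (merge
order), 0-based; user row IDs never become node IDs — they live in
`objects`. When a column dendrogram is present the feature order is
materialized: `feature_names` and every leaf's `features` are permuted
into the column tree's leaf order, so a consumer never has to apply the
permutation itself.

The validator returns violations as data (a character vector naming node
and rule), not exceptions, and the serializer and renderer refuse invalid
documents. Checked invariants: exactly one root; children and parents
mutually linked and reachable; `count` is 1 at leaves and the sum of the
children's counts elsewhere; `distance` is 0 at leaves and non-negative
everywhere; leaf `features` match the feature-name count; `objects` are
non-empty and globally disjoint; metadata keys are data leaves with value
lists of the metadata width; a column dendrogram has one payload-free leaf
per feature.

## Exploration and rendering

`leaf_order` (left-before-right depth-first traversal) defines display
order. `objects_under` answers a dendrogram-node click with the leaf and
object IDs below it; `rows_for_objects` is the inverse highlight query and
returns leaf IDs, not colours, keeping the semantics renderer-agnostic.
`cut_at` returns the $k$ subtree roots obtained by repeatedly expanding
the current root with the largest distance (ties resolved towards the
later merge), which is always a valid forest even under centroid/median
inversions.

The SVG renderer lays out the row dendrogram left, heatmap centre,
metadata right and column dendrogram on top. Branch positions are linear
in merge distance, so deeper merges sit farther from the leaves. The data
scale spans the document-wide min/max by default (per-column on request);
metadata always use their own scale, with a fixed qualitative palette for
categorical columns assigned by sorted label order. Highlights overlay the
strongest colour of the highlight scale (default `Reds`) at 35% opacity.
Coordinates are formatted with two fixed decimals, making output
byte-deterministic. Hiding the heatmap (`heatmap_visible = FALSE`) keeps
dendrogram and metadata — useful when the feature count is very large,
e.g. hashed fingerprints.

## Scaffold grouping

`group_by_scaffold` numbers scaffolds 1, 2, 3, … in order of first
appearance and preserves input order inside groups, so permuting the input
permutes numbering but never membership. The scaffold key is an injected
function: grouping is testable without any chemistry toolkit, and
`murcko_scaffold_keys` provides an optional backend that derives canonical
Murcko-scaffold SMILES through an external RDKit interpreter. Compounds
whose key cannot be derived (unparsable or acyclic structures) are listed
separately rather than errored.

## The synthetic-data generator

`make_blobs` draws `n_clusters` random centres and rescales them so the
*smallest* pairwise centre distance equals `separation * noise_sd`, then
adds isotropic Gaussian noise. `separation` is therefore a worst-case
centre spacing in noise units: 0 makes labels unrecoverable by
construction, while 50 — the setting used for the label-recovery check —
puts blobs ~50 standard deviations apart, where Ward clustering must
recover the labels exactly (adjusted Rand index 1). Defaults (5 features,
3 clusters, separation 6, unit noise) describe a modest, clearly clustered
descriptor table. The generator emulates cluster structure only: it does
not reproduce correlated descriptors, heavy-tailed columns, batch effects
or missing cells of real screening data, so passing tests demonstrate
correctness of the pipeline's algebra, not robustness to every real-world
distribution. All generators run inside a private seed scope and restore
the global random state.

## Problem sizes and numerical notes

The verification suites use the sizes at which the guarantees are
exhaustive yet quick: 200 random instances with 4–30 rows for the
linkage/oracle agreement, 200 random documents for round-trip identity, 40
points for label recovery, and a 48-combination option grid for the
validator. Height comparisons use an absolute tolerance of 1e-9;
serialization round-trips are exact. Degenerate inputs have defined
behaviour: duplicate points merge at height 0 (lexicographically first in
the oracle), constant features normalize to 0, a constant vector is
rejected under the correlation metric, and a single-row matrix cannot be
clustered. `k = n` compression produces singleton groups whose
re-clustering reproduces the original merge heights.

## Limitations

No streaming parser (documents are held in memory); no height-based
dendrogram cut; no z-score or quantile normalization; the renderer is
static by design — interactivity belongs to browser-side consumers of the
format; Ward/centroid/median under non-Euclidean metrics follow the
Lance–Williams recursions of the clustering backend but have no
from-definition oracle, so their cross-checks are Euclidean-only.
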