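# dendroheat

Hierarchical clustering and the cluster-heatmap JSON document format, in R.

The cluster heatmap — a data heatmap whose rows and columns are ordered by
dendrograms from agglomerative clustering — is a workhorse visualization for
chemical and biomedical matrices (compound descriptor tables,
high-throughput screens, expression data). Interactive heatmap viewers do
not cluster; they consume a pre-clustered document. `dendroheat` is the
data-preparation side of that workflow: it turns a delimited table of row
IDs and numeric features into a validated three-block JSON document
(`data`, `metadata`, `column_dendrogram`) that encodes the heatmap, its row
and column dendrograms and per-row annotations, and it provides the
programmatic queries a viewer or analysis server needs on top of such a
document.

## What it computes

* **Min-max scaling.** Each feature *x* is mapped to
  *x′ = (x − min(x)) / (max(x) − min(x))*, so every feature lies in [0, 1]
  and no wide-ranged descriptor (e.g. molecular weight against logP)
  dominates the distances. Optionally the dendrogram is built on normalized
  values while the heatmap displays the original ones.
* **Agglomerative clustering** of rows and/or columns via `stats::hclust`
  with linkages single, complete, average, Ward, centroid, median and
  weighted, and metrics euclidean, manhattan, correlation, cosine and
  hamming. Heights use the convention in which two singletons merge at
  their plain dissimilarity. An independent O(n³) from-definition
  agglomerator (`naive_linkage`) serves as a verification oracle.
* **Row compression.** The row dendrogram is cut into *k* groups (undoing
  the k−1 highest merges) and each group is aggregated to one row by mean
  or median; each reduced row remembers the original row IDs it represents
  in its `objects` list.
* **Document serialization, parsing and validation** with exact numeric
  round-tripping and a validator covering every structural invariant
  (single root, linked parents/children, counts, distances, payload
  shapes, object disjointness).
* **Exploration queries**: display order of leaves, the objects under a
  dendrogram node, the rows holding given object IDs, cutting a tree into
  *k* subtree roots.
* **Static SVG rendering** (row dendrogram, heatmap, metadata in an
  independent colour scale, column dendrogram, highlights) that is
  byte-deterministic.
* **Scaffold grouping**: compound IDs grouped by identical molecular
  scaffold keys (pluggable key function; an optional RDKit backend derives
  Murcko scaffolds from SMILES).

## Worked example

```r
library(dendroheat)

d <- read_data_table(text = "id,logP,MW,TPSA
CHEMBL1,3.2,250,45
CHEMBL2,5.8,590,30
CHEMBL3,3.4,260,48
CHEMBL4,5.5,600,33", header = TRUE)

round(apply_minmax(d, fit_minmax(d))$values, 3)
#>          logP    MW  TPSA
#> CHEMBL1 0.000 0.000 0.833
#> CHEMBL2 1.000 0.971 0.000
#> CHEMBL3 0.077 0.029 1.000
#> CHEMBL4 0.885 1.000 0.167

cfg <- run_config(axis = "both", normalize = TRUE, write_original = TRUE)
doc <- api_run(cfg, d)
cat(serialize_document(doc, digits = 4, pretty = TRUE))
```

The document clusters the *normalized* values (rows CHEMBL1/CHEMBL3 and
CHEMBL2/CHEMBL4 pair up at heights 0.1858 and 0.2047, joining at 2.216)
while each leaf's `features` array shows the *original* values:

```json
"leaf_0": {
  "count": 1,
  "distance": 0,
  "features": [3.2, 250, 45],
  "parent": "node_0",
  "objects": ["CHEMBL1"]
},
"node_2": {
  "count": 4,
  "distance": 2.216,
  "left_child": "node_0",
  "right_child": "node_1"
}
```

Queries and rendering work on the same object:

```r
leaf_order(doc$data$nodes)
#> [1] "leaf_0" "leaf_2" "leaf_1" "leaf_3"
objects_under(doc$data$nodes, "node_0")$object_ids
#> [1] "CHEMBL1" "CHEMBL3"
svg <- render_svg(doc, render_options(highlight = "leaf_0"))
```

The same pipeline is available from a shell (`inst/exec/dendroheat`):

```sh
Rscript inst/exec/dendroheat data.csv -m metadata.csv -dh -mh -a both -o out.json
```

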