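# pfascluster

Semi-supervised metric-learning QSAR for per- and polyfluoroalkyl
substances (PFASs), at desk scale.

Thousands of PFAS structures are in commerce; for any given biological
target (Cyp enzymes, genes, cell lines) only a small fraction carry an
assayed active/inactive call. This package is for cheminformaticians and
environmental-health researchers who want to triage such sparsely labeled
collections: it learns a task-specific molecular distance from the labeled
minority, embeds and clusters *all* molecules in that space, and attributes
activity to concrete substructures.

## What it computes

1. **Ingest & PFAS filters** — molecule tables (id, SMILES, per-target
   activity labels) with RDKit canonicalization; membership filters for
   "contains a C–F bond" (`[#6][F]`) and "contains a perfluoroalkyl run of
   ≥3 carbons" (`[CX4]([F])([F])[CX4]([F])([F])[CX4][F]`).
2. **Featurization** — 2048-bit ECFP4 fingerprints, optionally augmented
   with a scaled docking-affinity co-descriptor.
3. **Metric learning** — a linear map `L` minimizing the contrastive loss
   `Σ_sim d² + Σ_dis max(0, m − d)²` over labeled pairs, where
   `d(x,y) = ‖L(x−y)‖₂` (Mahalanobis distance with `M = LᵀL ⪰ 0`).
4. **Embedding & clustering** — PCA, optional 2-D t-SNE maps, k-means
   (k-means++/Lloyd) with silhouette-based selection of k.
5. **Attribution** — per-cluster maximum common substructure (RDKit FMCS)
   of the active members and the **bioactive ratio**: the fraction of
   labeled motif-carrying molecules that are active.
6. **Affinity summaries** — fraction of molecules binding stronger
   (strictly more negative) than a kcal/mol threshold, plus the mean.

A seedable synthetic-data generator plants all of this structure
(fluorinated scaffolds, an ester activity motif, sparse labels, affinity
separation) with exact ground truth, so the whole pipeline is testable
offline. Chemistry primitives run through the pre-installed Python RDKit via
a bundled batched helper; `python` with `rdkit` and `scikit-learn` must be
on `PATH`.

## Worked example

```r
library(pfascluster)

res <- run_pipeline(validate_config(list(
  seed = 2,
  out_dir = "run1",
  synthetic = list(n_molecules = 500),   # omit and set `input` for real data
  metric = list(epochs = 40, max_pairs = 1000),
  cluster = list(k = 6)
)))
cat(readLines(res$summary_path), sep = "\n")
```

```
pfascluster run (seed 2)
molecules: 500 (target CYP2C9)
metric: 2048 -> 64, loss 15492.9 -> 208.791
clusters: k = 6, silhouette = 0.2202
top motif: [#6]-&!@[#6]-&!@[#6]-&!@[#6]-&!@[#6]-&!@[#8]-&!@[#6]-&!@[#6]-&!@[#6] (bioactive ratio 0.931, 27/29 labeled matches)
```

Reading it: the contrastive loss fell by almost two orders of magnitude over
the 40 epochs; the 6-cluster partition of the learned space has mean
silhouette 0.22; and the top-ranked bioactive cluster's common substructure
is an alkyl-ester backbone `C-C-C-C-C-O-C-C-C` — in this synthetic world a
mid-chain oxygen occurs only in the planted ester motif, so all 29 labeled
molecules matching it are ester carriers, of which 27 are active (bioactive
ratio 0.931, near the planted P(active | motif) = 0.9). Per-stage artifacts
(`molecules.csv`, `metric_model.json`, `clusters.csv`, `motifs.csv`,
`manifest.json`) land in `run1/`.

The same stages are available as functions (`read_molecule_table()`,
`filter_cf()`, `ecfp4()`, `build_constraints()`, `fit_metric()`,
`metric_transform()`, `pca_embed()`, `select_k()`, `cluster_motif_report()`,
`affinity_summary()`, `generate_dataset()`), and as a CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","pfascluster",package="pfascluster"))')" \
  run --config config.json
```

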