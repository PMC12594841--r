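# scregulon

Master-regulon discovery along branched single-cell trajectories.

Tumor-infiltrating CD8+ T cells differentiate from a naive, stem-like root
through an intermediate memory trunk into distinct terminal fates — a
cytotoxic effector branch, an exhausted branch and a dysfunctional branch —
and the transcription factors (TFs) that *drive* a branch are often invisible
in their own mRNA. `scregulon` implements the full in-silico workflow that
identifies such drivers from single-cell RNA-seq: it infers each TF's
**regulon** (its signed target set) from mutual information across cells,
converts per-cell expression into per-cell **protein activity**, reconstructs
the branched trajectory, and ranks regulons by how strongly they regulate
each branch's differential signature. A bundled synthetic-data generator
plants known regulons, activities, branch topology and tissue preferences so
that every stage is tested against ground truth.

## The method

- **Regulon inference (ARACNe-style).** For candidate regulator *r* and gene
  *g*, dependence is the plug-in mutual information of the equal-frequency
  binned rank histogram, MI = Σ p<sub>ij</sub> log p<sub>ij</sub>/(p<sub>i</sub>p<sub>j</sub>)
  (nats). Edges must exceed a permutation-null threshold (Bonferroni over
  candidate edges); triangles are pruned by the data-processing inequality
  (the strictly weakest edge of each fully connected triple is removed,
  computed order-independently); a consensus is taken over bootstrap cell
  resamples. Target **mode** (sign of regulation) is the Spearman correlation
  of regulator and target signatures; the confidence weight is the edge MI
  scaled within the regulon.
- **Protein activity (aREA / NES).** Per cell, gene z-scores are
  rank-transformed to quantiles q; a target with mode m and weight w
  contributes w·[m·Φ⁻¹(q) + (1−|m|)·Φ⁻¹(½+|q−½|)]; the weighted mean es is
  normalized as NES = es·√n_eff with n_eff = (Σw)²/Σw², so the
  gene-shuffling null is ~N(0,1). Activities from multiple networks are
  integrated by confidence self-weighting,
  NES\* = Σ<sub>k</sub> NES<sub>k</sub>|NES<sub>k</sub>| / √(Σ<sub>k</sub> NES<sub>k</sub>²).
- **Tissue preference.** R<sub>O/E</sub> = observed / chi-square-expected
  cells per cluster×tissue; > 1 is enrichment (≥ 2.5 flagged strong), with a
  per-patient one-way ANOVA on patient-wise R<sub>O/E</sub> replicates.
- **Trajectory.** Minimum spanning tree over cluster centroids in PC space;
  the root is the leaf with maximal naiveness score; pseudotime is geodesic
  distance from the root after projecting each cell onto its cluster's
  incident edges; subtrees beyond the first branching node are branches,
  named effector/exhausted/dysfunctional by their phenotype-score profiles.
- **Master regulons.** Per branch, a signed Wilcoxon rank-sum z per gene
  (branch vs rest) forms the branch signature; each regulon's aREA NES in
  that signature gives a p-value, Benjamini–Hochberg q across regulons, and
  TFs with q ≤ 0.05 and ≥ 25 targets (top 3 by |NES|) are the branch's
  master regulons.

## Worked example

```r
library(scregulon)
res <- run_pipeline(default_run_config(seed = 1))
print(res)
head(as.data.frame(res$rankings$effector), 3)
```

```
pipeline_result: 600 cells, 7 cluster(s), root=C1
  dysfunctional masters: NR4A1, TBX21, EOMES
  exhausted masters: TOX, TBX21, ZEB2
  effector masters: ZEB2, TBX21, TCF7
  branch_4 masters: EOMES, TCF7, TBX21
     tf      nes            p            q regulon_size rank
1  ZEB2 9.506954 1.963276e-21 1.374293e-20           38    1
2 TBX21 8.430851 3.431598e-17 1.201059e-16           48    2
3  TCF7 3.306471 9.447903e-04 2.204511e-03           27    3
```

The run simulates the reference dataset (600 cells, 300 genes, six planted
TF programs), rebuilds the trajectory, and ranks regulons per branch: the
two planted effector programs (ZEB2 late, TBX21 early) top the
effector-branch ranking at q ≈ 10⁻²⁰ — the NES is the regulon's enrichment
in the branch signature in null standard deviations — while the planted
exhaustion (TOX) and dysfunction (NR4A1) drivers win their own branches.
Against the planted truth this run recovers regulon targets at median
F1 = 0.72 and planted activities at median Spearman ρ = 0.85.

The numbered scripts under `analysis/` run the same stages as a narrated
workflow (simulate → cluster/embed → tissue preference → scores/trajectory →
GRN/activity → master regulons), writing their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess_cluster.R
# ... through analysis/06_master_regulons.R
```

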