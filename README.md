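# decoyclust

Comparison and clustering of protein structure decoys in R.

Protein structure prediction pipelines routinely generate thousands of
candidate conformations ("decoys") for one target and then pick a
representative by clustering the ensemble. The bottleneck is the similarity
matrix: for *N* conformers, *N*(*N*−1)/2 pairwise structure comparisons.
`decoyclust` provides that workflow end to end for equal-length models
compared on Cα coordinates:

- **Six similarity measures**
  - **cRMSD** — coordinate RMSD after optimal rigid superposition, computed
    in closed form: with both sets centred and the 3×3 cross-covariance
    `M = (1/N) Σ aᵢbᵢᵀ`,
    `cRMSD = sqrt(Rg_A² + Rg_B² − 2(λ₁ + λ₂ + Sλ₃))`,
    where λ are the singular values of `M` (roots of the characteristic
    cubic of `MᵀM`, so no SVD is needed on the hot path) and `S = sign det M`
    corrects for reflections.
  - **dRMSD** — RMS difference of internal distance matrices,
    `sqrt( 2/(N(N−1)) Σ_{i<j} (d_ij^A − d_ij^B)² )`; superposition-free and
    mirror-blind.
  - **GDT_TS** — `(100/4) Σ_c max C_c / N` over cutoffs 1/2/4/8 Å, where
    `C_c` counts atom pairs within `c` after a superposition. Exact
    optimisation is NP-hard; the score is searched over seeds from all
    contiguous fragments of lengths {4, N/4, N/2, N} (plus powers of two in
    `gdtExt` mode), each refined on the atoms closer than 3.5 Å until the
    selected count is stable for four iterations.
  - **TM-score** — `max (1/N) Σ 1/(1 + (dᵢ/d₀)²)` with
    `d₀ = 1.24(N−15)^⅓ − 1.8` Å, over the same search.
  - **MaxSub** — the TM-score functional with fixed `d₀ = 3.5` Å.
  - **CMO** — Sørensen index of the two contact sets,
    `100 · 2n(A∩B)/(n(A)+n(B))`, contacts defined by a strict distance
    cutoff.
- **Matrices** — all-vs-all (each unordered pair computed once and
  mirrored; bit-identical for any worker count) and vs-reference scoring,
  plus strict threshold pair filtering and similarity→distance conversion.
- **Clustering** — K-means (Lloyd, seeded restarts, distance-matrix rows as
  features) and hierarchical agglomerative clustering (single, maximum,
  average linkage), with representative selection by **min(⟨R⟩/f)** — mean
  within-cluster distance over cluster fraction, favouring large tight
  clusters — and the cluster medoid as the returned model.
- **Synthetic decoys** — a deterministic generator of helix-based ensembles
  with planted clusters at controlled cRMSD separation, used throughout the
  tests.
- **I/O and CLI** — multi-model PDB and one-column list files in; pair
  tables, matrices and cluster reports out; a `clusco`-style command line
  (`inst/exec/clusco`).

## Worked example

```r
library(decoyclust)

decoys <- make_decoy_ensemble(decoy_recipe(seed = 7))  # 3 planted clusters x 20 models
ens <- decoys$ensemble
ens
#> <decoy_ensemble> 60 models, uniform length 36

rmsd_mat <- all_vs_all(ens, "rmsd")
glance(rmsd_mat)
#> # A tibble: 1 × 6
#>   measure n_models n_pairs min_score mean_score max_score
#> 1 rmsd          60    1770     0.583       7.08      14.6

clusters <- hierarchical_cluster(rmsd_mat, "average", k = 3)
tidy(clusters)
#> # A tibble: 3 × 7
#>   cluster  size     f mean_r criterion representative representative_id
#> 1       1    20 0.333  0.711      2.13             20 synthetic:c1:m20
#> 2       2    20 0.333  0.705      2.12             21 synthetic:c2:m1
#> 3       3    20 0.333  0.726      2.18             41 synthetic:c3:m1

rep_idx <- select_representative(clusters, rmsd_mat)
model_ids(ens)[rep_idx]
#> [1] "synthetic:c2:m1"

head(vs_reference(ens, ens[[rep_idx]], "tm"), 3)
#> # A tibble: 3 × 2
#>   model_id        score
#> 1 synthetic:c1:m1 0.402
#> 2 synthetic:c1:m2 0.422
#> 3 synthetic:c1:m3 0.415
```

The 1770 pair scores split cleanly: within-cluster cRMSD averages ≈ 0.7 Å
(the generator's 0.3 Å per-coordinate noise), between-cluster pairs sit far
above the planted 6 Å seed separation, and all three clusters are recovered
exactly with ⟨R⟩/f ≈ 2.1 each; the overall representative is the medoid of
the cluster with the smallest criterion. TM-scores to that representative
are ≈ 0.4 for models in the other clusters.

From a shell, the same analyses run as:

```sh
clusco -l models.list -s rmsd -o pairs.txt      # all-vs-all 3-column pair file
clusco -l models.list -s rmsd 0 20              # K-means into 20 clusters
clusco -i tra.pdb -r ref.pdb -s tm -o out.txt   # TM-score of each model vs a reference
```

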