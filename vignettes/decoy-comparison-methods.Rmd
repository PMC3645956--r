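---
title: "Methods: similarity measures, clustering and the synthetic decoy generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity measures, clustering and the synthetic decoy generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoyclust)
```

This vignette records the models, numerical choices and design decisions
behind `decoyclust`, in the spirit of a methods section: what each measure
computes, which knobs matter, what the synthetic generator does and does
not emulate, and where the design was genuinely open.

## Scope and assumptions

All comparisons are **index-paired on a single atom type** (Cα by default,
configurable via `atom_name`). Models must have equal lengths; there is no
sequence alignment, chain-break detection or insertion-code handling. This
matches the standard decoy-ensemble setting, where every conformer is a
model of the same chain. Hetero records are ignored; alternate locations
collapse to the first-encountered altloc per residue, a deterministic rule
that tolerates the common PDB dialects.

## cRMSD without a rotation matrix

The minimum RMSD over proper rigid motions is obtained in closed form.
Centre both coordinate sets, form the per-atom cross-covariance
`M = (1/N) Σ aᵢbᵢᵀ`, and let `λ₁ ≥ λ₂ ≥ λ₃ ≥ 0` be the singular values of
`M` with `S = sign(det M)`. Then

```
cRMSD² = Rg_A² + Rg_B² − 2(λ₁ + λ₂ + Sλ₃)
```

with the radii of gyration also per-atom (`Rg² = (1/N) Σ ‖aᵢ − ā‖²`). The
`1/N` placement on both `M` and `Rg²` is what makes the identity hold
per-atom exactly; the test suite pins this normalisation down by requiring
equality with an independent Kabsch-SVD implementation to 10⁻⁵ Å on 10⁴
random pairs. `S = −1` handles the case where the unconstrained optimum is
a reflection — the score then correctly reports the best *proper* rotation,
which is why a chiral structure has positive cRMSD to its mirror image.

The eigenvalues of `MᵀM` are computed as roots of its characteristic cubic
via the trigonometric (Viète) solution rather than an SVD. Numerical
safeguards:

- negative round-off eigenvalues are clamped to 0 before the square root;
- the radicand of the final formula is clamped at 0 (identical sets can
  produce −10⁻¹⁶);
- when the shifted cubic is numerically degenerate (relative discriminant
  below 10⁻¹², or the cosine argument escapes [−1, 1] beyond round-off) the
  code falls back to `svd(M)`, where the closed form is ill-conditioned.

One consequence worth stating: the closed form takes a square root across
a full cancellation, so "cRMSD of identical structures" is zero only to
about `sqrt(eps) × scale` (≈ 10⁻⁵ Å for protein-sized coordinates), and the
tests assert it at that tolerance rather than exactly.

The explicit rotation (`kabsch_rotation()`) is kept for the fragment search
below; its reflection fix — flipping the singular vector of the smallest
singular value when the determinant is negative — also breaks ties
deterministically for degenerate (collinear) point sets.

## The shared fragment search: GDT_TS, TM-score, MaxSub

Exact GDT optimisation is NP-hard, so the three superposition-search scores
share one heuristic:

1. every contiguous window of lengths {4, ⌊N/4⌋, ⌊N/2⌋, N} (stride 1,
   duplicates removed, lengths < 4 dropped) seeds a Kabsch superposition of
   the full chains on that fragment;
2. each seed is refined by re-superposing on the atom pairs closer than
   3.5 Å (`refine_cutoff`), iterating until the selected-atom count is
   unchanged for 4 consecutive iterations (`stability_window`);
3. a hard cap of 100 iterations per seed guards against count oscillation,
   and a selected subset smaller than 3 atoms ends that seed's refinement —
   neither bound is stated by the classic descriptions of the heuristic,
   but both are needed for guaranteed termination;
4. the requested measure is evaluated over **all** N pairs at **every**
   superposition visited (seed and each refinement step), and the maximum
   kept. Whether intermediate superpositions should be scored at all was an
   open choice; scoring them can only raise the reported maximum and keeps
   the three measures on literally the same search trajectory.

GDT_TS tracks each cutoff's maximal count independently and reports
`100 × mean(max C_c / N)` — the community-standard normalisation, so
identical structures score 100 even though the raw definition is in counts.
TM-score uses `d₀ = 1.24(N−15)^⅓ − 1.8` Å; the formula is negative for
N ≤ 17, so it is floored at 0.5 Å (a documented package choice — any small
positive floor works, and short chains are rare in practice). MaxSub is the
same functional with `d₀ = 3.5` Å.

The `gdtExt` mode adds seed lengths 8, 16, 32, … below N. "Many more
fragments" is all that is promised by tools offering such a mode; powers of
two were chosen here as a geometric ladder between the minimum window and
the chain length. Since extended seeding searches a superset of
superpositions, `gdtExt ≥ gdt` holds on every pair, and the tests assert
it.

## dRMSD and contact-map overlap

Both are superposition-free. dRMSD is the RMS difference of internal
distance matrices over the N(N−1)/2 unordered pairs. CMO binarises each
structure at a strict distance cutoff (`d < cutoff`, not ≤) and scores two
maps by the Sørensen index `100 · 2|A∩B|/(|A|+|B|)`. Conventions chosen
where the raw formula is undefined: two empty maps score 100 (identical
emptiness), one empty against one non-empty scores 0. Contact defaults —
8 Å on Cα, no minimum sequence separation — are package choices surfaced as
parameters, since no universal standard exists. Both measures are blind to
chirality; cRMSD is not, and the test suite checks the three jointly on
mirrored fixtures.

## Matrices, filtering, distances

`all_vs_all()` computes each unordered pair exactly once and mirrors it.
This is also a correctness decision: the search heuristic is not formally
symmetric in its arguments, so evaluating `(min(i,j), max(i,j))` once makes
the matrix symmetric by construction. The `workers` argument splits the
pair list into deterministic contiguous chunks assembled in pair order, so
results are bit-identical for any worker count — the portable version of a
determinism-under-parallelism contract. No triangle-inequality pruning is
attempted; pair selection within a threshold is plain post-hoc filtering
with strict inequality (`filter_pairs()`), matching the classic
`awk '$3 < 3.2'` idiom on the three-column pair file.

`to_distance()` maps similarities to dissimilarities (TM/MaxSub → 1 − s,
GDT/CMO → 100 − s; RMSDs pass through). Clustering refuses a matrix with a
non-zero diagonal, which catches the common mistake of passing a similarity
matrix directly.

## Clustering and representative selection

Hierarchical clustering delegates to `stats::hclust` (single / complete /
average linkage) with the tree cut at the user's `k`; K-means runs Lloyd
iterations from seeded random centres, best of 10 restarts by within-cluster
sum of squares, 300 iterations maximum. Two open choices:

- **K-means feature space.** Vector-space K-means needs coordinates for
  its centroids, but the package's measures include non-embeddable ones
  (CMO, GDT). Each model is therefore embedded as its row of the distance
  matrix — its profile of distances to every model — which works uniformly
  for every measure at O(N) features per model. This differs from running
  K-means on raw coordinates and is recorded as a deliberate deviation
  risk.
- **Tie-breaking at equal merge heights** follows `hclust`'s deterministic
  internal ordering rather than an explicit lexicographic rule; with
  continuous scores exact ties have measure zero, and determinism (same
  input, same tree) is what matters for reproducibility.

The representative is chosen in two stages: the winning cluster minimises
`⟨R⟩/f` (mean within-cluster distance over the cluster's fraction of the
ensemble — singletons have `⟨R⟩ = 0` by convention, so an all-singleton
partition degenerates to the lowest-index model); within the winner, the
returned model is the **medoid**, minimum mean distance to co-members,
lowest index on ties. The criterion only picks the cluster; the medoid rule
is this package's addition, chosen because it is the standard
distance-matrix notion of a central member.

The numeric method codes accepted by the CLI (`0` = K-means, `1` = single,
`2` = maximum, `3` = average) follow the conventional ordering of such
tools; only the K-means assignment of `0` is universal, the rest is a
documented package convention.

## The synthetic decoy generator

`make_decoy_ensemble()` emulates a multi-trajectory decoy ensemble of a
small single-domain protein: by default 3 clusters × 20 models of a
36-residue chain (a villin-headpiece-sized subdomain), within-cluster noise
0.3 Å per coordinate and ≈ 6 Å cRMSD between neighbouring cluster seeds —
a 20× separation-to-spread ratio, comfortably above the 5× the clustering
tests require, and scales chosen to mirror the sub-Å-to-teens-of-Å cRMSD
range typical of published molecular-dynamics decoy sets.

Cluster seeds are **hinge deformations** of an ideal α-helix (rise 1.5 Å,
100°/residue, radius 2.3 Å, giving 3.8 Å Cα steps): the C-terminal half is
rotated about an axis through the chain midpoint, with the per-cluster
angle calibrated by bisection so consecutive seeds differ by the recipe's
`between_offset` in cRMSD. A hinge rather than a translation is essential —
rigid offsets are removed by superposition and would plant zero
between-cluster cRMSD. Members add isotropic Gaussian noise to their seed;
with per-coordinate sd σ, two cluster mates differ by ≈ σ√6 before
superposition (≈ 0.73 Å at the default), slightly less after.

Everything is a pure function of the recipe seed, and generation leaves the
caller's RNG stream untouched.

What the generator does **not** emulate: physically realistic backbones
(no excluded volume, no energy function), non-isotropic conformational
noise, cluster-size imbalance beyond what the recipe states, and partially
overlapping basins like a trajectory converging into the native cluster.
Passing the clustering-recovery tests therefore shows the algorithms are
correct on well-separated ensembles, not that any real decoy set is that
clean.

## Problem sizes used by the tests and the acceptance script

The package's property checks run at desk scale: 10⁴ random pairs of 4-200
atoms for the closed-form-vs-SVD comparison, 100 pairs for the dRMSD loop
equivalence, 60-model ensembles of 36 residues for matrix and clustering
checks, ≤ 20-model matrices for the MST single-linkage oracle, and 8-atom
fixtures where exhaustive subset-superposition enumeration (70 subsets) is
feasible. These sizes were picked so every guarantee is verified by an
independent oracle in seconds while exercising the same code paths a
thousand-model production run uses.

## Known limitations

- Equal-length, index-paired comparison only: no mmCIF, no all-atom or
  backbone modes, no alignment of different sequences.
- The GDT/TM/MaxSub search is a heuristic; it lower-bounds the exact
  optimum and is not guaranteed to match other implementations'
  heuristics on every pair (self-comparisons and the dominance properties
  above are guaranteed).
- K-means on distance-matrix rows is O(N²) memory; the package targets
  small-to-moderate ensembles, not out-of-core matrices.
- CMO uses sequence-order-dependent contact identity; the full
  order-independent CMO alignment problem is out of scope.
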