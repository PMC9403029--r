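---
title: "Positive and negative pocket signatures: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positive and negative pocket signatures: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pocketsig)
```

## The model and its assumptions

`pocketsig` predicts whether a small-molecule drug binds a protein by
comparing the protein's surface pockets with two consensus descriptions of
pocket space: a *positive* structural signature built from the binding
pockets of known targets, and a *negative* signature built from the most
binding-pocket-like pocket of each known non-target.  The underlying
assumptions are:

1. the drug's binding sites share weakly conserved 3D arrangements of
   atoms, even across unrelated folds;
2. non-targets contain pockets that superficially resemble the binding
   pocket, and these near-native decoys carry class information of their
   own — discriminating against them is more informative than a fixed
   score threshold when targets and non-targets are structurally similar;
3. pocket identity is captured by atom positions plus coarse typing
   (element and residue type), so a sequence-order-independent geometric
   alignment is the right comparison primitive.

A signature position `i` stores a 3D centroid, frequency tables
`AtomFreq_i` (by element) and `ResFreq_i` (by residue type) expressed as
fractions of contributing member structures, and a *preservation ratio*
(fraction of members contributing any atom there).  Alignments are scored
by

    Score = RMSD * N^(-1/3) + alpha * (1 - SeqSim / BestSeqSim)

with `SeqSim = sum_i(AtomFreq_i + ResFreq_i)` over aligned positions and
`BestSeqSim` the same sum over the modal frequencies *of the same aligned
positions*.  Computing `BestSeqSim` over aligned positions only (rather
than all signature positions) keeps the sequence score inside `[0, 1]` by
construction; this was a genuinely open choice and is the one we adopted.
In pocket-to-pocket alignment the reference pocket is treated as a
one-member profile, so frequencies degenerate to 0/1 indicators — the
single-structure limit of the same formula.

A query protein is scored on its top 3 largest pockets; for each pocket
the *same* pocket is aligned to both signatures and the protein reports
the pocket with the minimum difference `delta = Score_pos - Score_neg`.
The decision rule is strict: a target requires `delta < 0`.  We report the
minimum-delta pocket rather than the first pocket below zero because it is
deterministic and independent of pocket ordering.  The package also
retains the single-signature mode (`classify_positive_only()`, strict
cutoff 0.85) for comparison; the two modes are isolated — the difference
rule never consults the cutoff, the positive-only rule never consults the
negative signature.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `alpha` | 1.2 | – | weight of typing vs geometry; results are insensitive near 1 |
| `match_distance` | 2.0 | Å | heavy-atom correspondence acceptance after superposition |
| `min_aligned` | 8 | positions | below this an alignment is meaningless; reported as no-alignment (`Inf` score) |
| `min_preservation` | 0.5 | fraction | every signature position is present in ≥ 50% of members |
| `max_positions` | 100 | positions | minimalistic-signature cap; cutoff raised in 0.05 steps until satisfied |
| `positive_only_cutoff` | 0.85 | score | single-signature operating point |
| `top_k_pockets` | 3 | pockets | largest-volume pockets scored per query |
| `n_random_significance` | 100 | scores | size of the random docking background |
| `grid_spacing` | 1.0 | Å | pocket-finder voxel size |
| `probe_radius` / `vdw_radius` | 1.4 / 1.7 | Å | solvent-exclusion radii |
| `burial_threshold` | 0.55 | fraction | of 32 rays (8 Å) that must hit protein for a voxel to count as buried |
| `min_pocket_volume` | 50 | Å³ | discards voxel-noise cavities |
| `max_pocket_atoms` | 30 | atoms | pocket lining cap, ranked by cavity contact |

The preservation-cutoff schedule deserves one note: the cutoff rises in
0.05 steps while the signature exceeds 100 positions, but never past the
point where a step would empty the signature; residual ties are resolved
by keeping the 100 positions with highest preservation (then larger modal
atom frequency, then lower index).

## The alignment search

The alignment itself is defined here (the field offers many variants and
the comparison primitive is not uniquely pinned down by the scoring
function).  Candidates are seeded from pairs of approximately congruent
atom triangles (all three sorted side lengths within 0.5 Å), with the
triangle vertex pools favouring rare element types and central atoms so
typed motif atoms anchor the search even inside large, carbon-rich
pockets.  Each seed is Kabsch-superposed and grown to a fixed point by
iterated threshold matching; the resulting candidates are deduplicated and
the strongest are polished with an optimal bipartite (Hungarian)
assignment over all admissible pairs.  The candidate with the lowest
combined score wins; near-ties (within `tie_tol = 1e-9`) go to larger N,
then to the lexicographically smallest correspondence.

Two deliberate implementation choices:

* **Greedy matching inside the growth loop, Hungarian only as polish.**
  A full assignment per iteration per seed is the textbook formulation but
  costs ~50x more and changed no test outcome; the final candidates are
  assignment-optimal either way.
* **Maximal matchings only.**  For pockets with more than
  `exhaustive_limit = 7` atoms we do not enumerate sub-matchings of a
  fixed point.  `RMSD * N^(-1/3)` decreases when N shrinks faster than
  RMSD, so admitting arbitrary subsets lets small geometric coincidences
  outrank genuine motif correspondences.  Pockets with ≤ 7 atoms on both
  sides are aligned by exhaustive enumeration of all admissible
  correspondences, which provably returns the score optimum — that is the
  regime in which the test suite compares against a brute-force oracle.

Degenerate inputs: collinear point sets cannot be superposed and return a
no-alignment result (not an error); `delta` involving two infinite scores
is reported as `+Inf` (never a target).

## Signature construction

Signatures are built by progressive profiling along an average-linkage
guide tree computed from the pairwise alignment score matrix (ties merge
the clusters containing the smallest leaf indices; unalignable pairs enter
the tree with twice the largest finite score).  At each internal node the
smaller profile is aligned to the larger (signature-alignment semantics,
modal types as query typing) and matched positions pool their counts with
support-weighted centroid means; unmatched positions are appended.  The
signature frame is therefore the frame of the largest branch, which makes
the build deterministic.  Members that cannot reach `min_aligned` matched
positions at their merge are dropped with a warning and excluded from the
preservation denominators — otherwise a single outlier would dilute every
preservation ratio.  Input order does not affect frequencies or
preservations beyond floating-point noise; positions are reported in
descending preservation order.

During profiling, positions whose support can no longer reach the final
cutoff even if every remaining member contributed are discarded early.
This pruning is exact (it cannot change the final signature) and keeps
intermediate profiles small.

## The pocket finder

The built-in finder replaces an external alpha-shape server with a grid
construction: voxels within `vdw + probe` of a heavy atom are solvent
excluded; open solvent is flooded from the box boundary through low-burial
empty space; the unreached empty voxels form cavities (6-connected
components).  Volumes are voxel counts times `spacing^3` — they reproduce
"largest pockets" *ordering*, not alpha-shape volumes, which is explicitly
out of scope.  Pocket atoms are the heavy atoms within `contact_cutoff`
of a cavity voxel, capped at `max_pocket_atoms` ranked by how much cavity
each atom touches.  Because a voxelised cavity of a few thousand voxels
changes by more than one voxel under an arbitrary rotation, the
rigid-invariance property is tested at a 5% relative volume tolerance
rather than the idealised ±1 voxel.  Co-crystal binding pockets bypass the
finder entirely: they are the heavy protein atoms within `contact_cutoff`
(default 4.5 Å) of any ligand heavy atom, with volume taken from nearby
cavity voxels or, failing that, the convex hull of the pocket atoms.

## What the synthetic generator emulates — and what it does not

`make_benchmark()` plants a typed pocket motif (default 14 positions in a
10 Å-diameter ball, ≥ 1.5 Å apart) into each structure with per-coordinate
Gaussian noise (`noise_sigma`, default 0.3 Å), independent position
dropout (default 0.2), 10% type perturbation, and a random rigid
placement, surrounded by a hollow scaffold shell of alanine-like carbon
pseudo-atoms that seals the motif inside a detectable cavity.  Negatives
carry a second motif sharing a `confusability` fraction of the positive
motif's positions.  Two generator choices matter for interpreting green
tests:

* the scaffold is *deliberately decorrelated* across structures (random
  shell radius ±3 Å, centre offset ±2.5 Å, orientation, tangential
  jitter), so scaffold atoms line individual pockets but stay below the
  50% preservation cutoff — as a real decoy background should;
* the default motif has 14 positions because a conserved core must retain
  at least `min_aligned = 8` positions after dropout to be alignable at
  all; recovery tests that specifically probe the 8-position limit pass
  `n_motif = 8` explicitly.

The generator emulates conserved geometry with noise, dropout and
confusable decoys.  It does **not** emulate real protein folds, realistic
pocket shapes, sequence context, side-chain flexibility, or crystal-
structure artefacts.  A green synthetic cross-validation therefore
establishes that the pipeline recovers planted, rigidly-embedded motifs at
the stated noise levels — not that it reaches any particular performance
on experimental kinome data, which requires curated structure sets and
external docking.

## Baseline and external inputs

The nearest-neighbour sequence baseline uses Needleman–Wunsch global
alignment with BLOSUM62, gap open 10 and gap extension 0.5 (community
defaults; the method itself names none), similarity being the fraction of
aligned positions with a positive substitution score, normalised by the
shorter sequence so fragments are penalised symmetrically.  Assignment
requires a strictly maximal neighbour with similarity strictly above 0.6;
ties or sub-cutoff maxima leave the protein unassigned, and evaluation is
reported both over the assigned subset and over all proteins.  Docking
scores are ingested (TSV), never computed; empirical significance is the
fraction of random-structure scores at least as good, with the "<1%"
convention corresponding to a value of 0 against 100 random scores.

## Known limitations

* The pocket finder is a contract-faithful stand-in, not an alpha-shape
  reproduction; absolute volumes differ from published server output.
* The alignment search is a deterministic heuristic above 7 atoms;
  optimality is guaranteed (and oracle-tested) only in the exhaustive
  regime.
* Cross-validation pools confusion counts over folds (per-fold averaging
  is the other convention; pooled counts are stabler at these sizes).
* One positive and one negative signature per drug; multi-signature
  ensembles and allosteric-site variants are out of scope.
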