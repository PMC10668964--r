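---
title: "Quantifying local structural change at protein phosphorylation sites"
author: "ptmlocal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying local structural change at protein phosphorylation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the approach

Phosphorylation of serine, threonine or tyrosine (deposited as the
residue codes SEP, TPO, PTR) is the most common post-translational
modification, yet its structural footprint is heterogeneous: some
proteins barely move, others rearrange only in the immediate
neighborhood of the modified residue, and some differ globally between
their intact and modified depositions. `ptmlocal` implements a
comparison pipeline that makes this heterogeneity measurable:

1. **Curation.** Candidate pairs of chains — one intact, one carrying at
   least one phospho-residue, sharing a UniProt accession — pass a set
   of inclusion criteria before analysis (minimum length 15 residues,
   shared accession, canonical intact form, length difference at most
   5 residues, global sequence identity at least 90% after mapping
   phospho-residues to their parents, at most 3 phospho-residues,
   lowest-RMSD candidate selection, one chain per structure, and
   removal of redundant accession/locus combinations).
2. **Geometry.** For each accepted pair: global Cα RMSD after optimal
   (Kabsch) superposition; then, for sequence windows of ±3, 6, 9, 12
   and 15 residues around each modification site, a *fresh*
   superposition restricted to the window's Cα atoms, the radius of
   gyration of both forms over the window's atoms, and the summed
   per-residue solvent-accessible surface area.
3. **Segmentation.** Pairs with global RMSD > 2 Å form group N1
   (globally different; local comparison is not meaningful). Among the
   globally similar pairs, those with at least one window RMSD > 2 Å
   form group N2 (a genuine local rearrangement); the rest are N3.
4. **Distributions.** Per-group medians and Gaussian-kernel density
   estimates of the window metrics describe how the response varies
   with neighborhood size.

The normalized deltas are defined as

* `ΔRg = (Rg_ptm − Rg_wt) / Rg_wt × 100 + 100` (percent; 100 means no
  change), and
* `ΔSASA = (SASA_ptm − SASA_wt) / L_surr` (Å² per residue), where
  `L_surr` is the residue count of the scope — `2k + 1` for an
  untruncated ±k window, the chain length for the whole protein.

Window SASA is always the *sum of whole-chain per-residue SASA* over
the window members. The neighborhood is never excised and recomputed in
isolation: cutting it out would expose artificial surface at the cut
points and dominate the signal.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| RMSD threshold | 2.0 | Å | conventional boundary between "same fold, same conformation" and a real difference; equality counts as *not exceeding* (difference requires strict `>`) |
| neighborhoods | 3, 6, 9, 12, 15 | residues | spans one helical turn (±3) up to a small domain's worth of backbone (±15) |
| identity threshold | 0.90 | fraction | tolerates point substitutions and small unmodelled stretches while excluding homologs |
| min length / max length difference | 15 / 5 | residues | excludes peptides and truncation-mismatched depositions |
| max phospho-residues | 3 | count | heavily modified chains (histone tails carry up to 14) confound a per-site analysis |
| SASA probe radius | 1.4 | Å | water probe |
| SASA mesh points | 960 | per atom | Fibonacci lattice; the isolated-atom analytic error is < 0.1% and a 10-residue chain changes by < 1% against a 4000-point mesh |
| van der Waals radii | C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 | Å | Bondi-style heavy-atom set; unknown elements fall back to 1.80 Å with a warning |
| gap open / extend | 10 / 0.5 | score | conventional values for a match-1/mismatch-0 identity matrix; identity uses the alignment length (gap columns included) as denominator — the stricter reading |
| edge margin | 2 | residues | a coil site within 2 positions of a helix or strand counts as "coil-edge" (border zone); with margin 0 the category disappears by construction |

All of these live in `curation_config()`, `sasa_params()` and
`pipeline_config()` and are test-covered at their defaults.

## Design choices where the design was open

* **Residue indexing** is 1-based and contiguous over the observed
  residues, the natural convention in R; author numbering (with
  insertion codes) is carried alongside and used for all reported loci.
* **Hydrogens are removed and never re-added.** All geometry is
  heavy-atom-only with radii chosen accordingly. Re-adding hydrogens
  with a modeling tool only canonicalizes their presence between the
  two forms; omitting them achieves the same comparability without an
  external dependency, at the cost of slightly smaller absolute SASA
  values that cancel in ΔSASA.
* **Alternate locations** keep the highest-occupancy conformer, ties
  broken by file order — deterministic and standard. Multi-model (NMR)
  files contribute only their first model.
* **Superposition** is plain Cα Kabsch with no outlier-rejection
  cycles. Structure viewers' `align`-style tools iteratively discard
  poorly fitting atoms, which lowers reported RMSDs by an
  implementation-defined amount; a pure least-squares fit is exactly
  reproducible. Absolute RMSDs here can therefore sit slightly above
  what such tools print for the same pair.
* **Windows are anchored on the modified chain** and mapped through the
  alignment correspondence to the intact chain; unmatched positions
  shrink the paired window, and windows with fewer than 3 matched
  residues are skipped and logged. With multiple sites (≤3), the pair's
  per-k window RMSD is the maximum over sites — the most sensitive
  aggregation for detecting any local change.
* **Cohort-level criteria.** Two of the inclusion rules are not
  pair-intrinsic: the lowest-RMSD rule (reported as C6 on the losing
  candidates of a shared intact chain) and accession/locus redundancy
  (C9 on the discarded duplicates, lowest global RMSD surviving).
  "One chain per structure" (C8) is checked as a split-rule violation
  on models built from more than one chain identifier. The per-pair
  criteria C1–C5 and C7 are evaluated without short-circuiting so a
  verdict lists every violation.
* **Secondary structure** defaults to header HELIX/SHEET records when
  present, else a φ/ψ-region heuristic (helix φ ∈ [−100°, −30°],
  ψ ∈ [−80°, −5°]; strand φ ∈ [−180°, −90°], ψ ∈ [90°, 180°] or
  [−180°, −170°]; helix runs < 4 and strand runs < 3 revert to coil).
  Precomputed external annotations can be supplied as a file; no
  assignment program is ever invoked as a subprocess.
* **KDE** uses a Gaussian kernel with Scott's bandwidth
  (`sd(x)·n^(−1/5)`) on a 500-point grid spanning the data range ± 4
  bandwidths. Curves are not clipped at physical bounds such as
  RMSD ≥ 0; mass leaking below a bound is visible in the curve rather
  than silently renormalized.

## What the synthetic generator emulates

`make_backbone()` grows N/CA/C/CB backbones by natural-extension
placement from ideal bond geometry and canonical φ/ψ torsions, so
Cα–Cα spacing (3.80 Å) and the secondary-structure ground truth are
exact by construction. `make_pair()` derives the modified member by
swapping the site residue for its phospho form (idealized phosphate:
P–O 1.6 Å, tetrahedral oxygens), applying one of three backbone
perturbations, and adding 0.05 Å Gaussian coordinate noise:

* **null** — no backbone change: the chemical modification alone, the
  signature of group N3;
* **local** — a smooth bump confined to ±6 residues of the site
  (plateau over the inner half, cosine rolloff to exactly zero at the
  declared half-width, direction rotating along the chain so the
  deformation is far from any rigid-body motion), peak amplitude 3 Å:
  the N2 signature, window RMSD above 2 Å while the global RMSD stays
  well below;
* **global** — a chain-wide low-frequency deformation of amplitude
  4 Å: the N1 signature.

Amplitudes, the 120-residue default length and the noise level were
fixed once as the study conditions; over 50 seeded replicates per
scenario the classifier recovers the designed label in ≥ 95% of cases
(in practice 100%). Cohorts cycle the site locus over coil, helix and
strand positions of the mixed backbone so context statistics are
populated. All randomness derives from the scenario seed; regeneration
is bit-stable.

What the generator does **not** emulate: side-chain rotamers, real
phosphate chemistry and its hydrogen-bond network, crystal-contact
artifacts, unmodelled loops, sequence heterogeneity between
depositions, and experimental coordinate error structure. Passing the
synthetic recovery tests therefore demonstrates that the *pipeline
machinery* is correct and sensitive at the 2 Å decision scale — not
that real intact/modified pairs will partition cleanly.

## Numerical notes

* Kabsch superposition handles the reflection case by sign-correcting
  the smallest singular vector so the rotation determinant is +1; the
  weighted variant normalizes weights internally. Optimality is checked
  in the tests against a quaternion-search oracle on random instances
  (agreement to 1e-3 Å; typically 1e-13).
* The SASA mesh is a Fibonacci lattice, which integrates the sphere
  exactly enough that an isolated atom's area is correct to machine
  precision at any mesh size; occlusion accuracy is what improves with
  more points.
* Degenerate inputs fail loudly: empty chains, empty sequences,
  fewer than 3 correspondence points, single-valued KDE samples and
  empty summaries all raise errors rather than returning NaN.
* Boundary values: RMSD exactly at the threshold classifies as similar;
  a window clamped at a terminus is flagged `truncated` and its actual
  residue count is used as `L_surr`.

## Problem sizes

The shipped analysis workflow (`analysis/01…05`) runs a cohort of 15
pairs (5 per scenario, 120 residues each); the acceptance script
additionally re-derives the classifier recovery over 50 replicates per
scenario and the numeric-core oracle checks (200 superposition
instances, 960-point SASA mesh, 1000-sample KDE). These sizes give
stable statistics while keeping a full run in the minutes range on one
core.

## Known limitations

* Applying the pipeline to deposited structure pairs requires a local
  mirror and a manifest; nothing is downloaded. Group proportions
  obtained on real data depend on the deposition snapshot and on the
  superposition convention (see the outlier-rejection note above).
* Sequence windows are windows in *sequence*; a residue spatially
  adjacent to the site but distant in sequence is never part of the
  neighborhood. Absolute-distance (Å-radius) neighborhoods are out of
  scope.
* The dihedral secondary-structure heuristic is deliberately coarse
  (no 3₁₀/π subclasses, no hydrogen-bond criterion) and will disagree
  with DSSP/STRIDE near element boundaries — exactly where border-zone
  sites live, which is why external annotations can be substituted.
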