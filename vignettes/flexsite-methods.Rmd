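---
title: "Druggability assessment with light protein flexibility: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Druggability assessment with light protein flexibility: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most structure-based druggability estimators treat the receptor as rigid.
That is adequate for well-formed enzyme active sites, but it systematically
misses *cryptic pockets*: sites that are small or shallow in the crystal
structure yet can open to a drug-like cavity through modest side-chain
rearrangement and local backbone movement. Such pockets are common at
protein-protein interaction (PPI) interfaces. flexsite implements a
three-step pipeline for this problem: (1) detect and score candidate pockets
on the rigid structure; (2) for pockets whose physicochemical score passes a
gate, model light flexibility by docking hydrophobic probes and repacking
nearby side chains; (3) re-detect and re-score the pocket on the relaxed
models and classify it.

## Pocket detection

A regular grid (default spacing 0.35 Å) is laid over the receptor plus an
8 Å margin. Three per-point quantities decide whether a grid point is a
*site point*:

* **Probe vdW energy.** A neutral united-atom carbon probe interacts with
  every receptor heavy atom within 8 Å through a 6-12 Lennard-Jones
  potential (pair minimum 4.0 Å and well depth 0.15 kcal/mol against
  carbon, Lorentz–Berthelot mixing elsewhere). A site point must have
  energy ≤ −`maxvdw` (default 1.0 kcal/mol).
* **Enclosure.** 110 quasi-uniform directions (an antipodally symmetric spherical Fibonacci set)
  are cast from the point; the enclosure fraction is the share of rays whose
  first entry into the receptor vdW envelope lies within `maxdist` (10 Å).
  Ray–sphere intersection is computed in closed form rather than by
  marching, which removes step-size artefacts; a 10⁶-random-ray oracle in
  the test-suite agrees within 0.02. A site point needs enclosure ≥ 0.4.
* **Outside the receptor** vdW envelope.

Site points must additionally be supported by at least `nthresh` = 7 other
site points within 1.76 Å (applied once, not iterated), and are then
clustered by single linkage with a 5.0 Å cut: groups whose closest points
are closer than `dthresh` join. Clusters below `mingroup` = 7 points are
discarded; the five largest sites (by point count, ties broken by volume
then centroid order) are kept. Site volume is the number of distinct
occupied grid cells times the cell volume.

These defaults are the published permissive detection settings for finding
shallow, flexible pockets (maxdist = 10, enclosure = 0.4, maxvdw = 1.0,
dthresh = 5.0, mingroup = 7, nthresh = 7, grid = 0.35, modphobic = 0); each
is a configurable field of `detection_config()`.

## Descriptors and the druggability score

Per-site descriptors are the mean site-point enclosure *e*, hydrophobic and
hydrophilic potentials *h* and *p*, volume *V*, and a size count *n*. The
polar potentials are distance-weighted kernel sums, `(1 − r/6 Å)²`, over
polar atoms (N, O; S outside Cys/Met; charged atoms doubled) and apolar
carbons respectively. Both are normalized so that the site-point mean over
a packaged reference pocket — a 300 ų hemispherical pocket with a
two-thirds apolar lining — equals 1; a mixed lining is used because a
purely apolar reference would leave the hydrophilic normalization constant
undefined. The constants are frozen in the package and re-derived by a
regression test.

The druggability score is the weighted sum

```
Dscore  = 0.094 · sqrt(n) + 0.60 · e − 0.324 · min(p, 1)
Dscore+ = Dscore + 0.3 · h
```

with the published coefficients of the original druggability score as defaults
(`score_weights()`); the hydrophilic cap implements the bounded polar
penalty. Because the detection grid is much finer than the grid those
coefficients were calibrated on, the size term uses a volume-equivalent
count at a 1.4 Å reference spacing, `n = V / 1.4³`; the raw fine-grid count
still drives `mingroup` and ranking. Scores are reported rounded half away
from zero to one decimal, and the decision gates are applied to the rounded
values, matching the reporting convention of the thresholds.

## Flexibility modeling

Sites with reported Dscore+ > 1.3 advance to a two-stage induced-fit
procedure with two packaged hydrophobic probes: rigid naphthalene
(stage 1), then a tetra-substituted naphthalene (TSN, MW ≈ 363 Da, ethyl /
propyl / two cyclohexyl substituents on a 2,3,6,7 pattern — the exact
regiochemistry is a packaged convention) whose substituent torsions are
sampled at 60° steps into at most six conformers.

Docking is an exhaustive rigid-body search: translations on a 1 Å lattice
over the site points (clipped to a 25 Å box about the site-point centroid
anchor), a deterministic rotation set, and conformer enumeration. Poses are
scored by the probe–receptor Lennard-Jones sum plus a hydrophobic-contact
bonus and a per-clash penalty; only net-favourable poses are admitted, and
clashes against the receptor as docked are prohibitive. What makes this an
*induced-fit* search is that both stages dock against a receptor whose
repackable side chains near the site are temporarily trimmed to Cβ — the
standard induced-fit device — so a probe can enter a pocket that current
rotamers occlude; repacking afterwards operates on the untrimmed receptor
with the pose in place and resolves exactly those residues.

Repacking assigns each residue with any heavy atom within 5 Å of the probe
the rotamer minimizing clash plus Lennard-Jones energy against its
environment and the probe, greedily in order of worst clash, over two
sweeps. Rotamers come from a compact backbone-independent chi table
(canonical −60/180/60° targets, ±30° sub-sampling around the best
candidate). If the best rotamer still clashes, an optional capped
steepest-descent translation of the residue (backbone included) is applied —
a deliberately simple stand-in for local backbone relaxation, bounded by a
1.5 Å cap so the light-flexibility contract (no backbone atom moves more
than 1.5 Å) holds by construction. A model with an unresolved hard clash is
discarded.

Stage 1 keeps the best two naphthalene poses and repacks around each;
stage 2 docks TSN from each variant (probe removed), repacks again, and
aims for at least ten models. When TSN admits no pose from a variant — a
genuinely narrow pocket — the stage-1 variant itself is kept as a model, so
a pocket opened by naphthalene alone is still rescored. The four
top-scoring models are re-detected and re-scored in a 24 Å box around the
anchor, and the per-site flexible result is the maximum rescored Dscore+
across the scored models (ties to the larger volume); the maximum is our
declared convention where the aggregation rule was open.

## Classification

* **rigid gate:** reported rigid Dscore+ > 1.3 (strict);
* **flexible gate:** reported flexible Dscore+ ≥ 1.7, the rigid gate plus
  the empirically systematic score increase flexibility modeling induces;
* **drug-like volume:** 160–800 ų, inclusive at both ends (a published
  borderline case with a flexible volume of exactly 160 ų counts as
  druggable);
* **cryptic pocket:** rigid volume ≤ 100 ų, rigid enclosure ≤ 96 %
  (a strict-`<` mode is available), flexible result passing both flexible
  gates, and a chain of at least 100 residues;
* sites with rigid volume > 800 ų are flagged `oversized_site` and not
  advanced.

Interface annotation marks a PPI pocket when any atom of the winning TSN
pose (hydrogens included) lies within 2.0 Å of another protein chain, and
a ligand pocket when the site's occupied cells overlap the vdW envelope of
a ligand removed during preparation by more than 0 ų.

## Structure preparation

Waters are always removed. Het entities with molecular weight ≤ 1000 Da
are removed (and recorded for the ligand-overlap annotation) unless their
code is on the cofactor keep-list (heme variants, Zn, Mg); heavier
entities are kept and flagged. Molecular weight is estimated from the
heavy-atom composition with valence-based implicit hydrogens. Missing
side-chain atoms are completed from ideal residue templates; hydrogens are
placed geometrically for polar positions only (backbone amide by the
bisector rule, side-chain polar hydrogens through local template frames)
with fixed default protonation states — Asp/Glu deprotonated, Lys/Arg
protonated, His neutral Nε. Apolar C–H hydrogens stay implicit, a
united-atom convention; no pipeline stage consumes them, and skipping
hydrogen-network optimization follows the observation that restrained
minimization does not significantly change druggability scores.

## Synthetic fixtures and what they do (and do not) show

All geometric claims are tested on generated receptors with analytic
ground truth: spherical cavities, open hemispherical bowls, flat slabs,
two-cavity structures, and a rotamer-gated cryptic cavity, written as legal
PDB files so tests exercise the real I/O path. Wall atoms (double shells
packed at ~1.8 Å) are placed at the cavity radius plus the probe
*standoff* — the distance at which the probe potential against a dense flat
carbon wall crosses zero, `rmin_pair/5^(1/6)` ≈ 3.06 Å, derived from the
integrated 10-4 form of the pair potential — so the analytically-truthed
radius coincides with the detectable region. Detected spherical-cavity
volumes agree with `4/3·π·r³` within a 15 % tolerance across the sweep.

Two consequences of the declared model are worth knowing. First, a large
flat surface carries a thin band of marginally-enclosed (~0.41–0.43),
energetically favourable points just above the 0.4 threshold; the slab
fixture is therefore a finite patch, on which every flat-face point stays
below the threshold. Second, open pockets accrete a small cap of site
points above their mouth plane, so hemispherical-bowl volumes are used for
site-existence and enclosure checks rather than strict volume accuracy.

The gated fixture realizes the cryptic-pocket mechanism in miniature: a
drug-like 3.8 Å-radius cavity is crossed through its centre by a lysine
side chain anchored in the wall, leaving a detectable ring well under
100 ų. Any probe docked into the pocket must overlap the chain; the wall
is molded snugly (3.0 Å) around both the closed and the open conformation,
so the open recess is clash-free for the gate but never holds site points
of its own. The fixtures emulate pocket geometry, lining polarity and
single-degree-of-freedom gating; they do not emulate real protein packing,
electrostatics, solvation or cooperative backbone motions, so passing
tests establish the correctness of the geometric and combinatorial
machinery, not predictive accuracy on real proteins.

Problem sizes throughout (fixture radii 2–5 Å, grids of ~1–3 million
points, one induced-fit cycle per advanced site with four scored models)
were chosen so a full desk-scale validation runs in minutes on a single
core while still exercising every stage at the published parameter values.

## Validation against published benchmarks

Per-structure scores and volumes printed in the two published validation
tables ship as data fixtures; they are inputs, not recomputation targets,
because they depend on a proprietary scorer. From them the package
reproduces the protein-protein interaction error rates — a 12 % false
positive rate and 0 % false negative rate under the flexible gate and
drug-like volume rule — and the score-variation comparison: per-target
variation `(max − min)/mean`, rounded to whole percent, with median 13 %
and sample (n−1) standard deviation 10 % for the flexibility method versus
median 21 % and standard deviation 94 % for the docking-based method. The
sample standard deviation is a derived convention: it reproduces both
printed summary values.

## Numerical choices and known limitations

* Ties in site ranking break by volume, then lexicographic centroid, so
  reports are reproducible; the whole pipeline is deterministic for a
  fixed configuration and seed.
* The admission ceiling for poses is 0 (any net-favourable pose); the
  pose-energy scale is internal and only its ordering matters.
* The support filter is applied once, not iterated to a fixed point.
* Degenerate inputs: empty structures, Cα-only chains and unparsable files
  raise typed errors; grids beyond the point budget suggest a coarser
  spacing.
* The rotamer set is compact; side chains with more than two chis sample
  the distal chis coarsely, which can miss narrow recesses in real
  proteins. Backbone relaxation is a capped rigid residue translation, far
  simpler than a molecular-mechanics minimizer.
* The phobic/philic normalization is anchored to one packaged fixture;
  absolute h and p values on real proteins carry that convention.
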