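---
title: "Methods: crystal and trajectory water analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crystal and trajectory water analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Ordered waters at a protein–ligand interface carry real binding-energy
consequences: a water that simultaneously hydrogen-bonds ligand and protein
(a *bridging* water) extends the interaction network an inhibitor relies
on, and a water found at the same superposed position across many crystal
structures of one protein (a *conserved* water) marks a hydration site
that any new ligand must exploit or displace. `hydrosite` measures both
from the two data sources a modeller typically has — a family of crystal
structures of one protein with different bound ligands, and
explicit-solvent MD trajectories of those complexes — plus a synthetic
generator that plants known hydration structure so every analysis can be
checked against exact ground truth.

## Structure model and trajectory dialect

A structure is an ordered atom table (serial, name, residue, chain,
coordinates in Å, element, record type) with waters flagged by residue
name (`HOH`, `WAT`, `TIP3`, case-insensitive, configurable). A trajectory
is a topology plus an `atoms × 3 × frames` coordinate array at a fixed
frame interval, 2 ps by default — the natural spacing when a 2 fs
integrator writes every 1000 steps. Multi-model PDB is the one on-disk
trajectory format: it keeps fixtures human-readable and diffable, and the
parser enforces the contract the analyses need (equal atom counts across
models, line-numbered coordinate errors, round-trip identity on stored
fields at the `%8.3f` coordinate precision). Only the first alternate
location is kept; mmCIF, insertion codes and connectivity records are out
of scope. Hydrogens are optional in crystal structures and only required
by the strict angle criterion below.

## Superposition and the acceptance filter

Structures of the same protein are paired atom-by-atom on
`(chain, residue number, atom name)` — a same-protein assumption that
tolerates point mutations at paired positions, replacing any
sequence-alignment step. The Kabsch solution (SVD of the cross-covariance
matrix, reflection branch excluded) gives the rigid transform minimising
RMSD over the paired atoms; the whole mobile structure, waters and ligand
included, is then moved by that transform. Families are screened by
post-fit RMSD with a 0.5 Å default threshold. The pairing level for both
fit and threshold defaults to Cα — the least mutation-sensitive choice —
and can be set to backbone or all protein atoms. Degenerate geometry
(fewer than 3 pairs, collinear points) is an error, not a silent fit.

Per-frame trajectory RMSD fits every frame to frame 1 on a fit selection
and reports RMSD on a (possibly different) report selection; both
selections are fixed at frame 1, so region-based selections such as "the
5 Å shell around the ligand" are well defined across frames.

## Crystal-water criteria

* **Hydrogen bond (crystal mode):** two polar heavy atoms (N, O, F, S), one
  in each group, at most 3.0 Å apart. Distance-only, because most crystal
  structures lack hydrogens; the cutoff is the conventional upper end of
  donor–acceptor distances.
* **Active-site water:** water oxygen within 5.0 Å of any ligand atom.
* **Bridging water:** at least one hydrogen bond to the ligand *and* one to
  protein atoms simultaneously. Direct contact by default; a flag allows
  one intervening hydrogen-bonded water (two-water bridges occur in real
  sites, but chaining inflates counts, so it is opt-in).
* **Conserved-water clustering:** greedy single linkage with a
  per-structure cap. The water whose `match_radius` neighbourhood spans
  the most structures seeds a cluster; each structure contributes at most
  its nearest in-radius water; the centroid is refined once; assigned
  waters leave the pool. Clusters are reported by decreasing multiplicity
  with ties broken by distance to the ligand, and tie-breaking everywhere
  is lexicographic on (label, residue number) so output is reproducible
  byte-for-byte. The default `match_radius` of 1.2 Å stays below half a
  water–water contact distance, so two genuinely distinct sites can never
  merge; when the positional scatter of a family is known (e.g. planted
  jitter of σ = 0.3 Å in the validation fixtures, or B-factor-derived
  uncertainty in real families), a radius near 5σ — 1.5 Å for σ = 0.3 — is
  the better operating point, and that is what the validation suite uses.
* **Displaced waters:** apo waters whose oxygen lies within 1.4 Å
  (≈ the water-oxygen van der Waals radius) of any atom of the superposed
  holo ligand.

## Trajectory hydration criteria

* **Solvation shells:** first shell = minimum water-oxygen-to-ligand-atom
  distance ≤ 3.4 Å; second shell = (3.4, 5.0] Å. Both shells use the
  minimum-atom-distance convention; a centre-of-mass mode exists behind a
  flag for comparison, but mixing conventions between the two shells
  would make the counts depend on ligand size, so the consistent form is
  the default. Boundaries are closed above, and first + second always
  equals the within-5 Å count.
* **Occupancy:** for each (solute atom, water oxygen) pair, the percentage
  of frames within 5.0 Å. This is deliberately a *contact* occupancy —
  trajectory hydrogen-bond tables in this field pair carbon atoms with
  water oxygens at a 5 Å cutoff, which only a distance criterion
  reproduces. A strict mode (donor hydrogens required,
  donor–H···acceptor angle ≥ 120°) is flag-enabled; the angle default is a
  documented package choice, as common practice ranges 120–150°.
  Occupancy is exactly `100 × frames_present / frames`, reported to two
  decimals in the table writers.
* **Residence time:** per-frame presence of a water oxygen within 1.4 Å of
  a fixed site, summarised as visits (maximal presence runs) and the
  longest run, optionally bridging absences up to `gap_tolerance` frames;
  a bridged run's length includes the gap frames. Site coordinates live
  in the trajectory's own frame — fit first if the solute tumbles.
* **Density grid:** each frame is Kabsch-fitted to frame 1 on the solute,
  so the grid — a cube (default edge 100 Å, voxel 0.5 Å) centred on the
  frame-1 solute centroid — never moves while the molecule does. Every
  water oxygen increments its containing voxel; waters outside the grid
  land in an overflow tally, so `sum(counts) + overflow =
  frames × waters` is an exact invariant. Voxel size 0.5 Å resolves site
  separations well below water–water contact distances while keeping a
  100 Å cube tractable (8 × 10⁶ voxels).
* **Hydration sites:** greedy peak-picking on the grid. The highest-count
  voxel proposes a site; its occupancy is the fraction of frames with a
  water oxygen within the 1.0 Å site radius; voxels within the site
  radius are cleared; extraction stops when the proposed site's occupancy
  falls below the threshold (default 25 %). Per site the mean number of
  neighbouring waters within 3.5 and 5 Å of the occupying water and its
  mean distance-criterion hydrogen-bond count are averaged over occupied
  frames.

## The synthetic generator

The generator stands in for downloaded crystal structures and
explicit-solvent MD runs, and its defaults are the study conditions the
analyses are validated under — they are fixed, not tuning knobs.

The "protein" is a rippled ring of Gly-like residues (N, CA, C, O per
residue; 40 residues for crystals, 30 for trajectories, ring radius 12 Å)
around a central ligand: pure geometry, no force field, sufficient for
every distance-based operation. Crystal families plant conserved sites
2.8 Å from polar ligand atoms at stated presence fractions (defaults 1.0,
0.8, 0.5 across 10 structures), with Gaussian site jitter (σ = 0.3 Å, a
typical positional scatter for well-ordered crystal waters), per-atom
scaffold jitter (σ = 0.05 Å), a random rigid motion per structure, far-off
distractor waters, and — because each crystal's side chains and ligand
pose adapt to its own water — contact partners placed at exactly 2.8 Å
from each structure's realised water position. The apo variant removes
the ligand and restores ordered waters inside the ligand volume (default
9, configurable), so displaced-water counting has exact truth. Atom
overlaps below 0.5 Å abort generation.

Trajectory waters follow deterministic presence schedules realised
exactly (block layout by default, even-spread and Bernoulli modes by
flag): present frames place the water at its site plus Gaussian jitter;
absent frames hand it to the bulk pool, a 10–25 Å shell around the ligand
in which waters random-walk (0.5 Å/frame) — far enough that bulk never
enters either solvation shell. The elongated trajectory ligand (atoms
0.8 Å apart along x) makes the minimum-distance geometry exact: a water
perpendicular to the chain at distance *d* has minimum ligand distance
exactly *d*, which is what lets scripted shell means (2.6 Å and 4.2 Å
sites, safely inside the 3.4 / 5 Å bands at 5σ of the default jitter) and
the five-rung contact-rate ladder be recovered to the resolution of one
frame. Rigid tumbling, when enabled, transforms frames 2…n only — frame 1
defines the lab frame that per-frame fitting recovers — and its random
draws happen after all placement draws, so planted truth is bit-identical
with tumbling on or off. All randomness flows from the single seed in the
spec; emitted ground truth includes an independent brute-force shell
recount from the final coordinates.

What passing these fixtures does *not* show: the generator has no water
exchange kinetics, no hydrogen-bond network, no correlated protein
motion, and its thermal jitter is frame-independent. Recovery of planted
truth validates the analysis arithmetic and conventions, not the physics
of real hydration.

## Validation problem sizes

The test suite works at sizes chosen to exercise every code path while
staying quick on one core: occupancy scripts up to 10⁴ frames, shell
scripts at 500 frames, density grids of 60 Å at 0.5 Å spacing over
300 frames, 100 seeded ten-structure families for bridging/conserved
recovery, and 50 random ≤ 300-atom instances per brute-force oracle
comparison. The quaternion-search superposition oracle (400 random unit
quaternions plus Nelder–Mead polishing) is independent of the SVD path it
checks.

## Known limitations

* Residue-number pairing assumes one consistent numbering across the
  family; renumbered entries would need external mapping first.
* The crystal hydrogen-bond criterion cannot distinguish donors from
  acceptors without hydrogens; reported contacts are symmetric.
* Greedy clustering and greedy peak-picking are order-dependent by
  design (deterministic and reproducible, but not globally optimal); very
  diffuse hydration — density smeared across many voxels with no clear
  peak — is reported as low-occupancy sites or none at all.
* Binary trajectory formats and binding-energy estimates are out of
  scope.
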