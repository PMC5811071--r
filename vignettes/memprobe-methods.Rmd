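---
title: "Methods: transition probes, cholesterol maps and motif scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transition probes, cholesterol maps and motif scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memprobe)
```

## The scientific problem

SLC6-family neurotransmitter transporters (the dopamine, serotonin and
norepinephrine transporters) work by alternating access: the protein cycles
between an outward-facing state, open to the synaptic cleft, and an
inward-facing state, open to the cytoplasm. The early steps of the
out-to-inward transition have a recognisable structural signature on the
intracellular (IC) side: the IC half of transmembrane helix 5 (TM5) unwinds
within its conserved glycine/proline helix-breaking motif and kinks at the
hinge proline, water penetrates toward the second sodium (Na2) site, and the
residues lining the IC exit pathway become solvent exposed. Cholesterol
bound at the TM1a/TM5/TM7 interface (site 1 in the crystal structures)
suppresses exactly these motions.

`memprobe` packages the analysis layer for this problem: the six
time-resolved probes that diagnose the transition, monitors for the
extracellular/intracellular gates, per-residue fluctuations, volumetric
cholesterol occupancy maps with binding-site statistics, CRAC/CARC
cholesterol-recognition motif scanning, and Cα principal component analysis.
Because the microsecond trajectories behind such studies are rarely
deposited, the package also ships a deterministic synthetic toy-transporter
generator: every analysis stage can be validated against planted ground
truth without any simulation data.

## The six probes

All residue numbers below are hDAT author numbering, loaded from the
`"hdat"` preset (`load_selection_presets()`); an `"hsert"` preset carries
the serotonin-transporter gate pairs and T276 probe.

1. **TM5 RMSD** (Å, threshold ≥ 5). Frames are superposed on the protein
   core — all protein Cα except the termini (58–65, 595–601), TM5 (256–286)
   and EC loop 2 (178–236) — and the Cα RMSD of the IC half of TM5
   (258–273) is measured against the reference without refitting. Excluding
   the moving segment from the fit keeps the core superposition unbiased.
2. **TM5 helicity** (%, threshold ≤ 50). Percent of window residues whose
   backbone dihedrals fall in an α-helical window, φ ∈ [−100°, −30°] and
   ψ ∈ [−67°, −7°]. The assignment method behind published helicity traces
   is typically unstated; a dihedral window was chosen because it is
   hydrogen-independent, deterministic, and testable on constructed
   geometry (a DSSP-style criterion can be substituted — the window is an
   argument). Terminal residues lacking a dihedral leave the denominator.
   The probe window is 258–273; the full-TM5 range is configurable.
3. **TM5 kink angle** θ (degrees, threshold ≥ 20). The hinge is the TM5
   proline P273. Principal axes (first singular vector of the centred Cα
   coordinates, oriented N→C) are fitted to the sub-segments before and
   after the hinge, excluding hinge ± 1 — the distorted hinge turn itself
   carries no axis information. θ is the unsigned angle in [0°, 180°]; a
   150° kink reads 150°, never 30°. On an ideal straight helix the measured
   angle is not exactly zero: sub-segments spanning a non-integer number of
   helical turns have a small intrinsic axis wobble (≈ 2° for the 16- and
   12-residue sub-segments of the TM5 window), far below the 20° threshold.
4. **Na2 water count** (threshold ≥ 15). Distinct water molecules (counted
   through their oxygen; a water without oxygen is an error) strictly
   within 10 Å of the instantaneous geometric centre of the heavy atoms of
   the Na2-coordinating residues G75, V78, L418, D421, S422. Anchoring on
   the residue shell rather than the ion keeps the probe meaningful after a
   hypothetical sodium release; the anchor is switchable.
5. **IC exit-path SASA** (Å², threshold ≥ 220). Shrake–Rupley solvent
   accessibility summed over residues F69, S72, G75, G258, S262, V266,
   T269, F332, G425, E428, T432.
6. **T261 SASA** (Å², threshold ≥ 50). The same calculation for the
   conformation-dependent phosphorylation site alone.

The thresholds (5 Å, 50%, 20°, 15, 220 Å², 50 Å²) are the dashed-line
values of the inward-occluded reference state, stored in
`default_state_thresholds()` and serialized with every pipeline run.
`call_state()` marks a frame inward when all six probes lie on the inward
side of their threshold *inclusively* — thresholds are drawn as lines, not
open intervals — and a trajectory "shows transition" when at least one
frame does. Raising any ≥-threshold can only shrink the transition set
(tested as a monotonicity property).

**Gate monitors.** Salt-bridge pairs (R85–D476; R445–E428, R60–D436) report
the minimum distance between basic side-chain nitrogens and carboxylate
oxygens; the aromatic lid (Y156–F320) the distance between ring-heavy-atom
centroids; polar pairs (Y335–E428, S262–D68) the minimum hydroxyl-to-
carboxylate oxygen distance. Raw distances are reported; a contact cutoff
(e.g. < 4 Å for a formed salt bridge) is presentation-layer, since the
underlying analyses publish distance traces, not binary states.

## Solvent accessibility

`sasa()` is a plain Shrake–Rupley implementation: per heavy atom, the
fraction of `n_points` quasi-uniform sphere points (deterministic
golden-section spiral) at radius `r_atom + 1.4 Å` lying inside no other
probe-expanded sphere, times the shell area. Radii are a Bondi table keyed
by element; an unknown element is an error naming the atom. The occluding
environment is protein heavy atoms only — lipids, waters and ions never
shadow the surface, so the probe measures conformational opening, not
solvent fluctuation. At the default 960 points a free sphere is within 1%
of its analytic area; doubling the points moves well-exposed residues by
well under 1%, and values agree with a 10×-denser computation to 2% on
random clusters. No R package in the supported environment provides SASA,
which is why the primitive is implemented here and oracle-tested.

## Cholesterol occupancy maps and binding sites

`build_occupancy_grid()` superposes all frames on a reference (any
selection; typically all protein Cα), then marks a voxel occupied in a
frame when any heavy atom/bead of a cholesterol-class molecule falls in it;
occupancy is the occupied-frame fraction, which makes the grid a histogram
— invariant to frame order. Defaults: 1 Å voxels for atomistic systems,
2 Å for coarse-grained-style fixtures (the map resolution is not a
published constant; these are conventional volumetric-map choices). The
**bulk** reference is the mean occupancy of voxels 15–25 Å away from any
protein heavy atom, restricted to the membrane slab (|z − mean lipid z|
below a leaflet half-width), so it measures the lipid bulk rather than
solvent.

`detect_sites()` thresholds voxels at 3× bulk — the enrichment used for the
published density maps — and groups them by 6-connectivity (faces only;
stricter components, fewer spurious merges). Each component becomes a site
with an occupancy-weighted centroid and a residue list: protein residues
with any heavy atom within 6 Å of a member voxel centre. That contact rule
is the reproducible stand-in for the manual, visual residue assignment the
original maps used.

Two COM rules, mirroring the two published definitions, quantify binding:

- **occupancy fraction**: fraction of frames in which *any*
  cholesterol-class molecule's mass-weighted COM is within 8 Å (strict) of
  the site-residue COM;
- **bound trace**: per-molecule COM separation with a strict 5 Å bound
  cutoff, no smoothing; binding/unbinding events are False→True/True→False
  transitions, dwell times come from bound run lengths.

"Within 8 Å" and "shorter than 5 Å" are both read as strict inequalities;
boundary frames are measure-zero in practice and the convention is fixed
here. Distances use the minimum-image convention on the orthorhombic box,
with molecules assumed whole — the generator writes whole molecules, and
the published cutoff tests do not state their imaging convention, so the
simplest correct contract was adopted.

## Motif scanning

CRAC (`L/V – X(1–5) – Y – X(1–5) – K/R`) and CARC
(`K/R – X(1–5) – Y/F – X(1–5) – L/V`) are scanned by explicit enumeration
of every spacer combination, deduplicated by (class, start, end) and
reported in full — published motif figures colour whole spans without
defining multiplicity, so all matches are kept and a merge flag is offered
for presentation. The unknown residue X is legal in spacers but never
matches an anchor. CARC admits phenylalanine at the central position; CRAC
does not — exactly the printed patterns. `overlap_report()` treats "a site
contains a motif" as ≥ 1 shared residue, the weakest defensible reading,
but reports the overlap length so stricter readings can be applied
downstream. The scanner is verified against an exhaustive
substring-by-regex oracle on every test sequence.

## Principal component analysis

`fit_pca()` superposes frames on the PCA selection itself against an
iterated mean (two iterations — the selection is published, the fit
protocol is not; the choice is recorded in the model's `fit_protocol`
field), then eigendecomposes the 3N covariance of the centred Cα
coordinates of the core (residues 66–171 and 232–548, excluding termini and
EC loop 2). Eigenvalue sums equal the ensemble variance by construction;
projections of the fitting ensemble onto distinct components are
uncorrelated. Projection of another trajectory fits each frame to the model
mean; projecting a different topology is refused unless an explicit residue
correspondence is supplied, because a silent positional match would be
wrong more often than useful. `extreme_structures()` displaces the mean to
the projection extremes for porcupine-style visualisation.

The **cosine content** diagnostic is
c_i = (2/T) (∫ p(t) cos(iπt/T) dt)² / ∫ p(t)² dt,
evaluated with trapezoidal sums and clamped to [0, 1]. Under this
definition a pure cosine of matching index scores 1; a linear ramp p(t) = t
scores 24/π⁴ ≈ 0.246, and a mean-centred ramp — the relevant case for PCA
projections, which are centred — scores 96/π⁴ ≈ 0.9855. Both closed forms
are asserted in the test suite. Values near 1 flag random-diffusion-like
sampling rather than converged motion.

Because rigid-body motion is removed before the eigendecomposition, a
displacement direction used to validate mode recovery must be orthogonal to
the six rigid degrees of freedom; the test fixtures project their planted
modes off that subspace, which is also why small systems would otherwise
show an apparent overlap deficit of order 6/3N.

## The synthetic toy transporter

`synthetic_spec()` / `build_bundle()` / `script_trajectory()` generate a
poly-alanine 12-helix bundle (backbone N, Cα, C, O plus Cβ, built from
ideal internal coordinates by natural-extension-of-reference-frame
placement) whose residue numbering tiles 58–609 so that every hDAT preset
resolves; the fifth block is "TM5" with its hinge at 273. The helices stand
on a 9-membered outer ring (radius 11.4 Å) around a 3-helix core (radius
4.2 Å), with TM5 flanked by the TM1 and TM8 blocks and backed by TM7 —
the site-1 neighbourhood. Each key helix is axially rotated so that its
probe residues face the bundle interior; for TM5 the exit-path residues
258/262/266/269 share one ~80° helical arc, so orienting that arc inward
buries the whole IC pathway in the resting state. These radii and
orientations were fixed at generator-design time so that the resting bundle
sits on the outward side of *every* probe threshold with a wide margin
(baseline IC-path SASA ≈ 93 Å² against the 220 Å² threshold, T261 ≈ 1 Å²
against 50 Å²) and a scripted opening crosses all six — the property the
fixtures exist to provide.

The transition script is geometric, not physical:

- **unwinding** k(t): the last k residues of the 258–273 window are rebuilt
  at extended dihedrals (−139°, +135°), flipping the helicity criterion
  deterministically, one residue quantum at a time;
- **kink** θ(t): the sub-hinge half is rigidly tilted so that the principal
  axes of the two sub-segments enclose exactly θ, opening toward the
  bundle exterior. Realising the axis angle itself (rather than applying a
  nominal rotation) makes the scripted angle recoverable to better than
  0.1° despite the intrinsic axis wobble of short helical segments;
- **displacement** d(t): the whole core-fit-excluded TM5 segment (256–286)
  is translated radially, so the TM5 RMSD probe reads exactly d and no
  helicity-window dihedral straddles a moving boundary;
- **hydration** N(t): waters occupy deterministic slots on three spherical
  shells (2.5–5.8 Å) around the Na2 centre, surplus waters are parked far
  outside the 10 Å cutoff, so the count is recovered exactly;
- **lipids**: single-bead cholesterol proxies (sufficient for every
  COM-based rule) either random-walk in the bilayer slab with reflection at
  the box and at a protein-exclusion cylinder, or are redrawn uniformly
  every frame ("ideal gas", the null model whose spurious-enrichment
  probability a binomial tail bound controls). A planted sticky site binds
  its dedicated bead with i.i.d. per-frame probability p within a small
  jitter radius; unbound excursions are drawn in the bulk, away from all
  sites, so the measured occupancy fraction equals the planted bound
  fraction exactly and converges to p at the binomial rate. Per-frame bound
  flags, site centres and all script vectors are emitted as ground truth;
- **noise**: optional isotropic Gaussian displacement of protein
  coordinates (per-residue RMSF then approaches σ√3).

Randomness comes from R's Mersenne-Twister, fully determined by the
recorded seed — deterministic and platform-stable within R, and the only
generator base R offers without adding dependencies. Identical specs
produce byte-identical fixtures on disk.

What the toy does *not* emulate: force-field energetics, realistic lipid
packing, side chains beyond Cβ (so gate monitors are exercised on
constructed side-chain geometries instead), correlated protein dynamics,
and membrane curvature. Passing tests therefore demonstrate that the
*analysis layer* measures what it claims to measure on data with known
truth — not that any biological conclusion re-emerges at desk scale;
microsecond-scale occupancy fractions and per-repeat transition calls are
out of reach by construction.

## Problem sizes and runtime choices

The validation suite uses 2-to-40-frame full bundles (2760 protein atoms)
for the probe suite, 2000-frame mini bundles (720 protein atoms, 200 beads)
for the occupancy statistics — the length at which a 3×-bulk excursion of
an ideal-gas voxel is excluded at the 0.99 level by the binomial bound —
and 960 sphere points for SASA (480 in the repeated per-frame suites).
These sizes were chosen so the full validation runs in minutes on one CPU
while every tolerance stays statistically meaningful.

## I/O and interfaces

Topologies and trajectories are read through bio3d (PDB, multi-model PDB,
DCD); the package's own multi-model writer adds the `CRYST1` box record the
Trajectory contract requires. Occupancy grids serialize to OpenDX, sites to
JSON, probe tables to CSV with units and thresholds embedded in the column
names, fixtures to PDB + JSON + YAML. `run_pipeline()` chains probes,
state call, gates, cholesterol mapping and PCA, and writes a summary JSON
plus the exact configuration and package version next to every output. A
thin command-line wrapper (`inst/scripts/memprobe.R`) exposes `run`,
`synth` and `motifs` subcommands over the same functions.

## Known limitations

- XTC trajectories are not supported (no reader in the supported stack);
  multi-model PDB is the reference format and DCD is read through bio3d.
- The helicity criterion is a dihedral window, not hydrogen-bond-based
  assignment; on real, noisy helices the two can differ near fraying ends.
- Occupancy-grid comparisons across differently oriented copies of the
  same system are exact only for lattice-preserving transforms; a general
  rotation re-bins the density at voxel resolution.
- The hSERT preset reuses the hDAT segment ranges alongside hSERT gate
  pairs; a residue-accurate hSERT mapping should be supplied as a custom
  preset file.
- `site_occupancy_fraction()` uses heavy-atom, mass-weighted COMs; a
  Cα-only variant of the published rule would shift fractions slightly
  (the atom set is an argument).
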