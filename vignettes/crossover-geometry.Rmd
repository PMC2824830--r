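---
title: "Measuring the chirality of DNA-DNA crossovers in crystal lattices"
author: "DNACrossover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the chirality of DNA-DNA crossovers in crystal lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DNACrossover)
```

## The model

Two juxtaposed B-DNA duplexes form a *crossover* characterized by three
quantities: the inter-axial closest-approach distance, the acute crossing
angle α between their helical axes, and the chirality (handedness) of the
crossing. Because B-DNA is itself a right-handed helix, the two
handednesses present different molecular surfaces to each other: a
right-handed crossing lets the backbone of one helix run along the major
groove of the other (self-fitting, "knob into hole"), whereas a
left-handed crossing aligns the *axis* of one helix with the partner's
groove direction, so only groove-floor-to-groove-floor juxtaposition is
possible. The package quantifies this on coordinates.

### Helical axes

Each duplex's axis is the total-least-squares line through its base-pair
origins (C1′–C1′ midpoints): the first principal direction of the centred
origin cloud. This follows the "best linear axis" notion; it is not a
curvilinear axis, and the fit RMSD is reported so that bent DNA is flagged
(`curvatureFlag`, threshold 2 Å RMSD). Duplexes longer than the
configured window (12 pairs, aimed at nucleosomal DNA) are analysed in
overlapping 12-pair windows, each window fitted and paired independently;
windowed fits that are still curved carry the flag into a
`low_confidence` column rather than being dropped.

### The signed crossing angle

With axis directions **u**, **v** re-signed so **u**·**v** ≥ 0 (the acute
convention) and **c** the vector between the closest-approach points (A to
B), the angle is |α| = arccos(**u**·**v**) and the sign is the sign of the
triple product (**u** × **v**)·**c**. The overall orientation of this
convention is not derivable from formulas alone — it is *calibrated*: a
constructed right-handed groove-backbone crossover (backbone of one helix
laid along the partner's major groove) must be positive. The calibration
constant is locked in code and asserted by a test; mirror reflection of
any assembly negates every α exactly (an improper isometry flips the
triple product), and proper rigid motions leave α unchanged. Exact
90° crossings are reported as +90 (the printed convention for tetragonal
crystal forms). Both properties are enforced as invariant tests.

A consequence of the acute convention is that the "raw" obtuse angle
180° − |α| is never reported; the magnitude is always folded into
(0°, 90°] before signing. Degenerate inputs are refused explicitly:
coincident axes have no defined sign, and parallel (zero-angle) axis pairs
are skipped by the crossover search with a `parallel` flag available from
`closestApproach()`.

### Base-pair frames and groove sectors

Frames follow the chemistry: origin at the C1′–C1′ midpoint, *y* along
C1′(I)→C1′(II), *z* the mean base-plane normal oriented along the strand-I
5′→3′ progression, *x* completing the right-handed triad. For correctly
handed B-DNA this *x* points at the major-groove edge atoms (purine
N7/O6/N6/C5, pyrimidine C5/N4/O4) — this is asserted per duplex. For
mirror-image coordinates (which arise in the chirality test fixtures) the
two requirements conflict; groove identity is chemical, so the frames are
re-anchored by flipping *x* and *z* with a warning, sacrificing the 5′→3′
sign of *z* but keeping every groove label correct.

Around each pair, the in-plane angle θ from +*x* partitions the circle
into sectors: |θ| ≤ 60° major groove, |θ| ≥ 120° minor groove, the two
60–120° bands backbone. The boundaries are symmetric even though the real
major groove subtends more arc; classification never depends on the exact
boundary, only on facing and insertion, which the fixtures verify.

### Interaction-mode classification

A phosphorus atom of one duplex is *inserted* in the partner's groove when
(i) its radial distance to the partner's fitted axis is at most the
penetration radius (10.5 Å; the B-DNA phosphate cylinder has radius
~9–10 Å), and (ii) it lies over the *groove floor*: its in-plane angle is
within 30° of the groove axis. The second condition is a deliberate
narrowing of the full ±60° major sector. Fixture verification showed why
it is needed: when two duplexes face each other groove-to-groove at tight
separations, the phosphates *flanking* the facing groove graze the
partner's penetration cylinder at in-plane angles of 33–55°, and with the
full-sector rule those juxtapositions misclassify as groove-backbone
contacts. Genuine insertions in groove-backbone poses sit over the floor
(|θ| ≲ 23°), so the 30° half-width separates the two regimes with margin
on both sides. Any major-groove insertion gives MAJOR_GROOVE_BACKBONE;
otherwise a minor-groove insertion gives MINOR_GROOVE_BACKBONE.

With no insertion, the mode is decided by which groove of each duplex
faces the partner. The facing direction is evaluated toward the partner's
pair-origin *centroid* rather than the closest-approach point: for shallow
crossings under coordinate noise the closest point slides several Å
axially and lands on a twist-misregistered frame (the local groove
direction rotates 36° per base pair), whereas the centroid direction is
stable and identical for noiseless poses. Major/major, minor/minor and
major/minor combinations map to the juxtaposition modes; if either face is
a backbone sector the crossover is UNCLASSIFIED rather than forced into a
category.

### Anchors and cation bridges

For groove-backbone contacts, the amino groups of the receiving duplex
(cytosine N4 for major-groove insertion, guanine N2 for minor) are scored
against the inserted phosphate group's oxygens (O1P/O2P/O5′/O3′). No
hydrogens are modelled, so all criteria are donor-heavy-atom distances: a
contact ≤ 3.4 Å is a hydrogen-bonded anchor; 3.5–4.5 Å is a proximal
anchor — the plain-text `[C]` / `(C)` markup in the report tables mirrors
the bold / bold-italic typography used in printed crossover tables. The
3.4 Å hydrogen-bond cutoff was chosen to abut the explicit 3.5–4.5 Å
proximal window so the two classes are disjoint by construction; the open
interval (3.4, 3.5) is a documented no-man's land assigned to neither.
Groove-groove modes return no anchors: that interaction is not
sequence-specific.

A cation bridges the crossover when it contacts at least one DNA atom of
each duplex within 4.0 Å. The single cutoff across Mg/Ca/Mn is deliberate:
inner-sphere-only criteria (≤ 2.6 Å) are too strict for older structures
with unmodelled waters, and 4.0 Å covers tight water-mediated geometries.
Monovalent ions (Na⁺, K⁺) are reported but flagged non-divalent; cobalt
hexammine is treated as a single cation site at the Co position. Drug
atoms (netropsin, distamycin, polyamides) are carried through parsing but
excluded from DNA-DNA contact classification, and waters are never ions.

## Tunable parameters

All thresholds live in `runConfig()` and are logged with every run:

| parameter | default | unit | role |
|---|---|---|---|
| `contactRadius` | 25 | Å | symmetry-expansion search radius (axial separations of interest are ≤ ~22 Å, plus margin) |
| `maxInteraxial` | 22 | Å | crossover distance gate |
| `penetrationRadius` | 10.5 | Å | inserted-phosphate radial cutoff |
| `insertionHalfWidth` | 30 | ° | groove-floor half-width for insertion |
| `hbondCutoff` | 3.4 | Å | anchor hydrogen bond |
| `proximalWindow` | 3.5–4.5 | Å | proximal anchor |
| `bridgeCutoff` | 4.0 | Å | cation bridge contact |
| `curvatureRmsd` | 2.0 | Å | axis-fit curvature flag |
| `windowSize` | 12 | bp | axis window for long/bent DNA |
| `minOverlap` | 3.4 | Å | interior margin of closest points (one rise) |

The Watson–Crick detection thresholds (3.5 Å, 65°, 9–11.5 Å) are
conventional geometric criteria, recorded in `detectBasePairs()`'s
signature and exercised on fixtures.

## The synthetic-data generator

`buildIdealBDNA()` produces a fiber-model duplex: planar idealized base
pairs (rings as regular polygons, Watson–Crick N1⋯N3 = 2.9 Å, glycosidic
bonds 1.47 Å, C1′–C1′ = 9.4 Å) stacked at 36° twist and 3.38 Å rise, with
backbone atoms on the 8.9 Å phosphate cylinder and the antiparallel
complementary strand generated automatically. Pair origins sit exactly on
the +z build axis, which is returned as a ground truth for axis-fit
oracles. `buildCrossover()` poses two such duplexes at a requested signed
angle and distance, rolling each about its own axis so the requested face
(backbone, major-groove floor, or minor-groove floor) points at the
partner; `makeMockCrystal()` embeds assemblies in a unit cell so the
file-based pipeline can be exercised end to end; `mirrorAssembly()` is the
chirality oracle.

What the generator emulates: B-form geometry, groove asymmetry, strand
antiparallelism, phosphate placement, crystallographic packing via real
space-group operators, seeded isotropic Gaussian coordinate noise. What it
does not: sequence-dependent fine structure (propeller, slide, roll),
sugar pucker, solvent, thermal anisotropy, or curvilinear axes. A green
closure test therefore establishes the correctness of the *geometry* and
*bookkeeping* of the pipeline — not that real crystals are ideal fibers;
for real structures the ±5° tolerance against printed crossing angles
absorbs the difference between a linear fit and curvilinear axis programs.

Pose feasibility is part of the generator's stated world. A
groove-backbone pose is only realizable when the inserting backbone
(phosphate radius 8.9 Å) reaches within the penetration radius of the
partner's axis, i.e. separations ≤ ~18.5 Å (and ≥ ~15 Å before serious
clashes); groove-groove poses below ~19 Å interpenetrate the phosphate
shells and their mode becomes genuinely degenerate, so the closure suites
sample groove-backbone poses at 15–18.5 Å and groove-groove poses at
19–25 Å, while unconstrained ("none") poses span the full 14–25 Å range.
Noisy-recovery poses use |α| between 30° and 85°, the crystallographically
observed range; near-parallel crossings have unstable closest-point
geometry under noise and are excluded from the noisy ensemble, not from
the noiseless one.

## Numerical choices

* Alternate locations resolve to the highest occupancy, ties to the first
  conformer in the file; only model 1 of multi-model files is read.
* Symmetry expansion deduplicates placed copies at 1e-6 (rotation and
  translation entries); the lattice-shift bound is derived from the
  contact radius plus the model diameter over each cell height and is
  tested against brute-force enumeration.
* Crossovers equivalent under a lattice isometry are collapsed by a
  signature of (α, distance, axial contact offsets) rounded at 1e-3/1e-1,
  keeping the lexicographically smallest provenance.
* Axis-fit RMSDs below 1e-9 are snapped to exactly zero (collinear input).
* Ties at exactly 90° fold to +90; the sign of a zero triple product
  (axes coplanar with the inter-axial vector) defaults to +.
* PDB output carries 3-decimal coordinates, so file round-trips preserve
  angles to ~1e-3 degrees and positions to 1e-3 Å; in-memory closure is
  exact to 1e-6 or better.
* Mode strings sort reports deterministically (mode, then α descending),
  and TSV output is byte-stable for identical inputs and configuration.

## Known limitations

* The linear axis is not a curvilinear helical axis; strongly bent DNA is
  only handled through windowing plus the curvature flag.
* The facing-groove determination uses the partner's origin centroid; for
  very long unwindowed duplexes contacting far off-centre this could pick
  a misleading direction (windowing keeps segments short in practice).
* Space-group coverage is the internal table of Sohncke groups observed
  in B-DNA crystal forms; files with other groups must carry their own
  operator records (mmCIF `_symmetry_equiv` or PDB REMARK 290), which take
  precedence over the table when present.
* Wobble and noncanonical pairs are labelled but not framed specially;
  modified bases are mapped to their parent base (5-methylcytosine to C,
  inosine to a G-like purine pairing with C, 1-aminopurine to A).
* No electrostatics, free energies, writhe or supercoiling simulation:
  the package measures and classifies geometry only.

## Session

```{r}
sessionInfo()
```
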