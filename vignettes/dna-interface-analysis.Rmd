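---
title: "Methods: geometry, contacts and threading at a protein-DNA interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, contacts and threading at a protein-DNA interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnareadout)
```

## Scope and model

`dnareadout` analyzes atomic models of protein-DNA complexes.  All
analyses are heavy-atom only: crystallographic models at typical
resolutions contain no hydrogens, so hydrogen bonds and salt bridges are
classified by donor/acceptor distance alone, without angular terms.
Waters and ions are excluded from contacts and surface areas by default
(solvent-mediated bridges are rarely resolved at these resolutions);
a flag re-includes them.  Alternate conformations collapse to the
highest-occupancy conformer (ties broken by altloc letter), giving a
deterministic single-conformer geometry.

## Backbone torsions and B~I~/B~II~ substates

Torsions follow the standard signed-dihedral convention used across
structural biology (the constructed quadruple (1,0,0), (0,0,0), (0,1,0),
(0,1,1) evaluates to -90 degrees, matching bio3d and biotite).  A torsion
whose defining atoms are missing is `NA`, never zero; 5'-terminal
nucleotides (no phosphate) lack alpha/beta and 3'-terminal ones lack
epsilon/zeta, so a *n*-bp duplex has 2(*n* - 1) classifiable
phosphodiesters.

The two B-DNA backbone substates differ in the epsilon (C4'-C3'-O3'-P)
and zeta (C3'-O3'-P-O5') torsions about the 3'-phosphodiester: B~I~ has
epsilon - zeta near -90 degrees (epsilon trans, zeta gauche-), B~II~ near
+90.  Published analyses report B~I~, B~II~ and an intermediate class but
not the cutoffs they used, so the classifier uses a symmetric dead zone:
B~I~ iff epsilon - zeta <= -45 degrees, B~II~ iff >= +45, intermediate
between.  Canonical substates sit near +/-90, so the +/-45-degree band
separates them with a wide margin while still admitting an intermediate
class; the band is a configuration key (`bi_bii_band`), not a constant,
because the boundary between "intermediate" and the named substates is a
convention, and reproducing someone else's counts may require their band.
Classification is monotone in epsilon - zeta by construction.

## Base frames, pair and step parameters

Each base's reference frame is obtained by least-squares (Kabsch)
superposition of an idealized base onto the observed ring atoms.  The
idealized geometries are derived once, from chemical-component-dictionary
ideal coordinates flattened onto a plane and placed so that Watson-Crick
partners are exactly related by a 180-degree rotation about the frame x
axis, with hydrogen-bond distances at canonical values (A·T: N6-O4
2.95 A, N1-N3 2.82 A; G·C: O6-N4 2.91 A, N1-N3 2.95 A, N2-O2 2.86 A),
glycosidic C1' anchored at the canonical B-DNA position and lambda
(C1'-C1'-N) angles near 54.5 degrees on both strands.  Because a planar
base admits an in-plane mirror that distance criteria cannot distinguish,
the placement's ring-traversal sense is validated against the standard
reference orientation for every base; the mirror image would flip the
fitted frame's z axis and corrupt every downstream parameter.

Intra-pair (buckle, propeller, opening; shear, stretch, stagger) and step
parameters (tilt, roll, twist; shift, slide, rise) use the symmetric
mid-frame construction: the bend angle between the two z axes is split
half-and-half about the hinge axis, twist is measured about the common z,
and the hinge components along the mid-frame x/y axes give tilt and roll.
The same decomposition serves pairs (strand-d frame flipped about x
before comparison; propeller is the roll-like component) and steps.  The
fiber generator composes frames with the *exact inverse* of this
decomposition, so builder parameters are recovered to numerical precision
- the generator/analyzer closure tested across random sequences.
Parameters are rigid-motion invariant (tolerance 1e-6) because only
relative frames enter.

Base-pair detection is geometric: C1'-C1' distance 10.4 +/- 1.6 A, at
least two inter-base N/O pairs within 3.5 A, base planes within 65
degrees, and - essential to avoid pairing with stacked diagonal neighbors,
which can satisfy all three - vertical separation along the mean base
normal below 2.0 A.  Candidates are ranked by hydrogen-bond support and
assigned greedily, one partner per nucleotide.

## Groove profiles

Groove widths are taken from phosphorus positions: for each phosphate,
the minimal cross-strand P-to-P distance with the partner offset
restricted to a window expressed along each strand's own 5'->3' direction
(-5..-2 bp for the minor groove, +2..+7 for the major).  The windows
bracket the canonical offsets (about 3 for the minor groove) while
letting the true minimum be found; both are configurable.  Distances are
raw, with no phosphate-radius subtraction, and each entry records its
partner phosphate for audit.  Positions with a truncated window report
the restricted minimum, flagged `edge` (minor) / `edge_MaG` (major).
`delta_PP_MiG` subtracts the 11.7 A regular-B-DNA average.  On the
default fiber duplex the interior profile is flat at 11.71 A - this
reference emerges from the generator's calibrated phosphate placement
(below), it is not subtracted in.

## Surface areas

SASA uses Shrake-Rupley sphere sampling with a deterministic Fibonacci
lattice (no random number generator: results are bit-reproducible), probe
1.4 A, 960 points per atom by default (doubling the density moves totals
by well under 0.5%), and Bondi-type radii (C 1.70, N 1.55, O 1.52, P
1.80, S 1.80, Fe 1.40 A), extensible per call.  An element without a
tabulated radius is an error naming the atom - no silent default.  Buried
surface area between two groups is SASA(A) + SASA(B) - SASA(A and B),
with third-party atoms excluded from all three computations (groups are
isolated by selection, not shadowed).  Iron-sulfur clusters and other
cofactors are counted with the protein group in the pipeline's
protein/DNA BSA.

## Contacts

Heavy-atom pairs below 3.8 A (strict, configurable) are enumerated by an
all-pairs scan and classified: `hbond` iff both atoms are N or O at
d <= 3.3 A; `salt_bridge` iff d <= 3.3 A between a titratable side-chain
nitrogen (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2) and a phosphate oxygen -
His bridges carry a `"possible"` qualifier because imidazole protonation
is unknown in a heavy-atom model; everything else is `vdw`.  DNA atoms
are annotated by moiety (phosphate: P/OP1/OP2/OP3/O5'/O3'; sugar; base)
and protein atoms by main-chain flag.  Residues with missing
(crystallographically disordered) side-chain atoms are flagged in the
summary rather than having positions invented.

## Operator threading and collision scanning

Threading models a different operator sequence onto a fixed template
backbone: backbone and C1' atoms are carried over bit-identically and
only base atoms are rebuilt from the idealized geometries.  Like-for-like
substitutions reuse the old base's fitted frame; purine<->pyrimidine
swaps use the standard pairing frame derived from the template partner
(the new glycosidic bond then follows ideal Watson-Crick geometry, which
is how interactive model-building tools behave and what the modeled
collision distances presume).  Complementarity across strands is
enforced; when both bases of a pair change, each is rebuilt independently
and the intra-pair geometry is whatever the template frames imply.  No
minimization, repacking or relaxation follows - the procedure is rigid by
design, so a collision means the sequence cannot be accommodated without
structural change.

The scan reports, for every base atom, protein heavy atoms within 4.0 A;
records below 2.85 A are `repulsive`, and N/O-N/O records between 2.6 and
2.85 A are additionally flagged as possible hydrogen bonds rather than
genuine collisions.  Verdicts are monotone in the cutoff.

## The synthetic generator

`build_fiber_bdna` chains base-pair frames with the analyzer's exact
inverse (defaults: twist 36.0 degrees, rise 3.38 A, zero roll, zero
propeller - a straight duplex), places idealized bases in each frame and
a shared B-form sugar-phosphate template alongside.  The template was
optimized once against standard bond lengths/angles, a C2'-endo sugar
pucker and canonical B~I~ torsions (chi -109, delta 137, epsilon -172,
zeta -93, gamma 47, alpha -65, beta 180 degrees), under the helical
symmetry constraint, with the phosphorus position calibrated so that the
minimal cross-strand minor-groove P-P distance of the default duplex is
11.7 A - the regular-B-DNA reference value, an average property of the
fiber model rather than a formula, fixed once and not revisited.
5'-terminal nucleotides carry no phosphate, as in synthesized
oligonucleotides, so a 23-bp duplex exposes 44 classifiable phosphates.

`apply_step_perturbations` rebuilds a fiber duplex with step overrides
and can retarget individual epsilon - zeta values by rotating the
3'-phosphate group about the C3'-O3' bond (sugar fixed) and root-finding
the rotation angle; the classified state then matches the request to
better than 1e-6 degrees.  The moved phosphate strains its P-O5' link -
the perturbation is a classification fixture, not a relaxed conformer.

`make_probe_complex` plants small amino-acid-like groups (Arg-like
guanidinium, Lys-like amine, His-like imidazole, single atom) near a
chosen nucleotide.  The approach direction is found by maximizing
clearance: among 400 candidate directions the one whose placement keeps
all non-target DNA atoms farthest away is selected, which automatically
finds the open groove mouth; the group is then spun about the approach
axis for side-clearance and slid to the first position where the closest
probe-DNA distance equals the request (within 0.05 A).  Infeasible
requests (buried targets) are errors.

What the generator does *not* emulate: sequence-dependent flexibility and
stacking preferences, counterions, solvent, thermal disorder, and real
protein architecture.  Passing tests on synthetic duplexes therefore
demonstrate the correctness of the geometric machinery under controlled
ground truth, not biological realism of the inputs; analyses of deposited
structures are exercised by the network-gated regression tests.

## Numerical choices and degenerate inputs

* Angles in degrees wrapped to (-180, 180]; the wrap maps -180 to +180.
* The mid-frame composition solves for the hinge axis by fixed-point
  iteration (converges in a handful of steps; tolerance 1e-14).
* Superposition uses SVD with a determinant guard so reflections are
  never returned; an independent quaternion-eigenvector oracle verifies
  RMSDs in the tests.
* Base frames need >= 6 ring atoms, otherwise the frame is undefined and
  dependent parameters error with the offending residue named.
* Pair detection returns an explicitly empty, diagnosed result when
  nothing pairs; component selection never returns a silently empty
  model.
* Pipeline stages that cannot run (no protein present, missing atoms)
  degrade to annotated gaps in the report; configuration errors abort
  before any stage runs.

## Problem sizes

The test suite runs entirely on generated inputs: duplexes of 4-40 bp,
random-sequence closure over 20 duplexes, 1000 random dihedral quadruples
against the rotational-search oracle, 50-atom SASA clusters against a
10,000-point oracle run.  These sizes make the default suite complete in
well under a minute on one CPU while exercising every code path; the
acceptance script's duplex is the full 23-bp operator.

## Known limitations

* Contact classification is distance-only; with hydrogens present an
  angular criterion would discriminate better.
* The B~I~/B~II~ band and the groove windows are conventions; counts near
  the band edge are sensitive to them (hence both are configuration
  keys surfaced in reports).
* Threading keeps sugar atoms fixed even for purine<->pyrimidine swaps;
  real DNA would relax the glycosidic geometry slightly.
* The groove profile is the phosphate-to-phosphate definition; refined
  curvilinear-axis widths and groove depths are out of scope.
* No assembly generation or symmetry expansion: the deposited asymmetric
  unit is taken as the complex.
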