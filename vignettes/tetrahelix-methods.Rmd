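---
title: "Methods: sequence and structural analysis of AGCGA-quadruplex DNA"
author: "tetrahelix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence and structural analysis of AGCGA-quadruplex DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrahelix)
```

## The problem

AGCGA-quadruplexes are a tetrahelical DNA family distinct from
G-quadruplexes and i-motifs. Their cores are built from four 5'-AGCGA-3'
tracts held together by non-canonical pairing: G-A pairs in N1-N7,
carbonyl-amino geometry that associate into GAGA-quartets; G-C
Watson-Crick pairs that join through either their minor-groove edges
(guanine amino to cytosine O2) or major-groove edges (cytosine amino to
guanine O6) into GCGC-quartets; G-G pairs in N1-carbonyl symmetric
geometry stabilizing the loop regions, some of them stacked at unusually
large inter-pair twists ("crisscross" couples); and, in
inosine-substituted variants, Hoogsteen G-I pairs. This package provides
the computational workflow around such structures: finding the sequence
consensus in DNA, classifying the pairing and quartets in multi-model NMR
coordinate ensembles, computing the helical/torsional descriptors used to
characterize them, converting NOE volumes into distance restraints, and
generating exact-truth synthetic fixtures for validation.

## Motif scanning

The AGCGA-quadruplex consensus is four literal `AGCGA` repeats separated
by three spacers of 1-20 nt; the G-quadruplex consensus is four `GGG`
tracts with 1-7 nt spacers. `scan_agcga()` / `scan_g4()` enumerate
occurrence chains over the (possibly overlapping) word occurrences.
Coordinates are 0-based half-open internally and in BED output; the TSV
report carries the repeat starts and spacer lengths explicitly.

Two reporting modes exist. `"all"` enumerates every valid decomposition.
`"minimal"` reports non-overlapping matches chosen by leftmost start,
then shortest end, then lexicographically smallest repeat starts; the
implementation is a depth-first search that always tries the nearest
completable next repeat, which is equivalent to the exhaustive rule
because shrinking the current repeat start never shrinks the set of
reachable completions. The test suite verifies this equivalence against a
brute-force enumeration oracle on a thousand random sequences.

`min_spacer` defaults to 1, matching the printed consensus; 0 is exposed
because merged repeats (an adenine deletion between two consecutive
repeats) occur in genomic instances. Minus-strand matches are found on
the reverse complement and mapped back to plus-strand coordinates.
Scanning is strand-aware by default since the biological search is for
folding potential of either strand.

The nearest-neighbour extinction coefficient at 260 nm uses the
Cantor-Warshaw-Shapiro single-strand coefficients shipped as
configuration data: the sum of dinucleotide coefficients minus the sum of
interior mononucleotide coefficients. For the 15-mer
`GCGAGGGAGCGAGGG` this evaluates to 155,200 M^-1^ cm^-1^:

```{r}
extinction_260("GCGAGGGAGCGAGGG")
```

## Coordinate model and base reference frames

`read_structure()` reads multi-MODEL PDB (via bio3d) and multi-model
mmCIF into an ensemble with one shared topology and per-model coordinate
matrices; hydrogens are retained because NMR ensembles carry them and the
hydrogen-bond detector uses them. Deoxyinosine (`DI`) is a first-class
residue type with a hypoxanthine base template.

Each base receives a right-handed orthonormal frame by least-squares
(Kabsch) superposition of an idealized base onto the observed ring atoms.
The idealized templates (`extdata/base_templates.tsv`) are Chemical
Component Dictionary ideal residue geometries re-expressed in the
standard nucleic-acid base reference frame, with the sugar-phosphate
moiety rotated about the glycosidic bond to a B-DNA-like anti chi of
240 degrees so that backbone-bearing synthetic fixtures are
conformationally typical. In this frame an ideal Watson-Crick partner is
the same-origin frame flipped 180 degrees about x, which the template set
reproduces to within 0.1 A hydrogen-bond geometry.

Pair and step parameters use the mid-frame (CEHS-style) formalism:
translations (shear/stretch/stagger, shift/slide/rise) are expressed in
the mid frame and rotations are decomposed into x/y/z components
(buckle/propeller/opening, tilt/roll/twist). For antiparallel pairs the
strand-II frame is flipped about x before the computation; pairs whose
base normals already agree -- the C2-symmetric N1-carbonyl G-G pair is
the relevant case -- are not flipped and show a characteristic opening
near 180 degrees. The construction is exactly invertible:
`frame_step_inverse()` realizes any parameter set about an identity mid
frame, and the test suite checks round trips to 1e-9 and rigid-motion
invariance to 1e-6.

A quartet's unit frame is anchored to its first constituent pair (origin
at the centroid of the two pair frames). A C2-symmetric quartet's
in-plane orientation is only defined modulo 180 degrees, so anchoring is
required for deterministic step twists between stacked quartets. Quartet
non-planarity ("quartet buckle") is not given a formal definition in the
experimental literature; here it is the angle between the best-fit planes
of the two constituent base pairs, in [0, 90] degrees, with the rms
deviation from a single quartet plane reported alongside. This
interpretation is prominent in the output metadata.

## Hydrogen bonds and classification

Each hydrogen is assigned to its nearest heavy atom (within 1.8 A); N/O
parents become donors. A bond requires donor-acceptor distance at most
3.5 A and donor-H-acceptor angle at least 120 degrees -- conventional
cutoffs, exposed in the configuration. Models without hydrogens fall back
to a per-base heavy-atom donor list with the distance criterion alone.

Pair classification is data-driven: `extdata/pair_patterns.tsv` maps
donor-atom/acceptor-atom patterns to classes (WC G-C; G-G N1-carbonyl
symmetric, reciprocal N1-H...O6; G-A N1-N7 carbonyl-amino; Hoogsteen G-I,
guanine WC edge donating into the hypoxanthine N7/O6 face), each with a
minimum bond count of two. New geometries are added by editing the table.
Quartets are assembled from classified pair couples with at least two
class-specific cross-links (GAGA: A N6-H to G N7; minor-groove GCGC: G
N2-H to C O2; major-groove GCGC: C N4-H to G O6), and GGGG quartets
directly as directed 4-cycles in the guanine N1-to-O6 / N2-to-N7 bond
graph. Membership conflicts are resolved by maximal total hydrogen-bond
count, then lowest residue indices, making reports deterministic.
Crisscross couples are stacked pair couples joining the same two strands
with inter-pair twist at least 35 degrees (the experimentally described
couples show 40-60 degrees).

## Torsions, puckers, grooves

Backbone torsions use the IUPAC atom quadruples; terminal residues report
absent alpha or epsilon/zeta as NA. Sugar pucker uses the
Altona-Sundaralingam pseudorotation formalism on the five endocyclic
torsions; North is P in [324, 36] and South P in [108, 180]. Glycosidic
classes are syn for chi in (0, 120), anti for [170, 280] and high-anti
for (280, 320] -- the anti window is anchored to the purine chi restraint
window used in the underlying structure calculations, and the syn window
to the standard +sc region (a published decision was internally
inconsistent here, so the package fixes the windows explicitly). Groove
width is the cross-strand P-P distance minus 5.8 A, labelled narrow
(< 4), medium (4-9) or wide (> 9), all configurable.

## NOE restraints

Calibration averages (arithmetically) the intra-nucleotide H8-H1' volumes
of residues supplied as clearly anti and maps that mean to 3.9 A.
Distances follow the isolated-spin-pair relation
r = 3.9 (V~ref~/V)^1/6^. Bin bounds are the standard strong (1.8-3.6),
medium (2.6-5.0), weak (3.5-6.5) and very weak (4.5-7.5) A classes. The
bins overlap, so bounds alone cannot define the assignment rule; the
class cutoffs on the estimated distance (3.0 / 4.2 / 5.5 A, near the bin
midpoints) are an explicit, configurable decision recorded in output
provenance. Anti purines receive chi restraints of 170-280 degrees and
anti pyrimidines 170-310 (force constant 200); classified hydrogen bonds
become 2.7-3.1 A heavy-atom restraints (force constant 20); GAGA-quartets
and N1-carbonyl G-G pairs receive planarity groups (force constant 50).
Restraint counts are properties of the supplied peak data and are carried
as provenance, never asserted as constants.

## The synthetic generator

`build_quartet_stack()` is the package's ground truth. Layer geometries
are solved once per session by deterministic multi-start Nelder-Mead
minimization of an objective that scores each class-defining hydrogen
bond (target donor-acceptor 2.9 A, near-linear via the attached
hydrogen) plus a steric penalty between non-bonded heavy atoms closer
than 3.1 A; the Watson-Crick pair needs no optimization because the
standard reference frame construction is exact. Pair layers are C2
solutions about the layer normal where the class demands it (N1-carbonyl
G-G), in-plane flipped arrangements otherwise; quartets are C2 (or, for
GGGG, C4) arrangements about an optimized in-plane center.

Stacking applies a cumulative twist about z and rise along z to each
layer's unit-frame-normalized layout, so injected rise and twist are
recovered exactly by construction. Buckle and propeller are injected
through the inverse mid-frame construction and are exact for
Watson-Crick pair layers; for quartet layers the `buckle` argument
rotates the second pair's plane and equals the resulting quartet buckle.
The injection-recovery sweep (rise 2.5-5.5 A, twist -60 to 60, buckle
-40 to 40 degrees) recovers all parameters to machine precision, far
inside the 0.1-unit acceptance band.

Default geometric parameters (rise 3.4 A, twist 25 degrees) are the
values characteristic of stacked GAGA-quartet cores in the experimental
ensembles; noise is isotropic Gaussian per atom under a fixed seed.
Class recovery on noiseless stacks is exact; at sigma = 0.15 A the
2.9 A bonds occasionally jitter past the 3.5 A detector cutoff, so
recovery is checked under fixed seeds and observed at 95-100%.

`plant_sequence_motifs()` writes exact truth tables for planted consensus
matches (recall is 100% at zero mutation rate), and
`simulate_noe_volumes()` generates volumes as V = scale r^-6^ e^eps^
with log-normal noise. Geminal and covalently close proton pairs
(< 1.8 A) are excluded from the default enumeration because such
cross-peaks are never used as distance restraints; with that convention
the zero-noise round trip brackets every true distance and 20%
multiplicative noise retains at least 95% containment.

What the generator does **not** emulate: solvent and counter-ion effects,
spin diffusion and anisotropic tumbling in NOE volumes, conformational
heterogeneity across models (noise is uncorrelated, real ensembles are
not), and sequence context around planted motifs beyond i.i.d.
backgrounds. Passing the synthetic checks therefore validates the
computational machinery, not the experimental interpretation of any
particular real ensemble.

## Topology calls

A structure is called a TYPE 1 AGCGA-quadruplex when it contains at least
two stacked GAGA-quartets plus at least one GCGC-quartet, and TYPE 2 when
at least four central G-C pairs occur with peripheral G-A pairs but no
GAGA-quartet; anything else is "none". These thresholds operationalize
prose definitions and are configuration-exposed. Quartet stack order is
reported along the first principal axis of the quartet centers, which
reproduces the expected core ordering
(GCGC/GGGG/GAGA/GAGA/GGGG/GCGC) on tetramer-like stacks.

## Problem sizes and validation scale

The shipped validation uses 300-1000 random sequences per scanner
property, stacks of up to 10 layers, ensembles of up to 5 models and NOE
tables of ~400-500 peaks; these sizes give stable statistics for every
property while keeping the default check suite fast. Deposited
experimental ensembles are supported as optional inputs: placing
`5M1L.pdb` / `5M2L.pdb` under `inst/extdata/deposited/` (or pointing the
`tetrahelix.deposited_dir` option at a directory containing them)
activates the full published-characterization checks in the test suite;
the files are not redistributed with the package.

## Known limitations

- Helical parameters follow the package's own mid-frame implementation;
  agreement with other tools is expected within a few tenths of a degree
  for near-planar pairs but conventions for strongly non-planar,
  parallel-stranded pairs differ across tools.
- The hydrogen-bond criteria of the original structure determination are
  not published; consensus-level agreement, not per-bond agreement, is
  the supported comparison.
- `analyze_structure()`'s TYPE 2 call is tentative when only part of the
  defining evidence is present; the report carries the raw pair/quartet
  tables so users can apply their own rules.
- No curvilinear helix axis, groove-width refinement against a reference
  frame set, or Leontis-Westhof 12-family annotation.
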