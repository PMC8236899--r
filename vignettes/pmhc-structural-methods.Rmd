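---
title: "Methods: comparative structural analysis of peptide-MHC complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative structural analysis of peptide-MHC complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmhcstruct)
```

This vignette documents the models, conventions and numerical choices behind
`pmhcstruct`, in the order the pipeline applies them. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## The unified domain frame

MHC class I (heavy chain + β₂-microglobulin) and class II (α + β chains)
ectodomains are compared under one nomenclature: `pa` = I-α1 or II-α1 and
`pb` = I-α2 or II-β1 form the peptide-binding superdomain `pab`; `ia` =
β₂-m or II-α2 and `ib` = I-α3 or II-β2 are the membrane-proximal IgSF C1
domains. Canonical per-domain numbering (rooted in the classic HLA-A2
numbering, with lowercase insertion codes such as `pb90b`) and the peptide
register P1…PΩ are **configuration, not inference**: the evolutionary
correspondence between positions comes from a hand-curated alignment whose
loop regions are genuinely ambiguous, and class II peptide registers are
established crystallographically. Re-deriving either at runtime would be a
research project of its own, and silently wrong numbering would corrupt
every downstream measurement. Each structure therefore carries a small YAML
document mapping author chains and residue ranges to canonical positions
(inclusive ranges, author numbering, PDB convention), with an insertion
table for the positions that need codes and the author numbers of P1 and
PΩ as register anchors. The map is validated to be bijective; unmapped
polymer residues are reported, never dropped.

Coordinate input is parsed through bio3d (PDB and mmCIF); alternate
locations are reduced to the highest-occupancy conformer (ties by altloc
letter) so that downstream geometry is deterministic. Hydrogens, absent
from most crystal structures, are never required: all geometry uses heavy
atoms, and the amide H is reconstructed where the hydrogen-bond model needs
it.

## Backbone hydrogen bonds and secondary structure

Backbone N–H…O=C bonds use the Kabsch–Sander electrostatic model with the
standard constants: partial charges ±0.20 e (N/H) and ±0.42 e (C/O) give

E = 27.888 · (1/d(ON) + 1/d(CH) − 1/d(OH) − 1/d(CN)) kcal/mol,

accepted below −0.5 kcal/mol, clamped at −9.9 for near-contact geometries.
The amide H sits 1.0 Å from N along the previous residue's O→C direction —
the rule the reference DSSP implementation uses (a bisector placement is
sometimes described in the literature; we follow the implemented rule, which
is what the frozen oracle strings in the tests were generated against).
Proline donates nothing; a C–N distance above 2.5 Å is a chain break. A
9 Å CA–CA prefilter bounds the pair scan; the tests verify on every fixture
class that it loses no bonds.

States follow the DSSP pattern rules: an n-turn at i is a bond CO(i)←NH(i+n);
two consecutive n-turns make a minimal helix spanning i…i+n−1 (minimum
lengths α ≥ 4, 3₁₀ ≥ 3, π ≥ 5); parallel/antiparallel bridges chain into
ladders, and ladders linked across gaps of at most 2 residues on one strand
and 5 on the other are merged (this is how β-bulges keep their sheet
membership). Bridge partners must have existing, chain-continuous
neighbours, so terminal residues never form bridges — matching the
reference implementation's edge behaviour, which the oracle comparison made
visible. Bends (κ > 70° over CA(i−2), CA(i), CA(i+2)) are reported as their
own state. Where patterns overlap, precedence is π > α > strand > 3₁₀ >
turn > bend: the π-over-α exception follows modern DSSP (≥ v3) and is what
reproduces π-helix calls at the H2a/H2b helix kink of primitive class I
structures; because older DSSP versions subordinate π, such calls are
version-sensitive and treated as soft expectations. Isolated single bridges
are bridges, not strands, and collapse to coil in the reported state set.

## Sheet topology and the two conserved irregularities

Strand runs are labelled S1, S2, … within each domain in canonical sequence
order (with the conventional A–G aliases in IgSF domains); counts other
than 4 per p-domain or 7 per IgSF domain are labelled best-effort with a
warning rather than an error, because real loops truncate strands.

A **β-bulge** is read off the merged ladder rungs: consecutive rungs whose
index step is one larger on one strand than on the other mean one extra
residue was squeezed in — two consecutive residues opposite a single
partner residue, flanked by regular pairs. Three gap signatures are
accepted, (1,0), (2,1) and (3,2), because the bulge may fall on a
doubly-bonded or a non-bonded pleat position, destroying one or two
additional rungs around it. Sidechain direction is the mean CB−CA vector of
the bulge pair against the least-squares sheet plane, "up" oriented toward
the helix CA centroid (dead band |cos θ| < 0.3 reported as lateral).

The **S2–S3 cleft** is decided from main-chain pairing only: strands S2 and
S3 of a p-domain are identified as the strands containing canonical
positions 24 and 36 (the definitional anchor pair), the facing (bridge)
pairs between them are collected, and the outermost pair is reported. The
cleft is present exactly when pairing stops at p24–p36; pairing reaching
p22–p38 means no cleft. When S2 or S3 cannot be identified the status is
undetermined, never false.

## Superposition

Domain superposition uses the Kabsch algorithm (SVD of the 3×3 covariance,
reflection excluded by the determinant correction) over CA atoms matched
through shared canonical ids — the alignment already states which residues
correspond, so a sequence-independent structural aligner would only add
nondeterminism. Consequently RMSD values may differ slightly from those a
structural aligner would report; orientation comparisons, the actual use,
are unaffected. Collinear point sets and correspondences below 3 atoms are
errors; residues missing the fitting atom are dropped with a count.

## Accessibility, contacts and interfaces

Solvent accessibility is Shrake–Rupley: per atom, the fraction of test
points on the sphere of radius r_vdW + 1.4 Å not occluded by any
neighbour's sphere, times the sphere area. Points are a deterministic
golden-spiral set (default 960 per atom; the tests check convergence
against 4000), expressed in the molecule's principal-axis frame with
third-moment sign anchoring so that areas are exactly invariant under rigid
transformation of the input; computations that must cancel across several
selections of the same structure (interface ΔSASA, knob burial, peptide
exposure) share one frame derived from the union. Radii are a single
Bondi-type element table shipped with the package; unknown elements fall
back to 1.70 Å with a warning. Because the exact radii behind published
interface tables are generally unspecified, absolute areas carry a
few-percent method variance and nothing in the package treats them as
exact; differences and flags are the robust outputs.

Contacts use the field's 4.0 Å any-heavy-atom convention; polar contacts
are N/O/S pairs at 3.5 Å, optionally bridged by water oxygens; disulfides
are SG–SG ≤ 2.5 Å. Interface summaries report any-burial interface
residues (ΔSASA > 0.1 Ų by default, the any-burial convention of
published interface tables) and the symmetric buried area
½(A_alone + B_alone − AB); per-side values are recoverable from the
per-residue ΔSASA tables. Waters are excluded from occlusion by default and
includable by flag (this matters only for water-mediated pocket networks).

## Peptide geometry and the knob score

The register report measures the P1–P9, P2–P9 and P1–PΩ CA spans, the bulge
height (maximum CA deviation from the straight P1→PΩ axis — an end-anchored
definition, not a fitted line, matching how peptide arching is described),
and per-register sidechain orientation: the sign of (CB−CA)·n̂ with n̂ the
pab strand-plane normal oriented toward the helix centroid (falling back to
the peptide centroid when no helices are assigned), with the ±0.3 cosine
dead band. Class I complexes show the arched peptide with P1 up and PΩ
down; class II shows the extended peptide with both down.

The knob score is the fractional burial of the ia56+ia60 sidechain atoms
(all non-backbone atoms) against the pab selection:
1 − SASA(sidechains | knob + pab) / SASA(sidechains | knob alone). The
insertion flag uses a 0.6 threshold, chosen so that the class I inserted /
class II not-inserted contrast separates cleanly; the continuous score is
always reported alongside, and glycine at a knob position yields an
undefined per-residue burial rather than a silent zero.

## Conservation

Per-domain identity is 100 × matches / columns where both sequences are
non-gap, restricted to the domain block; `X` counts as a mismatch, not a
gap. The denominator convention is not universal (block length is the main
alternative), which is why reported identities are rounded to integers and
compared with ±1 point slack. The lineage classifier evaluates rules in
fixed precedence — MHC-characteristic (all MHC groups conserved, outgroup
not) > ancestral (all groups) > a-/b-lineage > class-specific — where a
rule fires if some residue-type set (singletons plus the standard property
groups) reaches the support threshold (default 0.8) in every required group
and stays below it in every excluded group. Columns that only pass at a
relaxed 0.5 support are reported with `uncertain = TRUE`, mirroring the
low-confidence small-font tier used when such alignments are shaded by
hand. Published shading of this kind is explicitly partly subjective; the
classifier is deterministic given its configuration, and disagreements are
logged, not hidden.

## The synthetic-data generators

The generators exist to give every detector a constructed answer; they are
geometric caricatures with ideal bond lengths and angles, not homology
models, and they are bitwise-deterministic.

* Helices place poly-alanine backbones at exact φ/ψ (α −57/−47, 3₁₀
  −49/−26, π −57/−70, ω = 180), with CB at the L-configuration improper
  torsion (N–C–CA–CB = −120°, checked against reference residue
  geometry).
* β-sheets tile a flat-strand template whose φ/ψ (−150.32/148.40) were
  solved so that the two-residue screw repeat is a pure translation *and*
  the NH/CO vectors lie in the sheet plane; neighbouring strands are
  related by a two-fold rotation about the sheet normal with placement
  offsets (axial 2.498 Å, spacing 4.397 Å, plus a half-repeat shift for
  odd strand lengths, whose pairing parity differs) fixed once by
  minimising the ladder's Kabsch–Sander energy. An engineered bulge lifts
  one residue 1.5 Å out of the plane between two template slots and slides
  the downstream segment by (1.05, 0, 0.7) Å so the chain neither collapses
  onto the vacated peptide bond nor grazes the partner strand's
  sidechains; valid positions are 5…L−3 because the flanking regular pairs
  must themselves be detectable rungs under the terminal-residue rules.
* Toy complexes assemble an 8-strand floor (two 4-strand halves = pa and
  pb, canonical positions 1–40 plus helix positions from 46), two α-helical
  walls, a groove peptide and two helical IgSF stand-ins. The class II
  variant uses 18-residue walls and a 13-mer whose P−2/P−1 and P10/P11
  registers extend beyond the wall span; the class I variant uses 22-residue
  walls enclosing a 9-mer whose midsection is lifted (sin² profile, 2 Å)
  and whose P1 residue is rotated 180° about the peptide axis so its
  sidechain points up. Wall offsets (±6.6 Å lateral, 9 Å above the floor)
  were chosen once so that the peptide contacts floor and walls inside
  4.0 Å with no non-bonded heavy-atom pair below 2.2 Å. Ground truth —
  the peptide–pab contact list from an independent nested-loop scan at
  build time, the planted register, and the programmed ib hinge
  displacement — is stored with the object. The `ib_hinge_angle` rotates
  the ib stand-in about the wall axis through its attachment point, giving
  a closed-form centroid displacement of 2·|c−h|·sin(θ/2) for hinge point
  h and centroid c.
* Toy alignments plant per-column scenarios by drawing conserved groups
  from one residue family and unconserved groups from the four remaining
  disjoint families, one per member cycle, so no type set can reach 50%
  support by accident.

What passing tests on these fixtures shows — and what it does not: the
detectors are exact on geometry that realises their defining patterns
cleanly, and the measurement stack is internally consistent and invariant
under rigid motion. Real crystal structures add missing atoms and
residues, alternate conformations, distorted geometry near ligands, and
numbering quirks; the parser, numbering machinery and warnings are built
for those, but detector accuracy there is bounded by the published
qualitative calls the acceptance tests encode, not by the synthetic
recovery rates.

## Problem sizes and runtime choices

The shipped suite runs the toy complexes (~150 residues, ~780 atoms),
sheets up to 4×12 and alignments of ≤ 25 sequences; pipeline-level tests
and the acceptance script use 240–480 SASA sphere points where only
self-consistency matters, and the default 960 where closed-form accuracy
is asserted. Randomised property checks use 50–100 replicates under fixed
seeds. These sizes keep the full suite around a minute and a half on one
CPU while every code path, including the exhaustive no-prefilter hydrogen
bond scans and brute-force contact oracles, is exercised.

## Known limitations

* The DSSP equivalence is anchored to a specific reference implementation;
  π-helix calls differ across DSSP versions, and the package follows the
  modern precedence.
* Interface areas are method-variant at the few-percent level (radii,
  point counts); only differences and flags are treated as robust.
* Canonical numbering configurations for real structures are transcribed
  by the user; the package validates bijectivity but cannot validate
  evolutionary correctness of a hand-curated alignment.
* Peptide register inference (which pocket holds P1) is out of scope by
  design; registers are configuration.
* No groove-volume or pocket-cavity computation; pocket residue lists are
  configuration, not detection.
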