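---
title: "Quadruplex conformational analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadruplex conformational analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4conform)
```

This vignette records the scientific model behind `g4conform`, the
conventions and tunable parameters it relies on, what the synthetic
generator does and does not emulate, and the numerical choices made
where the design was genuinely open. It states no empirical number that
the test suite or `scripts/acceptance.R` does not itself compute.

## Conformational coordinates

Every nucleotide is reduced to two coordinates. The glycosidic torsion
χ (O4′–C1′–N9–C4 for purines, O4′–C1′–N1–C2 for pyrimidines) is
reported on [0°, 360°) with the IUPAC sign convention. The sugar pucker
is summarised by pseudorotation: with the endocyclic torsions indexed
ν₀ = C4′–O4′–C1′–C2′ through ν₄ = C3′–C4′–O4′–C1′ (so that
ν₂ = τ<sub>m</sub> cos P holds as written), we set
x = ν₂ and y = (ν₄ + ν₁ − ν₃ − ν₀) / (2 (sin 36° + sin 72°)) and take
P = atan2(y, x), τ<sub>m</sub> = √(x² + y²). The atan2 form fixes the
quadrant of P from the signs of numerator and ν₂ and degrades gracefully
when ν₂ passes through zero; a ring with all |ν| < 1° is rejected as an
undefined pucker rather than classified.

**Domain boundaries.** Only the low-syn band ([300°, 360°)) has a
sharply motivated definition — glycosidic angles beyond the typical
high-anti range that behave syn-like in V-loop anchors. The remaining χ
cuts (syn/intermediate at 120°, intermediate/anti at 180°, anti/low-syn
at 300°) follow common usage; they are package conventions chosen once
so that the partition is testable, not measured facts. North/south is
split at P = 90°/270°, the standard wheel halves; finer description
goes through the conformer label (20 envelope/twist names on an
18°-wide wheel, C3′-endo centred at 18°), so "south-east" puckers are
reported as C4′-endo/O4′-endo-region labels rather than as a third
domain. Angles averaged across ensemble models use circular means
because χ and P wrap at 360°.

## Chemistry detection

Residue codes for modified nucleotides are not trusted: chemical
component codes for LNA and 2′-F sugars vary across deposits. Instead,
the sugar chemistry is derived from geometry: a carbon bonded (< 1.8 Å)
to both O2′ and C4′ marks the 2′-O-4′-C methylene bridge of a locked
(LNA) sugar; a fluorine bonded to C2′ marks a 2′-F sugar, with the
ribo/arabino epimer decided by whether the fluorine lies on the
opposite or the same face of the sugar ring as the base attachment
(sign comparison against the ring-plane normal, invariant under rigid
motion and consistent under reflection because both signs flip); an
unbridged O2′ is ribose; otherwise deoxyribose. Missing ring atoms give
`"unknown"` rather than an error so that partial residues pass through
reports visibly.

## Quartet detection and topology

A Hoogsteen edge A→B requires **both** heavy-atom distances
d(N1_A, O6_B) and d(N2_A, N7_B) within the cutoff (default 3.5 Å). The
criterion is deliberately hydrogen-free: NMR deposits carry hydrogens
but crystallographic ones often do not. Quartets are directed 4-cycles
of such edges, reported once (canonical rotation starting at the lowest
chain/residue member), with two geometric guards: the four base
centroids must be coplanar within 1 Å, and no two members may come
closer than 5 Å centre-to-centre. The guards exist because at relaxed
cutoffs a stacked pair of quartets can form spurious cycles mixing two
layers; genuine quartet neighbours sit 6–7 Å apart while stacked bases
sit at 3.3–4.5 Å, so the separation test cleanly discriminates. Cycles
sharing three or more members are merged, keeping the smaller mean
hydrogen-bond distance.

Detection uses a moderate relaxation ladder (cutoff × 1, × 1.15,
× 1.3; column matching + 0, + 0.75, + 1.5 Å): the smallest cutoff
recovering the maximal quartet count wins, and any relaxation is
flagged in the result. The intent is that noisy ensemble members
degrade *visibly* — a partially unfolded model either still yields the
majority topology or carries a flag/error — never silently flip a
label. The per-ensemble topology is the majority vote over per-model
topologies; ties and disagreements are flagged with per-model labels
retained.

The stack axis is the first principal direction of quartet centroids,
oriented so that layer 1 contains the 5′-most core guanine — a fixed
reference that makes polarity signs and layer indices reproducible.
Only *relative* polarities (homopolar/heteropolar) and polarity
*equality* (the V<sub>S</sub>/V<sub>R</sub> call) are meaningful across
software, since no absolute sign convention is standard.

**Tracts and loops.** A tract is a maximal run of sequence-consecutive
core guanines sharing a column (chain-internal adjacency only, so
bimolecular cores whose columns mix chains are handled). Consecutive
core anchors in different columns define a loop over the intervening
non-core residues: same-layer connections are lateral (adjacent
columns) or diagonal; opposite-end connections are propeller loops when
both anchor tracts fill their columns, and V-shaped when the column
pair is interrupted (at least one anchor tract shorter than the layer
count), the columns are neighbours, at most two residues intervene and
at least three layers are spanned. The "interrupted column" criterion
operationalises the isolated guanine at a V-loop 5′-end: its column is
completed by guanines from elsewhere in the sequence.

**V-loop subtyping.** The inversion site is located from per-residue
backbone orientations — the sign of the axis-projected C5′→C3′ vector.
A literal walk over C1′ positions cannot distinguish the two subtypes:
with anchors on opposite outer layers, the jump step always reverses
the entry step, so a step-sign scan would label every V-loop identical.
The backbone orientation, by contrast, captures strand polarity
directly: opposite orientations at the two anchors put the inversion
within the loop (alternative subtype); equal anchor orientations with a
change towards the next core guanine put it after the loop
(conventional). If no orientation change occurs across anchor-5′,
anchor-3′ and the following guanine, the V-loop is reported as
inconsistent rather than guessed. The polarity class compares the
tetrad polarity signs of the two linked quartets (equal → V<sub>S</sub>,
opposite → V<sub>R</sub>) and is independent of the subtype; the
generator builds all four combinations and the suite checks them.

## Contacts

The base–backbone contacts of interest (O4′/O5′/F2′/O2′ ··· H8–C8) are
measured as acceptor–H8 distance and acceptor–H8–C8 angle. When a
deposit lacks H8, it is reconstructed in the N7–C8–N9 plane along the
external bisector at C8 with a 1.08 Å bond; on fixtures with built
hydrogens the reconstruction lands within 0.05 Å and changes contact
distances by under 0.1 Å. Presence thresholds are ≤ 3.5 Å (present) and
≥ 4.0 Å (absent), with an explicit ambiguous band between — short
contacts in these motifs cluster near or below 3 Å while their absence
shows as > 4 Å, and the band encodes the grey zone instead of hiding it.
Both thresholds are configurable. The angle is reported but never gates
the call: these CH···O-type interactions are genuinely acute (around
90–105°) and an angle filter tuned for canonical hydrogen bonds would
discard them. Ensemble scans report per-model values plus mean, min,
max and occupancy (fraction of models with a present call); distances
do not wrap, so plain means are used.

## Superposition and precision

Superposition is a least-squares rigid-body fit (Kabsch, via SVD, with
the determinant correction that forbids reflections). Pairwise ensemble
RMSD fits and measures on the same selection by default — matching the
G-core pairwise phrasing used for quadruplex ensembles — with an
optional distinct fit selection. The G-core selection is derived from
quartet detection, not residue numbers, so the same call works across
entries. An independent quaternion-method implementation serves as the
oracle in the test suite; the two agree to 1e-9 on random inputs.

## The synthetic generator

The generator exists to make every classifier testable without
downloads. It emulates, with idealized geometry:

* furanose rings solved numerically for any (P, τ<sub>m</sub>) with
  τ<sub>m</sub> ≤ 65° at standard bond lengths (C–C 1.52 Å, C–O
  1.41 Å). Not every torsion target is exactly closable with rigid
  bonds, so closure is solved in least squares over all five torsions;
  the residual is almost orthogonal to the pseudorotation cosine wave,
  and re-analysis recovers (P, τ<sub>m</sub>) within 1° across the
  wheel (the acceptance script measures the worst case over 50 random
  draws);
* planar bases from standard reference geometry, rotated to any χ
  exactly;
* Hoogsteen quartets solved so both hydrogen-bond distances sit at
  2.9 ± 0.1 Å around the cycle, mirrored in-plane for reversed
  polarity;
* complete quadruplexes: quartets stacked at 3.3 Å rise and 26° twist
  (typical potassium-form values), the chain threaded through planned
  tract slots, loop residues placed on outward arcs, phosphates bridged
  at 1.6 Å from the preceding O3′, per-model iid Gaussian coordinate
  noise (default σ = 0.2 Å, ten models — an NMR-ensemble-like spread),
  all reproducible from a seed, with ground-truth labels returned
  alongside.

The defaults were chosen once as field-typical values and are not
adjusted per test. What the generator does **not** emulate: energetics
(backbones between anchors are geometric, not minimized), realistic
loop conformers, counter-ions, and the physical coupling between
glycosidic angle, strand direction and tetrad polarity — the generator
exposes these as independent dials so that all label combinations can
be exercised, including combinations rare or impossible in real
structures. Because the noise is iid per atom, σ = 0.2 Å visibly
distorts endocyclic torsions of individual models (real NMR ensembles
preserve local geometry and vary collectively); torsion-level
assertions therefore use low-noise builds, while label-recovery tests
run at σ up to 0.3 Å. Passing tests on mocks demonstrate that the
classifiers invert the generator's geometric definitions under moderate
noise — they do not by themselves validate the classifications against
experimental ensembles, which is what the reference-entry checks (PDB
6YCV, 6YEP, 6TCG, 1U64; network required) are for.

## Numerical choices and degenerate inputs

* Torsions use the atan2 normal-vector form; coincident or collinear
  points raise a geometry error rather than returning NaN.
* The ring and quartet solvers are Nelder-Mead with multiple starts and
  fixed deterministic start lists; solutions are cached per target.
* Column matching between adjacent layers is the exact minimum-cost
  assignment over all 24 permutations — no greedy tie-break.
* Alternate locations: only blank or "A" records are kept, for
  deterministic behaviour on the rare ensembles that carry them.
* Multi-model files are validated to share one residue sequence and
  atom inventory after atom-name normalisation (prime marks, OP1/O1P);
  the first offending residue is named in the error.
* Waters, ions and non-nucleotide residues are retained in the
  container but flagged out of every analysis.
* Report numbers are formatted at fixed precision (angles 0.1°,
  distances and RMSD 0.01 Å) so repeated runs produce byte-identical
  files.

## Problem sizes

The test-suite and acceptance-script sizes — 50 random ring targets,
100 random torsion quadruples, 300–500-atom superpositions, 20 random
mock topologies at up to σ = 0.3 Å with 3-model ensembles, and 10-model
ensembles for the preset analyses — were chosen as the smallest sizes
at which the checked properties are stable across seeds.

## Known limitations

* Loop taxonomy covers lateral, diagonal, propeller and V-shaped
  connections; bulges, snapback tails and duplex–quadruplex hybrids are
  out of scope, as are tetrads other than G-quartets.
* The V-loop span rule (≥ 3 layers, ≤ 2 intervening nucleotides)
  admits the described 1–2 nt variants but will not recognise longer
  V-like connections.
* Chemistry detection requires the furanose ring atoms; heavily
  disordered sugars classify as unknown.
* The absolute tetrad polarity sign is a package convention; compare
  only relative polarities across tools.
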