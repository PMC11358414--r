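---
title: "Methods: conservation and contact-network analysis of receptor activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation and contact-network analysis of receptor activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consnet)
```

consnet implements an evolutionary–structural workflow for
G-protein-coupled receptors, built around the class F family (the ten
Frizzleds and Smoothened). Two composed analyses sit on top of reusable
stages: the *water-network* analysis, which asks which class-wide
conserved residues both rewire their contacts upon activation and line
the internal water pocket, and the *sterol-site* analysis, which asks
whether conserved, structurally continuous surface residues cluster at
the cholesterol-binding face. This vignette documents the models, the
parameters that matter, and the choices made where the design was open.

## Ortholog conservation

The substrate is a gapped multiple sequence alignment of orthologs of
one receptor. For column $j$ with non-gap depth $n_j$, let $m_j$ be the
most frequent symbol (ties between residues break alphabetically; the
gap wins only on strict majority). If $m_j$ is the gap the column scores
0 and is not conserved. Otherwise

$$f_j = \frac{c(m_j) + \sum_{b \in S(m_j)} c(b)}{n_j},$$

where $c(\cdot)$ are column counts and $S(a) = \{b \neq a :
\mathrm{score}(a,b) > t\}$ is the similarity group of $a$ under a
substitution matrix (BLOSUM80 by default, threshold $t = 1$, strict
inequality). A column is conserved when $f_j \ge 0.9$; the comparison is
greater-or-equal, applied with a $10^{-9}$ tolerance so that a column at
exactly 90% passes. Published BLOSUM80 tables exist in more than one
scaling, so every function accepts a caller-supplied matrix; the test
fixtures use a deliberately simple toy matrix with six similarity groups
to avoid depending on any particular published variant.

## Cross-paralog conservation and divergence

Positions aligned across the 11 class F receptors carry two summaries.
The *class-wide fraction* is the share of receptors whose orthologs are
conserved at the position (8 of 11 receptors gives 72.7%). *Divergence*
is the Shannon entropy, in bits, of the 11 per-receptor modal residues:

$$H = -\sum_r p_r \log_2 p_r .$$

Bits (base 2) are used because the two anchor cases then take the
familiar values: 0 for a position identical in all receptors, and 0.44
for a position where exactly one receptor of 11 deviates. Position
selection rules expose the cutoffs used by the two analyses: the
water-network analysis admits entropy up to 0.44 bits; the sterol-site
analysis takes the union of zero-entropy positions and positions whose
variation is restricted to residues scoring strictly above 2 in the
substitution matrix. Positions where any receptor's modal symbol is a
gap have undefined entropy and are never selected.

## Residue–residue contact scores

A contact network summarises packing: for residues $i < j$ (ordered by
chain, then number),

$$\mathrm{RRCS}(i,j) = \sum_{a \in i}\sum_{b \in j} w(d_{ab}), \qquad
w(d) = \begin{cases} 1 & d \le d_c \\
\dfrac{d_0 - d}{d_0 - d_c} & d_c < d < d_0 \\
0 & d \ge d_0 \end{cases}$$

over heavy atoms only, with $d_c = 3.23$ Å and $d_0 = 4.63$ Å. For
residues on the same chain within four positions of each other the
main-chain atoms (N, CA, C, O) of both residues are excluded, so trivial
backbone adjacency does not flood the network. Waters and ligands are
excluded; inter-chain pairs are off by default (the analyses are
single-receptor). The constants are parameters of `rrcs_params()` so
divergent calibrations can be configured. A bounding-sphere prefilter
skips residue pairs that cannot score, and the test suite holds the
result bit-for-bit equal to the exhaustive double loop.

The activation network is the signed difference
$\Delta = \mathrm{RRCS}_\mathrm{active} - \mathrm{RRCS}_\mathrm{inactive}$
over residues matched by (chain, number, insertion code, name); a pair
absent on one side contributes 0 there, and unmatched residues (for
example a loop disordered in one state) are reported rather than
silently dropped. No significance threshold is built in: callers must
state `min_abs_delta` explicitly, because no principled default exists.

## Mapping onto structures

*Water adjacency*: a residue is water-adjacent when any heavy atom lies
within 3.5 Å of a water oxygen — a hydrogen-bond heavy-atom distance; no
cutoff is canonical, so it is a parameter. *Ligand contact* uses 4.5 Å
against named sterol ligands (CHS/CLR), a hydrophobic-contact range.
Both sets are monotone in their cutoff.

*Surface* detection uses a coordination-number proxy instead of solvent
accessible surface area: a residue is surface if its Cα has at most
`surface_burial_max` neighbouring Cα within 10 Å. The default (20) is
calibrated on the synthetic 7-helix bundle, where planted outward-facing
patch residues reach 20 neighbours while crowded inter-helix residues
reach 21–24. On large real structures with true cores, a stricter value
is appropriate; the parameter exists for exactly that reason.

*Patches* are the connected components (Cα within 8 Å) of the residues
that are both conserved and surface, dropped below 3 members, ranked by
aromatic count (F/Y/W/H) — the enrichment signature of the sterol face.
This graph-component reading of "structurally continuous" is one
defensible definition among several; the radius is a parameter.

The water-network selection is the three-way intersection: residues with
at least one surviving $\Delta$ edge, at a conserved panel position, and
water-adjacent. Keying between panel positions and structure residues
goes through the generic-number map (Ballesteros–Weinstein style
`helix.position` labels); residues without a label simply never match,
so loop residues are eligible only if the caller labels them.

## Geometry

Helix axes are fitted by singular value decomposition of the centred Cα
trace; for six or more residues the trace is first smoothed with a
4-residue running mean, which cancels most of the Cα spiral (the
residual wobble of an ideal helix drops from 2.3 Å to about 0.26 Å) and
brings axis errors well under a degree. Kink angles are the angle
between the flank axes on either side of a pivot, each flank at least 4
residues. The opening of a transmembrane helix between two states is
measured after superposing the active structure onto the inactive one
over an anchor selection (by convention the Cα of the helices that do
not move, TM1–TM4): the angle between the intracellular sub-segment axes
(pivot to tip) and the displacement of a tip Cα. The published numbers
for such openings never come with a measurement recipe, so every element
of this convention (anchor, pivot, tip atom) is an argument.

Side-chain χ1/χ2 use the standard per-residue torsion atom definitions
and the IUPAC sign convention in (−180°, 180°]; a missing atom flags the
angle `NA` rather than failing, because cryo-EM models routinely omit
side-chain atoms. Two-state classification of a distance series offers a
fixed threshold and a deterministic 1-D 2-means (initialised at the 10th
and 90th percentiles, lower-mean cluster labelled state 1); the
published two-state behaviour of the extracellular bottleneck is
presented visually without a numeric cutoff, hence both modes.

Occupancy grids count, per cubic voxel (default 1 Å), the fraction of
frames in which at least one selected atom centre falls inside. Voxels
are half-open boxes and the origin is snapped down to a spacing
multiple, so grids over different regions align. The mask threshold is
greater-or-equal: at the 20% threshold a site visited in exactly 2 of 10
frames is retained. Atom centres, not spheres, are counted; whether the
original volumetric-map tooling counted spheres is not documented, and
centres keep the semantics exact and testable.

## Synthetic data: what it emulates, and what it does not

Every generator is deterministic given its seed and records its planted
truth. The defaults define the desk-scale study conditions used by the
tests and the acceptance script:

- `gen_msa()`: 50 sequences, designed columns (single-residue,
  similarity-group-restricted, or uniform-random), 5% gap noise —
  emulating ortholog alignments of a few hundred sequences at reduced
  depth.
- `gen_panel()`: 11 receptors with per-position patterns whose entropies
  hit the anchor values (0, 0.44, two-deviants, similar-only).
- `gen_helix()` / `gen_bundle()`: textbook α-helix geometry (1.5 Å rise,
  100° twist, 2.3 Å Cα radius), 7 helices of 24 residues on an 11 Å
  ring. The ring radius is calibrated so that helices pack close enough
  to carry inter-helix heavy-atom contacts (at looser packing the
  contact-change network of a planted swing would be empty). Waters sit
  3 Å off designated CB atoms, sterol-like ligand atoms 4 Å off the
  planted aromatic patch, both on outward-facing helix stripes
  (residues k, k+4, k+7, k+11, k+14 share one face) so the planted
  adjacency sets are unambiguous.
- `gen_state_pair()`: the active state swings the intracellular segment
  of helix 6 rigidly about a pivot placed so the tip Cα moves by exactly
  the requested displacement (lever arm
  $L = \mathrm{shift} / (2\sin(\mathrm{swing}/2))$, feasible for
  $L \in [13.5, 27]$ Å at 24 residues), and flips a planted tryptophan
  between two χ1/χ2 rotamers. Water-base residues are chosen by a
  geometric criterion — helix-6 residues whose CB lies within contact
  range of a neighbouring helix and well below the pivot — so the swing
  is guaranteed to rewire them.
- `gen_two_state_frames()`: distances alternate between two states
  (means 4/9 Å, SD 0.3 Å, mean dwell 25 frames), rotamers follow the
  state sequence with von Mises spread, and waters occupy sites in an
  exact recorded fraction of frames.

None of this is physically minimised: there are no hydrogens, no
realistic side chains beyond the planted tryptophan, no membrane and no
forces. Passing tests therefore demonstrate that the *measurements* are
correct and the *logic* of the compositions recovers planted ground
truth — not that the defaults are tuned for any particular real
receptor. Running the pipeline on deposited structures additionally
requires sensible burial and contact parameters for a real protein core,
and real data bring problems the generators deliberately omit: altloc
ambiguity beyond simple occupancy ties, missing side chains, and
alignment uncertainty upstream of the panel.

## Numerical choices and degenerate inputs

Fraction and entropy comparisons use a $10^{-9}$ tolerance;
greater-or-equal semantics everywhere a published rule says "equal to or
greater". Modal-symbol ties break alphabetically (determinism over
biology; no published tie rule exists). Empty alignments, all-gap
columns, constant series under 2-means, structures without Cα, absent
ligands and zero-water structures all return defined results or named
errors — never silent empties. Problem sizes in the tests (50-sequence
alignments, 24-residue helices, 200-frame series, 20-seed sweeps) keep
the whole suite in the low minutes on one core while leaving every
recovery margin wide.

## Known limitations

- Surface detection by Cα coordination is a proxy; it has no absolute
  meaning across structures of very different size.
- The entropy is computed over the 11 modal residues with equal weight;
  alternative weightings (e.g. by ortholog depth) are not implemented.
- Binary trajectory formats are not read; frame series enter as
  multi-model PDB behind the same `frame_series` contract.
- The contact-score constants follow the published contact-score
  algorithm's description; laboratories using recalibrated ramps should
  set them via `rrcs_params()`.
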