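# consnet

Evolutionary–structural analysis of G-protein-coupled receptor
activation, centred on the class F family (the ten Frizzleds and
Smoothened). The package is for structural bioinformaticians who have a
receptor structure pair (inactive / active), ortholog alignments for the
paralog family, and — optionally — trajectory frames, and who want to
answer two questions the class F literature poses:

1. **Water network**: which class-wide conserved residues both rewire
   their packing upon G-protein coupling and line the internal water
   pocket?
2. **Sterol site**: do conserved, structurally continuous surface
   residues cluster at the cholesterol-binding face?

## The statistics at the core

*Ortholog conservation* of an alignment column with non-gap depth
`n` and modal residue `m`:

    f = ( c(m) + Σ_{b: score(m,b) > t} c(b) ) / n ,   conserved ⇔ f ≥ 0.90

with BLOSUM80 similarity (strict `> t`, default `t = 1`); a gap-majority
column scores 0. *Cross-paralog divergence* at a position is the Shannon
entropy in bits of the 11 per-receptor modal residues
(`H = −Σ p log2 p`): 0 when all receptors agree, 0.44 when exactly one
of 11 deviates. *Contact rewiring* uses the residue–residue contact
score (RRCS), a per-residue-pair sum of a linear heavy-atom distance
ramp (1 below 3.23 Å, 0 above 4.63 Å, main-chain atoms excluded for
sequence-near pairs), and its activation difference
`ΔRRCS = RRCS_active − RRCS_inactive`. Geometry utilities measure helix
kink angles, transmembrane-helix opening between states (angle and tip
displacement after anchored superposition), χ1/χ2 rotamer series,
two-state distance classification and water-occupancy voxel grids with
a ≥ 20 %-style threshold mask.

Every input class has a deterministic seeded generator with planted
ground truth (`gen_msa`, `gen_panel`, `gen_helix`, `gen_bundle`,
`gen_state_pair`, `gen_two_state_frames`), so the full pipeline is
testable offline.

## Worked example

A synthetic inactive/active pair with a planted 15° helix-6 swing, a
4 Å tip shift, planted waters and a conservation panel:

```r
library(consnet)

sp <- gen_state_pair(swing_angle = 15, tip_shift = 4, seed = 42)
op <- tm_opening(sp$inactive, sp$active, "A", sp$truth$tm_range,
                 sp$truth$pivot_resno, sp$truth$anchor_resnos,
                 sp$truth$tip_resno)
sprintf("helix-6 opening: %.1f deg, tip displacement %.2f A",
        op$angle_deg, op$displacement)
#> helix-6 opening: 15.0 deg, tip displacement 4.00 A

run_water_network_analysis(run_config(
  inactive_structure = sp$inactive, active_structure = sp$active,
  panel = sp$panel, generic_map = sp$generic_map, min_abs_delta = 0.1))
#> water-network analysis: 3 residues at the water-pocket base
#>   A|603|  [6.3]
#>   A|604|  [6.4]
#>   A|608|  [6.8]
```

The three reported residues are exactly the generator's planted
water-base set: they are the only residues that are class-wide conserved
(zero entropy across the 11-receptor panel), adjacent to a water oxygen
within 3.5 Å, and carry at least one contact-change edge with
`|ΔRRCS| ≥ 0.1`. The bracketed labels are their generic
(helix.position) numbers.

The sterol-site analysis on the synthetic bundle with a planted
5-residue aromatic patch and a sterol-like ligand:

```r
b <- gen_bundle(seed = 42)
run_cholesterol_site_analysis(run_config(
  structure = b$structure, panel = b$panel, generic_map = b$generic_map,
  matrix = toy_substitution_matrix()))
#> sterol-site analysis: 2 conserved surface patch(es)
#>   top patch: 5 residues, 5 aromatic
#>   ligand contacts: A|306|, A|310|, A|313|, A|317|, A|320|
#>   overlap with top patch: 5 residues
```

The top-ranked patch (5 residues, all aromatic) coincides completely
with the ligand-contact set — the planted analogue of a conserved
cholesterol-binding surface. Desk-scale anchors are available directly:
`divergence_entropy(c(rep("W", 10), "L"))` rounds to 0.44 bits, and
`classwide_fraction(c(rep(TRUE, 8), rep(FALSE, 3)))` is 72.7 %.

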