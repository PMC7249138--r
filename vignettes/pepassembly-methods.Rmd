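---
title: "Methods: charge models, synthetic conformers and beta-turn counting in pepassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: charge models, synthetic conformers and beta-turn counting in pepassembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepassembly)
```

pepassembly is a desk-scale analysis chain for short amphiphilic
peptides whose self-assembly responds to pH, built around the uncapped
heptapeptide A6K (H2N--AAAAAAK--OH). Leaving both termini unblocked
gives the molecule three ionizable groups — the N-terminal amine, the
Lys-7 side-chain amine and the C-terminal carboxyl — so its charge
distribution, and with it the balance of electrostatic attraction and
repulsion between chains, is tunable by solution pH. This vignette
documents the models the package implements, the choices behind their
defaults, and what the synthetic data generator does and does not
emulate.

## The protonation model

Each ionizable site is treated as an independent two-state group whose
fractional charge at a given pH follows the Henderson--Hasselbalch
relation,

$$ q_\mathrm{base}(\mathrm{pH}) = \frac{+1}{1 + 10^{\,\mathrm{pH} - pK_a}},
\qquad
q_\mathrm{acid}(\mathrm{pH}) = \frac{-1}{1 + 10^{\,pK_a - \mathrm{pH}}}, $$

and the peptide net charge is the sum over sites. Both forms are
strictly decreasing in pH, so the net charge is a monotone function
with at most one root: the isoelectric point, which
`isoelectric_point()` finds by bisection on pH $\in [0, 14]$ until the
absolute net charge drops below `tol` (default $10^{-4}$ e), reported
to one decimal by default.

The default pKa table is the Bjellqvist set used by the ExPAsy Compute
pI/Mw tool: C-terminal carboxyl 3.55, N-terminal amine of Ala 7.59, Lys
side chain 10.00, with the full residue-specific table bundled.
Site-resolved pKa predictors assign structure-dependent values that are
not tabulated here; the Bjellqvist set is the established
sequence-based reference and reproduces the standard pI of 8.8 for
uncapped A6K, so it is the default, and `read_pka_set()` accepts
per-site overrides for users with structure-specific estimates.

```{r}
a6k <- peptide("AAAAAAK")
net_charge(a6k, c(2, 7, 8, 11))
isoelectric_point(a6k)
```

The rounded column uses nearest-integer rounding with ties away from
zero, matching the convention of quoting integer charge states (2e, 1e,
0, $-1$e across this pH series). `charge_state()` additionally labels
each site from the magnitude of its fractional charge — `charged`
($\ge 0.9$), `mostly_charged` ($[0.7, 0.9)$), `mixed` ($(0.3, 0.7)$),
`mostly_neutral` ($(0.1, 0.3]$), `neutral` ($\le 0.1$). The four cut
points are conventional renderings of the verbal categories
("substantially uncharged", "almost uncharged") and are arguments, not
constants. Molecular mass sums the standard average (or monoisotopic)
residue masses plus one water for free termini; uncapped A6K gives
572.66, i.e. the usual quoted 573 g/mol.

## Coordinate model and file formats

Coordinates live in a plain per-chain atom table in Angstrom;
`read_pdb()`/`write_pdb()` handle the multi-model, multi-chain
fixed-width PDB dialect (MODEL/ENDMDL per frame, TER per chain, CRYST1
for the box) and `read_gro()`/`write_gro()` the single-configuration
GRO dialect with nm fields converted at the boundary. Binary
trajectory formats are out of scope; trajectories are exchanged as
multi-model PDB. Residues missing any of N, CA, C, O are flagged
unusable and excluded from dihedral-based analysis with a warning
rather than an error, since a single damaged residue should not
invalidate a frame. GRO carries no chain identifiers, so chains are
recovered where residue numbering restarts; files with continuous
numbering across chains read back as one merged chain, a documented
limitation of the dialect rather than of the reader.

## The synthetic conformer generator

The study conditions this package targets are simulation snapshots of
80 peptides in a 512 nm$^3$ cubic box; the generator replaces such
trajectories with conformers whose secondary structure and spatial
organisation are known by construction, which is what makes exact
recovery tests possible.

Chains are built by sequential internal-to-Cartesian (NeRF-style)
placement from bond lengths (N--CA 1.458, CA--C 1.525, C--N 1.329, C=O
1.231, N--H 1.01 A), standard backbone angles, and per-residue (phi,
psi, omega) torsions with omega fixed trans (180 degrees). The
construction is the exact inverse of the dihedral measurement: round
trips agree to better than $10^{-6}$ degrees, and an independent PDB
reader's torsions agree with the intended values, anchoring the sign
convention. C-beta is placed with the C--N--CA--CB torsion at $-120$
degrees, the value measured on the ideal L-alanine template, so every
generated residue is L; the chirality test asserts the improper
N--CA--C--CB torsion is negative ($\approx -121$ degrees). Side chains
beyond C-beta are reduced to a single Lys marker: NZ on the CA--CB
direction at 4.9 A from CA, sufficient to place the side-chain charge
and measure radial amphiphilicity without a rotamer library. This is a
deliberate simplification: packing densities and contact surfaces of
generated systems are not those of fully side-chained peptides.

Motif templates (`motif_library()`) provide ideal alpha-helix
($-57, -47$), extended ($-139, 135$), polyproline-II ($-75, 145$) and
the two classic beta-turn types (type I inner residues
$(-60,-30)/(-90,0)$; type II $(-60,120)/(80,0)$), planted at a chosen
window with extended flanks. Random coils draw each residue from three
Ramachandran basins (beta, alpha-R, alpha-L) with configurable weights,
default $0.5/0.4/0.1$ — a generic disordered-ensemble composition
biased toward the broad beta/PPII region, as expected for an
alanine-rich peptide. All generators are pure functions of their
inputs and an explicit seed.

`make_system()` assembles frames of many chains. Dispersed placement
applies uniform random rigid-body moves with rejection until every
inter-chain heavy-atom minimum distance reaches `min_dist_A` (default
4 A); the constraint therefore holds exactly, not statistically.
Micellar placement orients each chain's N-to-C axis radially outward
from a central z-axis with the Ala end at a small inner radius, so the
Lys markers necessarily sit farther from the axis than the Ala
C-betas. It emulates the amphiphilic ordering of a micellar aggregate
— hydrophobic core, lysine shell — not its energetics, packing density
or size distribution. Consequently, passing tests demonstrate that the
analysis recovers planted composition and ordering, not that real A6K
assemblies have these properties.

## Secondary structure and beta-turn counting

Hydrogen-bond-energetics assigners such as STRIDE or DSSP are not
re-implemented; `classify_ss()` is a transparent dihedral-region
stand-in with the same label set (helix, sheet, turn, coil). Helix
requires at least four consecutive residues with phi $\in [-100, -30]$
and psi $\in [-80, -5]$; sheet at least two consecutive residues with
phi $\in [-180, -60)$ and psi $\in [60, 180]$ or $(-180, -150]$.
The phi boundary of the sheet region is half-open: the canonical
type-II turn template places its $i{+}1$ residue exactly at
phi $= -60$, and a closed boundary would absorb it into a sheet run.
Region tests operate on dihedrals rounded to $10^{-6}$ degrees so that
rigid-body motion, which perturbs measured torsions at the $10^{-12}$
level, can never flip a boundary classification. Residues in any
four-residue window whose terminal C-alpha atoms lie within 7 A that
are neither helix nor sheet are labelled turn; chain termini without
defined dihedrals default to coil but may join turn windows. Because
the classifier differs from STRIDE's energetic criteria, turn
percentages are comparable in spirit, not numerically, to
STRIDE-derived counts.

Beta-turns are detected per window $i..i{+}3$ by the two classic
criteria: (A) a backbone hydrogen bond from the C=O of residue $i$ to
the N--H of residue $i{+}3$, and (B) a C-alpha($i$)--C-alpha($i{+}3$)
distance strictly below 7.0 A. The literature treats the two as
alternative diagnostics without fixing a combination rule, so the
default accepts either, configurable to require both; each record
stores which criterion fired and the measured geometry. The
hydrogen-bond criterion is geometric — O···N $\le$ 3.5 A and
N--H···O angle $\ge 120$ degrees, a common definition — since no
energetic threshold is implied by the turn definition. Helix exclusion
is on by default: an ideal helix satisfies the distance criterion at
every window, but beta-turns classically require non-helical inner
residues. Proline cannot donate (no amide hydrogen); missing amide
hydrogens are reconstructed in the C(prev)--N--CA plane.

`turn_content()` reports two ensemble percentages per frame with
deliberately different definitions: `turn_percent` is the fraction of
residues the classifier labels turn, and `beta_turn_percent` the
fraction of residues inside at least one qualifying window (or, with
`denominator = "windows"`, the fraction of qualifying windows).
Neither bounds the other. Published turn statistics rarely state their
denominator; exposing both counting modes avoids guessing. On planted
ensembles the residue-fraction recovery is exact — ten type-II chains
of seven residues give $4/7 = 57.1$% in every frame with zero variance
— which is the property the acceptance suite checks in place of
re-running solvated molecular dynamics.

## Aggregate analysis

Chains are clustered by single linkage on the contact graph with a
4.5 A heavy-atom minimum-distance cutoff, a typical contact
definition. Radius of gyration is mass-weighted over the reduced atom
set. The amphiphilic profile projects Ala C-beta and Lys NZ markers
onto the plane perpendicular to the aggregate axis — the first
principal component of all C-alpha positions, its sign fixed
lexicographically for reproducibility — and reports
`mean_radial(Lys NZ) - mean_radial(Ala CB)` in Angstrom; positive
values mean lysines outside, the micellar signature. Fewer than three
chains give no meaningful principal axis, so a user-supplied axis is
required there.

The electrostatic score sums screened Coulomb terms
$q_1 q_2 / (4\pi\varepsilon_0\,\varepsilon_r\,r)$ over cross-chain
site pairs, with fractional charges from the protonation model at the
requested pH placed on representative atoms (N-terminal N, Lys NZ,
carboxylate-oxygen midpoint), relative dielectric 78.5 (bulk water)
and a 1.4 nm cutoff echoing common simulation truncation radii. It is
a qualitative interaction score — positive means net repulsion, as for
the all-cationic peptide at pH 2 — not a free energy: no solvent
screening beyond the uniform dielectric, no Ewald treatment, no
conformational response.

## Pipeline and problem sizes

`run_pipeline()` drives charge model, generation or loading, turn
counting and aggregate analysis from one YAML configuration with a
mandatory generator seed; every threshold in force is echoed into the
report, and identical configurations produce identical numeric
content. Two fixture configurations ship in `inst/extdata`: a
12-chain micellar system with planted type-II turns and an 80-chain
dispersed coil system in the 8 nm box.

The test suite exercises the oracle-agreement property on 100 random
chains, planted-fraction recovery on 10-chain ensembles over several
frames, amphiphilic ordering over 20 dispersed seeds, and one 80-chain
packing run — sizes chosen so the full suite completes in about a
minute while still covering the study's system scale once.

## Known limitations

* No molecular dynamics, energetics or kinetics: generated ensembles
  have prescribed, not emergent, structure; nothing here predicts
  whether a peptide actually assembles.
* The reduced side-chain model underestimates excluded volume; contact
  cutoffs tuned for full atomistic models may behave differently here.
* The dihedral-region classifier is not STRIDE; absolute turn
  percentages from the two are not interchangeable.
* Henderson--Hasselbalch sites are independent; site-site coupling
  (shifted microscopic pKa in assembled states) is not modelled.
* Cis peptide bonds, D-residues, insertion codes and binary trajectory
  formats are unsupported.
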