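---
title: "Methods: dual-target virtual screening with interaction fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-target virtual screening with interaction fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualscreen)
```

## Scope and model

`dualscreen` implements a point-based virtual-screening protocol for ligand
libraries docked against two (or more) protein targets — in the motivating
application, the membrane estrogen receptor GPER and the anti-apoptotic
protein Bcl-2, whose simultaneous blockade is a strategy against
triple-negative breast cancer. Docking itself is out of scope: poses and
signed binding energies arrive as inputs (SDF/PDB and CSV). The package owns
everything downstream: typed interaction detection, interacting-residue
fingerprints, binding-mode similarity to control ligands, drug-likeness /
toxicity / metabolism point scoring, the summative composite, and
deterministic ranking. Upstream of the screen it also owns the
compound-design arithmetic: enumeration of amide condensation products of a
carboxylic-acid scaffold with N–H nucleophiles, molecular formulas, and
monoisotopic masses for HRMS cross-checks.

## Interaction detection

All detectors work on geometry alone, in the receptor frame, with exhaustive
all-pairs enumeration — pockets are a few hundred atoms, so exactness is
cheap and there is no neighbor-list approximation to validate. Every cutoff
is a named entry of `geometry_params()` and every boundary is inclusive.

| interaction | criterion | default |
|---|---|---|
| hydrogen bond | donor–acceptor heavy-atom distance; D–H···A angle when an explicit H is present | ≤ 3.5 Å; ≥ 120° |
| π–π stacked | ring centroid distance and interplanar angle | ≤ 5.5 Å; ≤ 30° |
| π–π T-shaped | same distance; interplanar angle window | 60–90° |
| π-alkyl / π-cation / π-anion | ring centroid to atom or charged-group centroid | ≤ 5.0 Å |
| π-sulfur | ring centroid to S | ≤ 5.5 Å |
| alkyl, halogen | atom–atom | ≤ 4.5 Å |
| generic contact | any heavy-atom pair | ≤ 4.0 Å |

Rationale for the defaults: the hydrogen-bond window brackets the short
polar contacts (1.7–3.1 Å, H···A or heavy–heavy depending on protonation)
typical of docked sulfonamides; the 5.0 Å ring-to-atom cutoff reflects the
usual "below 5 Å" convention for π-mediated hydrophobic contacts; the
remaining values are the ranges interaction-diagram software conventionally
draws. They are declared package defaults, not fitted quantities, and every
one can be overridden per run. Interplanar angles between 30° and 60° are
deliberately classified as neither stacked nor T-shaped.

Perception rules:

* **Receptor side** is template-driven: aromatic rings from Phe/Tyr/His/Trp
  side-chain atom names, carboxylate anions from Asp/Glu (OD/OE midpoints),
  cations from Lys NZ and the Arg guanidinium centroid, sulfur from Met/Cys.
  Histidine is aromatic and neutral by default; `his_cationic = TRUE` adds
  it to the cation list. Residue identity is (chain, number, name) with
  insertion codes appended, preserved verbatim from the source PDB so that
  labels like Phe206 or Arg129 match the literature.
* **Ligand side** is inferred from the pose alone: bonds from covalent radii
  (Cordero values × 1.25), aromatic rings as planar 5/6-cycles (≤ 0.15 Å
  deviation from the least-squares plane), donors/acceptors as N/O,
  "alkyl" atoms as carbons bonded only to C/H **and not ring members**
  (aliphatic in the chemical sense — without the ring-membership condition
  every stacked ring pair would double-report as π-alkyl), plus halogens.
  Ligand formal charges are not guessed from geometry, so charged-group
  detection is receptor-sided; π-anion/π-cation records always pair a
  ligand ring with a receptor group.
* **Hydrogens**: when explicit hydrogens are present the hydrogen-bond
  detector applies the angle criterion; otherwise it falls back to
  distance-only, which is the right behavior for docking outputs stripped
  of protons. Distances are always reported heavy-atom to heavy-atom.

The fingerprint of a pose is the union of all typed records plus a generic
heavy-atom contact floor; the residue set is deduplicated, order-free, and
is the object compared across ligands.

## Scoring

* `similarity_bm()` — the binding-mode similarity of a tested ligand is the
  percentage of the **control** ligand's interacting residues it shares:
  100·|test ∩ control|/|control|. This rule-of-three reading (control ↔ 100,
  shared ↔ X) is the package's fixed interpretation; the literal count
  ratio 100·|test|/|control| rewards promiscuous binders and can exceed
  100%, so it is available only behind `method = "count_ratio"` for
  comparison. An empty control set is an error, not a zero.
* `lipinski_points()` — 10 points per parameter inside MW 200–500 g/mol,
  log P 2–5, HBA 5–10, HBD 2–5, boundaries closed. The acceptor/donor
  windows penalize *low* counts too; that departs from the classical
  one-sided rule-of-five limits and is kept as printed in the protocol this
  package implements.
* `tox_points()` — per endpoint (mutagenicity, teratogenicity,
  tumorigenicity, irritability): high 0, medium 10, low 20; codomain
  0–80 in steps of 10.
* `metabolism_penalty()` — high −20, medium −15, low −10. Annotations are
  expected pre-restricted to the variable moiety introduced by the amide
  coupling; the package consumes the categorical call and does not predict
  metabolism itself.
* `composite_score()` — Σ over targets of (|BE| + %similarityBM) plus the
  three ligand-level terms counted once. The sum deliberately mixes units
  (kcal/mol magnitudes ≈ 5–15 against percents and points): that is the
  protocol's definition and the default. An opt-in normalization
  (`normalize = TRUE`) rescales |BE| to a 0–100 range for sensitivity
  analyses but never changes the default output. How per-target blocks
  combine across targets is not specified by the protocol itself; the
  package's decision is an unweighted sum over targets with ligand-level
  terms counted once.
* `rank_library()` — descending composite, ties broken by ligand id in C
  collation; re-running on permuted input reproduces the identical order.
  Missing annotations never drop a ligand: the affected component takes its
  worst value (similarity 0, |BE| 0, 0 points, −20 penalty) and the row is
  flagged in `missing_data`, keeping the ranking total.

## Chemistry conventions

Molecular formulas render in Hill order. Monoisotopic masses sum
most-abundant-isotope masses (AME2020/IUPAC-CIAAW values tabulated to
≥ 6 decimals in `R/elements.R`; 4-decimal agreement with HRMS "calculated"
values requires at least this precision). Masses and formulas always refer
to the **neutral** molecule; [M+H]⁺/[M−H]⁻ arithmetic is an explicit
`adduct` argument, never implicit. Average molecular weights use IUPAC 2021
standard atomic weights. Log P is the Wildman–Crippen atomic-contribution
estimate and TPSA the Ertl fragment scheme, both computed through Open
Babel (ChemmineOB); these are fixed, published schemes — parity with any
particular web server's numbers is not a goal, and the range-based point
scoring absorbs scheme-level differences. Donor/acceptor counts are defined
structurally (N/O bearing H; all N/O), not by the log P scheme's typing.

Amide enumeration condenses each carboxylic-acid site (C(=O)–OH) with each
reactive N–H site (primary amine or sulfonamide nitrogen), eliminating
water and forming the C(=O)–N bond; one product per site pair, ordered by
site index. Formula conservation (product = acid + nucleophile − H₂O) holds
exactly by construction and is asserted property-style in the tests. On the
reference scaffold this reproduces the tosyl product C27H23BrN2O5S at
566.0511 Da — note that the neutral formula carries 23 hydrogens; a
22-hydrogen rendering of the same species sometimes seen in print is
consistent only with the deprotonated ion and not with the 566.0511
calculated value, so the package documents and uses the neutral count.
Implicit hydrogens on parsed connection tables are completed from standard
valence states (smallest allowed valence ≥ bond-order sum, charge-adjusted),
the usual SMILES/SDF convention.

## Synthetic data: what it shows and what it does not

`make_pocket_fixture()` builds idealized pockets: ligand feature groups
(hexagonal rings, lone polar atoms, methyl-like carbons, halogens) on a
sphere around the origin, with minimal residue templates placed radially at
planted distances. Planted geometries sit strictly inside thresholds
(≥ 0.2 Å / ≥ 10° margins), decoys strictly outside every applicable cutoff
(including the generic-contact floor) by ≥ 0.5 Å, and slot directions are
spread (Fibonacci sphere) with a verified cross-slot clearance so no
accidental contacts arise; the generator enlarges the pocket radius until
that clearance holds. This guarantees recall 1.0 / false positives 0 by
construction *for the detectors' own geometric definitions* — it validates
the implementation, not the chemistry: nothing about the fixtures tests
whether the cutoffs are biophysically optimal, whether real pockets are
this clean (they are not: waters, metals, strained geometry and borderline
contacts all occur), or how the detectors behave on crystallographic noise.
Similarly `make_ligand_library()` draws properties per parameter
independently and uniformly within/outside the scoring windows — real
libraries have correlated descriptors — and its expected-score table is
summed by independent literal arithmetic inside the generator, never by the
scoring functions, so pipeline-vs-oracle agreement is a genuine dual-route
check. Randomness everywhere is R's Mersenne-Twister under a caller-given
integer seed; fixtures are byte-identical across runs and platforms.

Test problem sizes (the package's own choices, set to exercise every code
path densely): 100 seeded fixtures × 20 planted + 20 decoy geometries for
the detector suite, a 500-ligand library for the scoring oracle, 20 random
rigid motions for invariance, exhaustive 3⁴ × 3 enumeration of the
annotation codomains.

## Numerical and degenerate-input choices

Cutoff comparisons are plain `<=` on IEEE doubles; planted fixtures keep
0.2 Å margins so floating-point noise cannot flip a classification, and the
boundary-inclusive rule is pinned by an exact-geometry test at 3.5 Å.
Ring planes come from an SVD fit; the interplanar angle is folded into
[0°, 90°]. Rigid-motion invariance holds to ~1e-13 Å because only distances
and angles are ever compared. Degenerate inputs fail loudly: empty formulas
are valid (mass 0) but empty strings are parse errors; a pose needs ≥ 1
heavy atom; duplicate (ligand, target) energy keys, duplicate ligand ids,
unknown risk levels and a zero-target configuration are all errors; an
empty control fingerprint aborts the pipeline naming the target. Pipeline
CSV output is rounded to 4 decimals, which also makes re-runs
byte-identical.

## Limitations

Water-mediated bridges, metal coordination, salt bridges among receptor
residues and trajectory-resolved (per-frame) analyses are out of scope.
Ligand protonation states are not predicted. Exact numeric parity with any
specific docking viewer, property server or toxicity predictor is a
non-goal — those tools' categorical outputs are consumed as inputs. The
composite score is a screening heuristic: its unit mixing is inherited from
the protocol it implements and it has no statistical calibration; it
ranks, it does not predict binding free energies.
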