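---
title: "Classifying biological interfaces versus crystal-packing contacts from B factors"
author: "CrystalContact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying biological interfaces versus crystal-packing contacts from B factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CrystalContact)
```

## The problem and the model

An X-ray crystal structure records a whole lattice of protein copies, so
the contacts it contains are a mixture of physiological interfaces and
packing artifacts that would not exist in solution. The classical
discriminator, buried surface area (ΔASA), works when biological
interfaces are systematically larger than packing contacts, and fails when
the two size distributions overlap.

This package classifies contacts from atomic *flexibility* instead.
Binding interfaces are load-bearing: their atoms are conformationally
ordered, which shows up as low crystallographic B factors relative to the
rest of the protein surface. Packing contacts are adventitious and show no
such rigidity signal. The pipeline therefore (1) finds the atoms that
genuinely form the interface, (2) scores their B factors on a scale
comparable between structures, and (3) classifies the interface with a
single learned threshold.

### B-factor normalization

B-factor distributions differ wildly between depositions (refinement
protocol, resolution, overall disorder), so raw values are never compared
across structures. Within each binding unit the package computes

$$ B^{norm}_i = \frac{B_i - \bar B}{\delta_B} \cdot \frac{1}{1.645},
   \qquad \ddot B^{norm}_i = \min[\max(B^{norm}_i, -1), 1] $$

with $\bar B$, $\delta_B$ the mean and population standard deviation over
the unit's (standard-residue, heavy) atoms. Division by 1.645 maps the
90% normal interval onto $[-1, 1]$; the clamp sends the two 5% tails to
$\pm 1$ so single grossly disordered atoms cannot dominate a sum. The
result is invariant under any affine rescaling of the deposited B column,
which is exactly the deposition artifact the normalization must remove.
Normalization is always per contact partner: the two sides of an interface
never share statistics.

Two conventions had to be fixed where more than one is defensible:

* **Standard deviation**: population form (divide by $N$). Over hundreds
  of atoms the difference from the sample form is far below any decision
  threshold, but it is pinned down for exact reproducibility.
* **Atoms entering $\bar B, \delta_B$**: the same atom set used for
  contact detection (hydrogens and waters excluded, hetero atoms
  excluded), so an atom is always normalized against the population it is
  compared with.

### Interfacial atoms: β contacts and the local-contact rule

Distance cutoffs alone over-count contacts: two atoms can be within range
yet have a third atom between them. A cross-unit pair (i, j) is counted
as a **β contact** only when

1. $d(i,j) < T_d + r^{vdW}_i + r^{vdW}_j$,
2. i and j share a Voronoi facet in the Voronoi diagram of the whole
   complex (they are direct geometric neighbours), and
3. the β-skeleton *forbidden region* is empty: no third atom k subtends
   an angle $\angle ikj \ge \angle\beta$. At the default
   $\angle\beta = 90°$ the forbidden region is the sphere with ij as
   diameter — the Gabriel-graph criterion, which also gives the test an
   exact combinatorial oracle.

An atom with at least one β contact is kept as interfacial only when its
*local contacts* — its own β contacts plus those of atoms within two
covalent-bond steps — exceed 2. Isolated grazing contacts are thereby
discarded. Local contacts are counted over β contacts (not over the looser
distance contacts): the contact currency is the same throughout the rule.

**Geometry implementation.** No Delaunay/Voronoi engine is assumed.
Condition (2) is decided exactly per candidate pair by clipping the
bisector plane of (i, j) with one halfplane per other atom
(Sutherland–Hodgman); the remaining polygon *is* the Voronoi facet, so its
area is available directly and facets below $10^{-12}$ Å² (cospherical
near-degeneracies) are rejected by construction rather than by perturbing
the input. The bounding square for the clip is deliberately enormous
(half-width $10^7$ Å + structure extent): Voronoi facets of hull pairs can
sit arbitrarily far from the atoms (sliver-tetrahedron circumcentres), and
the box must not truncate them. Test suites verify exact agreement with
brute-force Gabriel graphs and with independent Delaunay triangulations on
random clouds.

**Parameters.** $T_d = 2.8$ Å by default — roughly a water diameter of
slack over van der Waals contact, the conventional choice for
solvent-excluding atomic contacts — and $\angle\beta = 90°$. Both are
exposed (`contactParams()`) because published β-contact applications
inherit them from earlier work without fixing them uniquely; results that
depend on their exact values should be treated as parameter-sensitive.
Van der Waals radii use the standard crystallographic set (C 1.70, N 1.55,
O 1.52, S 1.80, P 1.80 Å; unknown elements 1.70 Å), overridable per call.

### Interface scores

With `min_r` the smaller of the two units' mean residues-per-chain:

| score | definition | polarity |
|---|---|---|
| `sigmaB` | $\sum \ddot B^{norm}$ over interfacial atoms (both units) | negative ⇒ biological |
| `avgSigmaB` | `sigmaB` / log(min_r + 1) | negative ⇒ biological |
| `noB`, `avgNoB` | count with $\ddot B^{norm} < 0$; same normalizer | large ⇒ biological |
| `product` | `avgNoB` · `avgSigmaB` / 100 | negative, large magnitude ⇒ biological |
| `deltaASA` | $(ASA_1 + ASA_2 - ASA_C)/2$ | large ⇒ biological (baseline) |

The logarithmic size normalizer damps the dependence of interface size on
chain length — essential for protein–peptide complexes, whose interfaces
are small in absolute terms but large relative to the peptide. The
logarithm base is not uniquely determined by the score's definition;
natural log is the default and the base is an explicit argument
(`logBase`), since the choice rescales `avgSigmaB` by a constant factor
(ln 10 ≈ 2.30 between the two common bases) without affecting any
classification built on the same base. `noB` counts strictly negative
normalized B; atoms exactly at 0 do not count. A contact with zero
interfacial atoms yields all-zero scores flagged `emptyInterface` — tiny
packing contacts are data, not errors.

### Solvent-accessible surface area

The ΔASA baseline needs a SASA engine; a Shrake–Rupley sampler is built
in. Each atom's sphere is inflated by the probe radius (1.4 Å, water) and
sampled with a deterministic golden-spiral lattice (960 points by
default); points inside any neighbour's inflated sphere are inaccessible.
Accuracy against analytic closed forms: an isolated sphere is exact to
≪ 1%, two-sphere overlaps agree with the spherical-cap formula to ~0.3%,
and refining 960 → 3840 points moves ΔASA on synthetic interfaces by
< 1%. Points that fall exactly on a neighbour's surface (coincident
spheres) are resolved by atom index so shared surface is counted once.
Published buried-area values are engine-dependent at the few-percent
level; comparisons to external ΔASA numbers should allow ±3%.

### Threshold learning and evaluation

All classification is single-feature thresholding. Candidate splits are
midpoints of consecutive distinct scores (a finite and complete set: every
achievable partition is represented). Each split is scored by the better
of its two decision directions' MCC; the top 10% of splits by rank (at
least one; ties at the boundary included) are *averaged* into the
threshold. Averaging trades a sliver of training MCC for stability of the
transferred threshold. The direction is learned as the majority among the
kept splits rather than hard-coded, so the same code path serves
negative-polarity B features and the positive-polarity area baseline.
"Top 10%" is read as the top decile of candidate splits; the alternative
reading (all splits within 10% of the best MCC) is a one-line change and
was not taken because it degenerates to the argmax on sharply peaked MCC
profiles.

For positives-only training data (affinity-annotated complex collections
have no packing negatives) the threshold is an empirical quantile
(linear-interpolation type 7) of the positive scores, with the direction
supplied from the feature's known polarity; the cross-dataset driver
places the quantile on the packing-facing tail, so `q = 0.25` always
means "sacrifice 25% of training positives", whichever the polarity. The
25% default is deliberately conservative against label noise in
automatically compiled positive sets.

Metrics are the standard confusion-matrix set (precision, recall,
specificity, accuracy, MCC) with biological as the positive class; any
zero denominator (MCC included) yields 0. Scores exactly at the threshold
fall on the packing side.

## The synthetic generator: what it emulates, what it does not

`syntheticComplex()` builds two chain-partitioned units of 4-atom
residues (N, CA, C, O) threaded serpentine over a jittered 3.5 Å lattice,
so peptide C–N bonds, residue partitioning, and a realistic
bonded/non-bonded distance separation all arise and the covalent-bond
inference, residue counting and PDB round-trip are exercised on every
generated complex (structures pass through the PDB writer and reader).
Geometries: `slab-contact` (flat interface, surfaces ~3.4 Å apart),
`sphere-pair` (compact blocks), `separated` (100 Å gap — no interface by
construction). B factors are drawn in raw Å² scale with unit-specific
mean (25–40) and standard deviation (8–12), so normalization is always
non-trivial; models are `uniform` (no spatial signal — the packing-like
null), `burial-gradient` (B rises towards the surface), and
`interface-rigid` (uniform base, atoms within 4.5 Å of the partner
lowered by `interfaceRigidity` unit standard deviations — the
biological-like signal; the default effect size of 1.0 standard
deviation is the planted class separation used in the recovery studies).

What the generator does **not** emulate: real secondary structure,
side-chain packing, crystal-lattice symmetry, correlated B-factor noise
(TLS groups), resolution-dependent disorder, or the size diversity of
real interface datasets. Passing the end-to-end recovery test therefore
demonstrates that the pipeline detects a planted flexibility signal
through the full geometry and normalization stack — not that real PDB
interfaces carry a signal of that strength.

## Numerical choices and degenerate inputs

* Alternate locations: highest occupancy wins, ties towards altloc `A`.
* Hydrogens and waters are excluded everywhere (contacts, normalization,
  SASA); non-water hetero atoms are never interfacial candidates but do
  block Voronoi facets and forbidden regions by default
  (`includeHetBlockers`), since a ligand sitting between two protein
  atoms genuinely interrupts their contact.
* Fewer than 5 points or a coplanar point set cannot define a 3-D Voronoi
  diagram and raise a degeneracy error rather than a silent answer.
* A unit with identical B factors throughout normalizes to all zeros with
  a warning (δ_B = 0).
* Covalent bonds: distance ≤ covalent-radius sum + 0.4 Å, restricted to
  same-residue pairs and peptide C(r)–N(r+1) pairs; disulfides S–S ≤
  2.3 Å. Insertion-code ordering is approximated by sequence-number
  adjacency.
* Biological units come from REMARK 350 when present; otherwise the two
  chain groups must be given explicitly — the assembly is never guessed.

## Problem sizes in the shipped studies

The validation studies are sized for a single CPU: geometry-oracle
equivalence uses 50 random clouds of up to 60 points; the threshold
learner is checked exhaustively up to n = 400 scores; the end-to-end
recovery uses 100 synthetic complexes of 480 atoms each (50
interface-rigid vs 50 uniform, two-fold cross-validation, with the
permutation null averaged over 20 relabelings — a single shuffle at
n = 50 per fold has sampling noise of ±0.3 MCC, so the averaged null is
the meaningful zero check). Larger runs only tighten the same
comparisons.

## Known limitations

* The B-factor signal presumes well-refined X-ray structures; the entry
  filter (`filterComplexEntry()`) enforces X-ray, < 2.5 Å resolution, ≥ 3
  atoms/residue, > 5 residues per partner and < 20% non-standard-residue
  contacts for exactly that reason. Structures with uniform or re-set B
  columns defeat the method.
* A full benchmark against curated interface datasets requires
  downloading those datasets and is out of scope here; the shipped
  validation is property-based plus synthetic-recovery.  The worked
  single-entry example (PDB 1UBY, an annotation-error case where the
  flexible, large-ΔASA assembly is the wrong one) runs when that entry is
  available locally.
* Symmetry mates are built only from REMARK 350 operators, not from
  space-group symmetry; NMR/EM structures are out of scope.
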