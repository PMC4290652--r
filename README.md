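# CrystalContact

Protein crystal structures in the PDB contain two kinds of protein–protein
contact: true biological interfaces, and crystal-packing contacts that exist
only because of the crystallization lattice. Telling them apart is a
long-standing annotation problem; interface size (buried area) is the
classic discriminator but fails when the two classes have similar contact
areas. `CrystalContact` implements a flexibility-based alternative: atoms
in genuine binding interfaces tend to be conformationally *rigid*, so the
crystallographic B factor (temperature factor, B = 8π²⟨u²⟩) of interfacial
atoms carries a class signal that buried area does not.

The package is aimed at structural bioinformaticians curating
protein-complex datasets from the PDB, and provides everything from PDB
parsing to threshold classification in one pipeline.

## Method

**Normalized B factor.** Per binding unit (one side of the contact), each
atom's B factor is standardized and mapped onto the 90% normal interval:

    B_norm,i = (B_i − B̄) / (δ_B · 1.645),   clamped to [−1, 1]

where B̄ and δ_B are the mean and (population) standard deviation over the
unit's atoms. Rigid atoms score towards −1, flexible atoms towards +1.

**Interfacial atoms via β contacts.** A cross-interface atom pair (i, j)
is a β contact when (i) dist(i,j) < T_d + vdW_i + vdW_j, (ii) i and j
share a Voronoi facet in the complex's Voronoi diagram, and (iii) no third
atom k subtends an angle ∠ikj ≥ ∠β over the pair (the β-skeleton
forbidden region is empty; at ∠β = 90° this is the Gabriel-graph test).
An atom is *interfacial* when it has ≥ 1 β contact and more than 2 local
contacts (its own β contacts plus those of atoms within two covalent-bond
steps).

**Interface scores.** With min_r the smaller of the two units' average
residues-per-chain:

- `sigmaB`  (ΣB): sum of clamped normalized B factors over interfacial atoms
- `avgSigmaB` = ΣB / log(min_r + 1)
- `noB` (No.B): number of interfacial atoms with negative normalized B,
  and `avgNoB` = No.B / log(min_r + 1)
- compound score `avgNoB · avgSigmaB / 100`
- baseline: buried area ΔASA = (ASA₁ + ASA₂ − ASA_C)/2 (Shrake–Rupley)

**Classification.** A single-feature threshold is learned by scanning all
score midpoints, ranking them by Matthews correlation coefficient (MCC)
and averaging the top 10%; for positives-only training data an empirical
quantile of the positive scores is used instead. Learned thresholds
transfer unchanged across datasets.

## Worked example

Because the package ships a synthetic-structure generator, the whole
pipeline runs without downloads:

```r
library(CrystalContact)

cfg  <- syntheticConfig(seed = 42, bfactorModel = "interface-rigid")
pair <- syntheticComplex(cfg, label = "biological")
interfaceFeatures(pair)
#> InterfaceFeatures SYN000042
#>   sigmaB=-64.753 noB=170 minR=30.00
#>   avgSigmaB=-18.857 avgNoB=49.505 product=-9.3350
#>   deltaASA=522.03 A^2 avgDeltaASA=152.017 (n interfacial=240)
```

The planted interface rigidity (1 standard deviation) drives ΣB strongly
negative: 170 of the 240 interfacial atoms have a negative normalized B.
A packing-like complex (`bfactorModel = "uniform"`) gives avgSigmaB near 0.
Of 2595 distance-filtered atom pairs only 221 survive the Voronoi and
forbidden-region criteria as β contacts — the contact definition is
deliberately sparse.

Threshold learning on planted Gaussian scores:

```r
tr <- syntheticScores(200, 200, muPos = -3, muNeg = 3, sigma = 1, seed = 11)
model <- optimalThreshold(tr$score, tr$label, featureName = "avgSigmaB")
model
#> ThresholdModel for avgSigmaB
#>   threshold=-0.0237 direction=negative-is-biological (41 splits averaged, top 10%)

te <- syntheticScores(200, 200, muPos = -3, muNeg = 3, sigma = 1, seed = 12)
interfaceMetrics(predictInterface(model, te$score), te$label)
#>    tp fp  tn fn precision recall specificity accuracy mcc
#> 1 200  0 200  0         1      1           1        1   1
```

The learned threshold sits at the class midpoint and transfers perfectly
to held-out data at this separation.

Real structures go through `readStructure()` +
`complexFromBiomolecule()` / `complexFromChains()`; a thin CLI over the
same functions is in `inst/scripts/crystalcontact.R` (subcommands
`contacts`, `features`, `train-threshold`, `evaluate`, `synth`).

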