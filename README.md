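# orbgap

Virtual reactivity screening for cycloadditions by **frontier bond-orbital
gaps**, from SMILES alone.

Frontier molecular-orbital theory predicts that an orbital-controlled
cycloaddition is fast when the gap between the substrate's highest occupied
orbital and the enophile's lowest unoccupied orbital is small. For real,
polyfunctional molecules the *global* HOMO/LUMO often sits on a spectator
group, so `orbgap` works with **bond orbitals** instead: the highest occupied
bond orbital (HOBO) and lowest unoccupied bond orbital (LUBO) are the
frontier orbitals restricted — by a quantitative localization threshold — to
the substructure that actually reacts. Candidates are ranked by

```
gap = LUBO(enophile) − HOBO(substrate),      smaller ⇒ more reactive
```

against a cycloheptatriene/norcaradiene (CHT/NCD) reference substrate.

The package implements the whole workflow for people who want to study or
extend this kind of reactivity-ML pipeline without a quantum-chemistry
backend:

1. **Molecular graphs** — SMILES/SDF input, Hückel 4n+2 aromaticity
   perception, canonical ordering, a declared SMARTS subset for fragment
   matching.
2. **Orbital oracle** — a parameterized Hückel π engine
   (`H_ii = α + h_i β`, `H_ij = k_ij β`, classical heteroatom table,
   editable parameter file) producing fragment-localized HOBO/LUBO labels.
3. **Fingerprints** — hashed circular (Morgan-style, radius ≤ 4) and path
   descriptors, 512–4096 bits, bit-exact across platforms.
4. **Dataset** — a synthetic labeled corpus generator over five enophile
   classes (alkene, alkyne, carbonyl, nitroso, azo/triazolinedione) with a
   stated Gaussian label-noise floor, plus CSV schema and stratified splits.
5. **Model zoo** — elastic net (glmnet), ε-SVR (e1071) and a seeded 1–3
   layer neural-network trainer; cross-validated descriptor × model
   **accuracy grid** with argmax selection.
6. **Screening** — predict energies for a candidate panel, compose gaps,
   rank, and flag reactive clusters with an anchor-derived threshold.
7. **CLI** — `orbgap label | generate | featurize | train | gridsearch |
   predict | screen`, each run writing a reproducibility manifest.

## A worked example

```r
library(orbgap)

# 1. the reference substrate: cycloheptatriene, HOBO on the triene
ref <- reference_substrate()                # oracle-labeled
ref$hobo_energy
#> [1] -0.4450419                            # beta units (alpha=0, beta=-1)

# 2. an enophile: nitrosobenzene, LUBO on the N=O bond
lab <- bond_orbital_label(parse_smiles("O=Nc1ccccc1"), "N=O")
c(lab$lubo_energy, lab$lubo_weight)
#> [1] 0.2151193 0.7544144                   # 75% of the orbital on N=O

# 3. the predicted gap (smaller = more reactive)
lab$lubo_energy - ref$hobo_energy
#> [1] 0.6601612
sty <- bond_orbital_label(parse_smiles("C=Cc1ccccc1"), "C=C")
sty$lubo_energy - ref$hobo_energy
#> [1] 1.107195                              # styrene: much less reactive

# 4. screen the shipped 42-compound panel
report <- screen_candidates(load_enophile_panel(), ref,
                            anchor = "O=C1N(c2ccccc2)C(=O)N=N1")
head(report$results[, c("name", "class", "gap", "reactive")], 4)
#>                                  name  class       gap reactive
#> 1 4-phenyl-1-2-4-triazoline-3-5-dione    azo 0.3804697     TRUE
#> 2 4-methyl-1-2-4-triazoline-3-5-dione    azo 0.3804697     TRUE
#> 3                    maleic anhydride alkene 0.4450419    FALSE
#> 4                   N-methylmaleimide alkene 0.4450419    FALSE

tapply(report$results$gap, report$results$class, median)
#>    alkene    alkyne     aryne       azo  carbonyl   nitroso
#> 1.1071953 1.0282607 0.5550419 0.4534544 1.0630759 0.6630630
```

The class medians reproduce the qualitative cluster picture: nitroso and
azo/triazolinedione compounds (and arynes, via externally supplied labels)
form the low-gap reactive stratum; alkenes, alkynes and plain carbonyls sit
well above it.

The ML stages follow the same API:

```r
rec   <- generate_corpus(30, seed = 1)                    # 150 labeled molecules
grid  <- grid_search(default_grid(), rec, target = "lubo", k = 5, seed = 1)
models <- train_energy_models(rec, grid$best$featurizer, grid$best$model)
predict_energies(models, "O=Nc1ccc(Br)cc1")               # HOBO/LUBO from SMILES
```

or from the shell:

```sh
orbgap generate --out corpus.csv --seed 1
orbgap gridsearch --data corpus.csv --out grid.csv --seed 1
orbgap screen --out report.json --anchor "O=C1N(c2ccccc2)C(=O)N=N1"
```

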