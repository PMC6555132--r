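# sigmaphore

An open R toolkit for 3D pharmacophore modelling and virtual screening,
built around sigma-1 receptor (σ1R) ligand recognition. It is aimed at
computational chemists who want a self-contained, scriptable alternative
to commercial pharmacophore suites: every model, feature definition and
protocol is explicit, versioned and reproducible.

## What it does

* **Encoded σ1R model library** — a structure-derived model
  (`5HK1-Ph.A`: one positive-ionizable feature, a proximal hydrophobe at
  3.7 Å, two distal hydrophobes at 7–13 Å, 21 excluded volumes), its
  curated derivative `5HK1-Ph.B` (distal hydrophobes merged at 3.0 Å
  tolerance, proximal widened to 2.2 Å, non-basic amidines excluded
  from the PI mapping), reproduced literature models (Langer, Gund
  up/down, Zampieri, Banister) and the classic Glennon two-distance
  rule. Models live in a portable JSON dialect (`pharmjson/1`) with
  editing operations (`merge_features()`, `set_tolerance()`) that replay
  the published A→B derivation.
* **Geometric matching** — feature perception (PI/HBA/HBD/HYD/AR) from
  explicit substructure definitions, hypothesis enumeration with
  distance pruning, Kabsch least-squares alignment, excluded-volume
  tests, and the FitValue score
  `sum(w * max(0, 1 - (d/tol)^2))`, in rigid or capped flexible mode.
  Special protocols: dual-direction aromatic screening and
  weighted any-omission affinity-prediction ranking.
* **Screening statistics** — enrichment factor (EF), hit rate
  (HR = 100·EF/EF_ideal), sensitivity/specificity and tie-aware
  ROC-AUC, with expectation-based handling of the tied non-hit mass.
* **Structure-derived model generation** — interaction-rule pruning of
  ligand features against a protein pocket plus excluded-volume
  placement, from PDB input or built-in toy complexes.
* **Diversity analysis** — circular (atom-type and functional-class)
  fingerprints at diameters 4/6, MACCS-type keys via OpenBabel, and
  pairwise Tanimoto distance statistics (mean/median/mode, histograms).
* **Synthetic benchmarks** — seeded generators for model-compliant
  actives, three families of decoys, labelled rankings with a target
  AUC, and toy protein–ligand complexes, so the whole stack is testable
  without any proprietary data.

## Worked example

Screen a seeded synthetic library against the curated σ1R model and
evaluate the ranking:

```r
library(sigmaphore)

model <- builtin_models()[["5HK1-Ph.B"]]
model
#> <pharmacophore 5HK1-Ph.B: 3 features, 21 exclusion volumes, max_omitted=0>
#>   [1] PI     (  0.00,  0.00,  0.00) tol 1.60 wt 1.00
#>   [2] HYD    ( -3.70,  0.00,  0.00) tol 2.20 wt 1.00
#>   [3] HYD    (  9.20,  0.25,  0.25) tol 3.00 wt 1.00
#>   PI customization: nonbasic_amidine

lib <- generate_ligand_library(model, n_actives = 30, n_decoys = 120,
                               seed = 42)
ranking <- screen_library(lib, model)
labelled <- join_activity(ranking,
                          dplyr::rename(lib[, c("id", "label")],
                                        compound_id = id))
report <- enrichment_report(labelled, fractions = c(1, 5, 10))
report
#> <screening performance: N=150, actives=30 (20.0%), ROC-AUC=1.000>
#>   top  1.0%: EF 5.00  HR 100.0%  TPR 0.07  TNR 1.00
#>   top  5.0%: EF 5.00  HR 100.0%  TPR 0.27  TNR 1.00
#>   top 10.0%: EF 5.00  HR 100.0%  TPR 0.50  TNR 1.00
```

Every generated active qualifies (the generator's construction
guarantee), no decoy does, so the AUC is 1 and the enrichment factor
equals its ideal value 1/0.20 = 5 at every early fraction — which is
what HR = 100% reports. `autoplot(report)` draws the early-enrichment
curve, `autoplot(report, type = "roc")` the ROC curve, and
`tidy(report)` / `glance(report)` return the numbers as tibbles.

The same machinery runs from the shell via the thin CLI in
`inst/cli/sigmaphore.R` (`models list|show|edit`, `screen`, `evaluate`,
`diversity`, `derive`, `simulate`).

## Package layout

| Area | Files |
|---|---|
| Molecules, SMILES/SDF I/O, ionization, conformers | `R/molecule.R`, `R/chem_io.R` |
| Substructure patterns (SMARTS subset) | `R/smarts.R` |
| Feature perception | `R/features.R` |
| Models, pharmjson, editing, built-ins | `R/pharmacophore.R` |
| Matching, screening protocols | `R/matcher.R` |
| Enrichment statistics | `R/metrics.R` |
| Fingerprints and diversity | `R/diversity.R` |
| Structure-derived generation | `R/derive.R` |
| Synthetic benchmarks | `R/synthetic.R` |
| CLI | `R/cli.R`, `inst/cli/sigmaphore.R` |

The methods vignette (`vignettes/pharmacophore-methods.Rmd`) documents
the model definitions, numerical conventions, design decisions and
limitations in detail.
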