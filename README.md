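# mmrt — retention-time prediction and interpretation for mixed-mode LC-MS metabolomics

Mixed-mode (MM) chromatography retains the polar, often charged metabolites
of central carbon metabolism — sugars, sugar phosphates, carboxylic acids,
amino acids — that reverse-phase columns cannot hold. On such a method the
retention time (RT) is a strong structural identifier, and a model that
predicts RT from structure lets an analyst rank the putative identities of
untargeted MS features that share an exact mass. `mmrt` is an R package
for that workflow, aimed at LC-MS metabolomics practitioners:

* **Graph featurization** — `parse_smiles()` turns a SMILES string into a
  heavy-atom connectivity graph with per-atom features (element, degree,
  valence, formal charge, radicals, hybridization, aromaticity) and
  per-bond features (type, conjugation, ring membership).
* **MPNN regressor** — `mmrt()` fits a message-passing neural network:
  T = 4 rounds of message passing with *edge networks* (a learned map
  A(e_ij) from bond features to a d×d matrix, so node j sends A(e_ij)·h_j
  to node i), GRU node updates, an M = 4-step *set2set* attention readout
  producing a permutation-invariant graph vector, and a single ReLU
  perceptron head. Prediction E_T is in minutes. Implemented in base R with
  analytic backpropagation and Adam; training is seed-reproducible.
* **Ghost-atom attribution** — `atom_effects()` zeroes one atom's feature
  vector (a "ghost" atom with no properties of its own) and reports
  ε_i = E_T − E_T(i), the atom's effect on retention.
  `dataset_subgraph_effects()` sums ε over all connected acyclic subgraphs
  of ≤ 5 heavy atoms, pools them across a dataset by canonical fragment,
  and ranks functional groups from retention-increasing (phosphates,
  carboxylic acids) to retention-decreasing (amides, amines).
  `group_occlusion_effects()` ghosts whole group instances at once, which
  recovers full group contributions even when a converged network encodes
  a group redundantly and per-atom occlusions saturate (see the methods
  vignette).
* **Annotation** — `filter_features()` (p < 0.01, fold change > 2,
  intensity > 1e6, all strict), `match_and_rank()` ([M−H]− and [M+Cl]−
  adducts, 3 ppm tolerance, candidates ranked by |predicted − observed|
  RT).
* **Baselines and QC** — descriptor-based linear/random-forest models
  (`fit_baseline()`, `compare_baselines()`), calibration statistics
  (`linearity_r2()`, `llod()`, `cv_percent()`) and a packaged 33-standard
  validation table (`table1_standards()`, `table1_summaries()`).
* **Synthetic ground truth** — `generate_molecules()` builds datasets whose
  true RT is linear in functional-group counts
  (8 + 15·phosphate + 4·acid − 7·amide − 3·amine + 0.5·hydroxyl min,
  noise sd 0.5), so parameter recovery, attribution signs and annotation
  ranking are all testable end to end without external data.

## Worked example

```r
library(mmrt)

# 60 synthetic molecules with known group-contribution ground truth
d <- generate_molecules(synthetic_spec(n = 60, seed = 42))
fit <- mmrt(rt_min ~ smiles, d, hidden_dim = 32, epochs = 120,
            batch_size = 16, seed = 42)
print(fit)
#> Mixed-mode retention-time MPNN
#>   60 molecules, hidden dim 32, 4 message steps, 4 set2set steps
#>   trained 120 epochs (batch 16, lr 0.001, seed 42); final loss 0.0074
#>   training RMSE 0.707 min; 100.0% of molecules within 2 min

# a phosphorylated acid elutes late; an amide elutes early
round(predict(fit, c("OP(=O)(O)OCCC(=O)O", "CCC(=O)N")), 2)
#> [1] 30.06 -0.87

# ghost-atom effects: phosphorus strongly increases retention
eff <- atom_effects(fit, parse_smiles("OP(=O)(O)OCCC(=O)O"))
round(tapply(eff$epsilon_min, eff$element, mean), 2)
#>    C    O    P
#> 0.46 0.38 3.30
```

The two predictions bracket the generator's true values (27 min for the
phosphate + acid molecule, 1 min for the amide) and the per-element mean
ghost-atom effects recover the expected direction: phosphorus pulls
retention up, while this small training set leaves carbon and oxygen near
zero. `render_atom_colormap()` writes the corresponding red/blue atom
coloring; `match_and_rank()` then uses predicted RTs to order isobaric
candidates for an observed feature.

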