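---
title: "Predicting and interpreting mixed-mode retention times from molecular graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and interpreting mixed-mode retention times from molecular graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mmrt)
```

## The problem

Mixed-mode (MM) liquid chromatography retains the hydrophilic, often charged
metabolites of central carbon metabolism — simple sugars, sugar phosphates,
carboxylic acids, amino acids — that reverse-phase methods cannot hold. The
retention time (RT, minutes) of a metabolite on such a column is a strong,
structure-dependent identifier, so a model that predicts RT from structure
can (i) rank putative identities of untargeted LC-MS features that share an
exact mass, and (ii) be interrogated to reveal which functional groups drive
retention. This package implements that stack in R: graph featurization of
SMILES, a message-passing neural network (MPNN) regressor, ghost-atom
attribution, subgraph effect ranking, descriptor baselines, m/z + RT
candidate ranking, and method-validation statistics.

## Featurization

`parse_smiles()` builds a heavy-atom connectivity graph. Hydrogens are never
nodes; their influence enters only through the valence and degree features.
Each atom is encoded as a 32-dimensional vector: element one-hot over
{C, N, O, P, S, F, Cl, Br, I, other}, degree one-hot (0–5), total-valence
one-hot (0–6), formal charge (scalar, clipped to [−2, 2]), radical-electron
count (scalar), hybridization one-hot {sp, sp2, sp3, sp3d, sp3d2, other} and
an aromaticity flag. Bonds carry a 6-vector: type one-hot
{single, double, triple, aromatic}, a conjugation flag and an in-ring flag.
The layout is versioned (`feature_layout()`); serialized models refuse to
load under a different layout.

Canonicalization is delegated to Open Babel (via ChemmineOB), which also
normalizes kekulized aromatic rings; tokenization, ring perception (a bond
is in a ring iff it is not a bridge), implicit-hydrogen assignment (organic
subset valence rules, aromatic bonds counted as 1.5 and the sum rounded up)
and hybridization (aromatic → sp2; triple or cumulated double bonds → sp;
a double bond on C/N/O → sp2; otherwise sp3, with hypervalent P kept sp3
and hypervalent S labelled sp3d) are implemented in the package, because no
installed R package exposes these per-atom features.

Design choices worth knowing:

* **Stereochemistry is ignored.** The features above are all achiral, so
  enantiomers — and any stereoisomers distinguished only by configuration —
  receive identical predictions. The canonical SMILES retains stereo marks
  for bookkeeping only.
* **Salts are rejected, not silently stripped.** A multi-fragment SMILES is
  an error unless `strip_salts = TRUE`, which keeps the largest fragment.
* **Charge/radical encodings are scalars**, not one-hots; the ranges are a
  package decision (the feature list that inspired this layout does not fix
  its encodings) and are recorded in the layout version.

## The regressor

`mmrt()` trains the network; node states are the atom vectors zero-padded
to `hidden_dim` (default 64, which must be at least the atom feature
length). One round of message passing sends, for every directed bond
(i ← j), the message A(e_ij) h_j, where the *edge network* A(·) is a linear
map from the 6 bond features to a `hidden_dim` × `hidden_dim` matrix; each
node sums its incoming messages and updates through a gated recurrent unit
(GRU). After T = 4 rounds, a *set2set* readout runs M = 4 processing steps:
a GRU controller emits a query q, dot-product attention over node states
yields a weights vector, and the attention-weighted sum r is fed back to
the controller; the final [q; r] is the graph vector. A single hidden layer
with rectified-linear activation and a linear output maps it to the scaled
RT. Because messages are summed and attention is a softmax over all nodes,
the prediction is invariant to atom reindexing by construction (checked to
1e-5 min in the tests).

Two presentation details of the readout are reconciled deliberately: the
set2set stage produces the permutation-invariant embedding, and the single
ReLU perceptron then forms the regression head. The set2set controller is
a GRU rather than an LSTM — the contract is only permutation invariance
plus a fixed-length output, and one recurrent-cell implementation serves
the whole network.

Training minimizes mean squared error on z-scored targets (the scaling
constants are stored in the model and undone at prediction). Optimization
is Adam at learning rate 1e-3, full fixed epoch count (no early stopping),
batch order reshuffled each epoch from the run seed. Defaults are 100
epochs with batch size 64. Training is bit-reproducible given (data order,
config, seed); all parameters and gradients are plain R matrices, and the
backward pass is analytic (verified against numerical differentiation in
the tests to a relative error of 1e-4 on sampled coordinates).

`split_dataset()` rounds the train count half-up, so 398 records at 80%
give exactly 318 train / 80 test. `mmrt_cv()` performs k independent
random resplits by default — five differently seeded 80/20 draws — rather
than disjoint folds; `method = "fold"` provides the partition variant.

## Ghost-atom attribution

`ghost_atom(graph, i)` zeroes atom i's feature vector while leaving all
bonds intact: the atom still occupies its place in the graph but has no
properties of its own. The atom's effect on retention is
ε_i = E_T − E_T(i), the difference between the model's prediction for the
intact molecule and for the ghosted one — always two fresh forward passes,
never a cached shortcut. Positive ε_i means the atom increases RT.

`enumerate_subgraphs()` lists every connected subgraph with up to five
heavy atoms whose bonds are all acyclic; a subgraph containing any in-ring
bond is excluded, so ring systems contribute only single-atom fragments.
(The alternative reading — exclude only complete rings — was considered
and rejected because partial ring arcs are not chemically meaningful
functional groups; the enumeration is verified against an exhaustive
connected-subset oracle.) Each occurrence is scored by Σε_i over its
atoms. `dataset_subgraph_effects()` pools occurrences across a dataset by
a canonical fragment key (exact canonicalization by permutation search,
feasible because fragments have ≤ 5 atoms; keys ignore stereochemistry,
consistent with the featurization), keeps fragments seen at least 30 times
— counting occurrences, so a molecule with two amides contributes two —
and ranks by the **mean** per-occurrence effect. The mean, not the total,
is the comparator because frequent small-effect fragments would otherwise
dominate rare strong ones; the per-fragment totals are still reported.
`group_effects()` aggregates the same ε sums over explicit functional-group
matches (phosphate, carboxylic acid, amide, amine, hydroxyl) instead of
enumerated fragments.

### Saturation of single-atom occlusion

Single-atom occlusion has a known failure mode that the synthetic
experiments expose clearly. A network trained to its loss plateau learns
*redundant* detectors for multi-atom groups: ghosting one oxygen of a
phosphate leaves four atoms whose features and bond pattern still signal
"phosphate", so E_T(i) barely moves and every per-atom ε in the group is
near zero — even though ghosting the *entire* group shifts the prediction
by the group's full contribution. (A ghosted input is also outside the
training distribution, so the network's response to it is extrapolation.)
The effect grows with convergence: moderately trained networks keep
informative per-atom phosphate effects, while fully converged ones
attribute phosphate retention to no single atom. Small, chemically
"localized" groups — the amide carbonyl, a lone amine nitrogen — remain
well attributed at any training length, because removing their one or two
informative atoms destroys the cue.

`group_occlusion_effects()` therefore complements the per-atom measurement:
it ghosts all atoms of a matched group instance simultaneously and reports
E_T minus the ghosted prediction. On converged synthetic fits this recovers
the full group contributions (phosphate ≈ +15 min at a ground truth of
+15) where the per-atom sums saturate. Atom-level maps and the fragment
ranking keep the per-atom ε definition; group-level summaries should prefer
whole-group occlusion.

## Annotation of untargeted features

`filter_features()` applies the strict thresholds p < 0.01, fold change
> 2 and intensity > 1e6 (all strict inequalities; boundary rows are
dropped) and orders by ascending p. `match_and_rank()` converts candidate
formulas to neutral monoisotopic masses from standard isotope masses,
forms [M−H]− and [M+Cl]− m/z values (singly charged negative mode; the
−1.007276 proton shift folds in the electron mass), retains candidates
within 3 ppm (the upstream peak-annotation convention of 5 ppm is a
documented alternative via the `ppm_tol` argument), predicts each
retained candidate's RT from its structure, and ranks by |predicted −
observed| RT with ties broken by |ppm error| then name. Unparseable
candidate SMILES are skipped with a warning rather than failing the run.

## Method-validation statistics

`linearity_r2()` is the squared Pearson correlation of the least-squares
response-vs-amount fit; `llod()` is the smallest amount reaching 3:1
signal-to-noise in all replicates, with `Inf` as the "never detected"
sentinel; `cv_percent()` is the sample SD over mean × 100. The packaged
33-standard table (`table1_standards()`) ships with a checksum; the one
typographical artifact in its printed source (a CV of "z12.4") is cleaned
at load with a message. `table1_summaries()` recomputes the headline
counts: 30/33 standards with R² > 0.98, 33/33 with R² > 0.96, 26/33 with
LOD < 1 pmole, and a median CV of 12.1% (12% when rounded as printed). The
median absolute mass error of the table's column is 0.54 ppm; it is
reported but deliberately not asserted against the published 0.49 ppm
figure, which was computed per injection rather than per metabolite and is
not recoverable from the table. Medians use the midpoint element for odd n
and the mean of the central pair for even n.

## The synthetic generator

`generate_molecules()` produces molecules with *known* ground truth so the
whole stack can be tested end to end without external data. Each molecule
is a random linear carbon scaffold (3–10 carbons) decorated, subject to
valence, with phosphate, carboxylic-acid, amide, amine and hydroxyl groups
(per-molecule counts drawn as Binomial(1, 0.40), Binomial(2, 0.30),
Binomial(1, 0.35), Binomial(1, 0.30) and Binomial(3, 0.35) respectively —
chosen so each group appears often enough to be estimated on a few hundred
molecules). The true RT is linear in the group counts:
8 + 15·phosphate + 4·acid − 7·amide − 3·amine + 0.5·hydroxyl minutes, the
first three magnitudes matching the reported functional-group effects on
mixed-mode retention; the amine value (−3) is a package choice covering a
weak negative contributor, and hydroxyl (+0.5) a weak positive one.
Observed RT adds Gaussian noise (sd 0.5 min). An optional non-additive
phosphate × amide interaction term is available for robustness
experiments. Linearity in group counts is deliberate: it is exactly the
structure ghost-atom attribution should detect, so sign and ranking
recovery is a meaningful end-to-end check.

What the generator does **not** emulate: rings and aromatic systems in the
training scaffolds, isomer-specific retention (true RT depends only on
group counts, so positional isomers share a true RT), intramolecular
hydrogen bonding and other long-range interactions, pH-dependent charge
states, and chromatographic peak shape. A model passing the synthetic
recovery tests has demonstrated that the architecture, training loop and
attribution machinery work — not that real mixed-mode retention is
additive; on real data, published test-set errors are several times the
training error, and molecules with intramolecular hydrogen bonds are
reported as the hardest cases. `generate_feature_table()` likewise builds
annotation fixtures whose decoys share the true candidate's exact mass
(same decoration multiset, different placement) but carry independently
drawn database RTs at least 4 minutes away, and whose non-hit rows each
fail exactly one filter threshold.

## Problem sizes and numerical choices

The recovery experiments in the tests and the acceptance script train on
300 synthetic molecules (80/20 split) for 150 epochs at hidden dimension
64 — the package's standard protocol sized so a full run completes in
minutes on one CPU while leaving the optimizer well past its loss plateau.
Smaller fits in the unit tests use hidden dimension 32 and a few epochs;
they exercise mechanics, not accuracy.

Other numerical decisions: the train-count rounding is half-up; RT
tolerance comparisons (`fraction_within`, filter thresholds) are strict
inequalities; a singular baseline design matrix falls back to a tiny ridge
penalty (λ = 1e-6) with a warning; `llod` returns `Inf` rather than NA
when nothing is detectable; annotation tie-breaks are deterministic
(|ppm|, then name); Glorot initialization with a 1/d-scaled edge network
keeps early message magnitudes stable; and softmax attention subtracts the
row maximum before exponentiation.

## Known limitations

* Enantiomers and configurational stereoisomers are indistinguishable.
* Aromatic perception trusts the canonicalizer's lowercase notation; exotic
  aromatic systems outside the canonicalizer's model are featurized as
  written.
* The descriptor set of the baselines is a documented stand-in, not a
  published feature list.
* The group matchers (`match_groups`) are deliberately simple patterns;
  they are sufficient for the synthetic chemistry and common metabolites
  but are not a general substructure-query engine.
* Real-data error figures reported for mixed-mode retention modelling
  (training/test RMSE on a 398-metabolite library, fractions within
  2 minutes, subset tables) require that library's RT table, which is not
  redistributable here; `evaluate_report()` recomputes such tables when a
  user supplies their own measurements.
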