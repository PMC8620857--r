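# Ghost-atom effects and subgraph effect ranking.

test_that("subgraph enumeration matches the exhaustive oracle on a 30-molecule fixture", {
  fx <- fixture_molecules()$smiles
  syn <- generate_molecules(synthetic_spec(n = 10, seed = 13))$smiles
  mols <- c(fx, syn)
  expect_length(mols, 30L)
  for (smi in mols) {
    g <- parse_smiles(smi)
    expect_equal(nrow(enumerate_subgraphs(g)), brute_subgraph_count(g),
                 info = smi)
  }
})

test_that("known enumeration counts: butane 10, benzene 6, single atom 1", {
  expect_equal(nrow(enumerate_subgraphs(parse_smiles("CCCC"))), 10L)
  expect_equal(nrow(enumerate_subgraphs(parse_smiles("c1ccccc1"))), 6L)
  expect_equal(nrow(enumerate_subgraphs(parse_smiles("C"))), 1L)
  # max_atoms caps fragment size
  sg <- enumerate_subgraphs(parse_smiles("CCCCCCCC"), max_atoms = 3)
  expect_true(all(lengths(sg$atoms) <= 3L))
})

test_that("fragment keys identify the same fragment across molecules", {
  g1 <- parse_smiles("OP(=O)(O)OCC")
  g2 <- parse_smiles("CCCOP(=O)(O)O")
  k1 <- enumerate_subgraphs(g1)
  k2 <- enumerate_subgraphs(g2)
  # the full phosphate fragment must appear under the same key in both
  phos1 <- k1$key[vapply(k1$atoms, function(a)
    sum(g1$element[a] == "O") == 4 && any(g1$element[a] == "P"), logical(1))]
  phos2 <- k2$key[vapply(k2$atoms, function(a)
    sum(g2$element[a] == "O") == 4 && any(g2$element[a] == "P"), logical(1))]
  expect_length(phos1, 1L)
  expect_identical(phos1, phos2)
})

test_that("atom effects are exactly differences of two forward passes", {
  fit <- small_fit()
  g <- parse_smiles("NC(CCC(N)=O)C(=O)O")
  eff <- atom_effects(fit, g)
  expect_equal(nrow(eff), g$n_atoms)
  e_t <- predict(fit, list(g))
  for (i in seq_len(g$n_atoms)) {
    direct <- e_t - predict(fit, list(ghost_atom(g, i)))
    expect_equal(eff$epsilon_min[i], direct, tolerance = 1e-9)
  }
})

test_that("a constant model yields zero effects; double-ghosting yields zero", {
  fit <- small_fit()
  fit$params$w2[] <- 0
  g <- parse_smiles("CC(O)C(=O)O")
  eff <- atom_effects(fit, g)
  expect_true(all(abs(eff$epsilon_min) < 1e-12))

  fit2 <- small_fit()
  gg <- ghost_atom(g, 2L)
  eff2 <- atom_effects(fit2, gg)
  expect_lt(abs(eff2$epsilon_min[2L]), 1e-12)  # zeros stay zeros
})

test_that("dataset_subgraph_effects aggregates per occurrence with mean", {
  fit <- small_fit()
  g <- parse_smiles("CC(O)CC(=O)O")
  eff <- atom_effects(fit, g)$epsilon_min
  tab <- dataset_subgraph_effects(fit, list(g), min_count = 1)
  sg <- enumerate_subgraphs(g)
  expect_equal(sum(tab$n_occurrences), nrow(sg))
  # single-atom fragment aggregate equals the mean of its atoms' effects
  for (el in unique(g$element)) {
    idx <- which(g$element == el)
    row <- tab[tab$fragment == el, ]
    expect_equal(row$n_occurrences, length(idx))
    expect_equal(row$mean_effect_min, mean(eff[idx]), tolerance = 1e-9)
  }
  # ranking is by descending mean effect
  expect_true(all(diff(tab$mean_effect_min) <= 1e-12))
})

test_that("an unreachable min_count gives an empty table, not an error", {
  fit <- small_fit()
  tab <- dataset_subgraph_effects(fit, list(parse_smiles("CCO")),
                                  min_count = 100)
  expect_s3_class(tab, "data.frame")
  expect_equal(nrow(tab), 0L)
})

test_that("atom colormap rendering writes a nonempty image", {
  fit <- small_fit()
  g <- parse_smiles("OP(=O)(O)OCC(O)C(=O)O")
  eff <- atom_effects(fit, g)
  path <- tempfile(fileext = ".png")
  render_atom_colormap(g, eff, path)
  expect_true(file.exists(path))
  expect_gt(file.size(path), 1000)
})

test_that("group effect summaries cover matched groups deterministically", {
  fit <- small_fit()
  smi <- c("OP(=O)(O)OCCC(=O)O", "CCC(=O)N", "CC(N)CO")
  ga <- group_effects(fit, smi)
  go <- group_occlusion_effects(fit, smi)
  expect_setequal(ga$group, c("phosphate", "carboxylic_acid", "amide",
                              "amine", "hydroxyl"))
  expect_setequal(go$group, ga$group)
  # instance counts agree between the two measurements
  expect_equal(go$n_instances[order(go$group)], ga$n_instances[order(ga$group)])
  # for a single-atom group (amine) the two measurements coincide
  expect_equal(go$mean_effect_min[go$group == "amine"],
               ga$mean_effect_min[ga$group == "amine"], tolerance = 1e-9)
  expect_identical(group_effects(fit, smi), ga)
})
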