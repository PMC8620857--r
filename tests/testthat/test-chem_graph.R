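# SMILES parsing and featurization.

test_that("simple molecules parse to the expected skeletons", {
  g <- parse_smiles("CCO")
  expect_equal(g$n_atoms, 3L)
  expect_equal(nrow(g$bonds), 2L)
  expect_true(all(g$bond_features[, 6] == 0))  # no ring flags

  b <- parse_smiles("c1ccccc1")
  expect_equal(b$n_atoms, 6L)
  expect_equal(nrow(b$bonds), 6L)
  expect_true(all(b$aromatic))
  expect_true(all(b$bond_in_ring))
  lay <- feature_layout()
  arom_col <- match("aromatic", .BOND_VOCAB_names <- c("single", "double",
                                                       "triple", "aromatic"))
  expect_true(all(b$bond_features[, arom_col] == 1))

  glc <- parse_smiles("OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O")
  expect_equal(glc$n_atoms, 12L)
  expect_equal(sum(glc$element == "C"), 6L)
  expect_equal(sum(glc$element == "O"), 6L)
  expect_equal(nrow(glc$bonds), 12L)
  expect_equal(sum(glc$bond_in_ring), 6L)  # the six pyranose-ring bonds
})

test_that("one-hot blocks of real atoms sum to 1 and of ghosts to 0", {
  lay <- feature_layout()
  n_el <- length(lay$elements)
  blocks <- list(elem = 1:n_el, degree = n_el + 1:6,
                 valence = n_el + 6 + 1:7,
                 hyb = n_el + 15 + 1:length(lay$hybridizations))
  for (smi in fixture_molecules()$smiles[1:10]) {
    g <- parse_smiles(smi)
    for (b in blocks)
      expect_true(all(rowSums(g$atom_features[, b, drop = FALSE]) == 1),
                  info = smi)
    gg <- ghost_atom(g, 1L)
    for (b in blocks)
      expect_equal(sum(gg$atom_features[1L, b]), 0)
  }
})

test_that("bond-type one-hot sums to 1 for every bond", {
  for (smi in c("CC(=O)O", "C#N", "c1ccccc1", "OC(=O)/C=C/C(=O)O")) {
    g <- parse_smiles(smi)
    expect_true(all(rowSums(g$bond_features[, 1:4, drop = FALSE]) == 1),
                info = smi)
    expect_true(all(g$bond_features[, 5:6] %in% c(0, 1)))
  }
})

test_that("ghost_atom zeroes exactly one atom and is idempotent", {
  g <- parse_smiles("CCO")
  gg <- ghost_atom(g, 3L)
  expect_equal(sum(gg$atom_features[3L, ]), 0)
  expect_identical(gg$atom_features[1:2, ], g$atom_features[1:2, ])
  expect_identical(gg$bonds, g$bonds)
  expect_identical(ghost_atom(gg, 3L)$atom_features, gg$atom_features)
  expect_error(ghost_atom(g, 0L), "out of range")
  expect_error(ghost_atom(g, 4L), "out of range")
})

test_that("featurization is consistent across rewritten SMILES of a molecule", {
  pairs <- list(
    c("OCC(O)CO", "C(O)(CO)CO"),
    c("CC(=O)O", "OC(C)=O"),
    c("c1ccccc1", "C1=CC=CC=C1"),
    c("NC(CCC(=O)O)C(=O)O", "OC(=O)CCC(N)C(=O)O"),
    c("OCC1OC(O)C(O)C(O)C1O", "C1(O)C(O)C(CO)OC(O)C1O"))
  for (p in pairs) {
    g1 <- parse_smiles(p[1])
    g2 <- parse_smiles(p[2])
    expect_identical(g1$smiles_canonical, g2$smiles_canonical, info = p[1])
    # isomorphic featurization: equal multisets of atom and bond rows
    sort_rows <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]
    expect_equal(sort_rows(g1$atom_features), sort_rows(g2$atom_features),
                 info = p[1])
    expect_equal(sort_rows(g1$bond_features), sort_rows(g2$bond_features),
                 info = p[1])
  }
})

test_that("heavy-atom counts agree with an independent formula parser", {
  fx <- fixture_molecules()
  for (i in seq_len(nrow(fx))) {
    g <- parse_smiles(fx$smiles[i])
    counts <- parse_formula(fx$formula[i])
    expect_equal(g$n_atoms, sum(counts[names(counts) != "H"]),
                 info = fx$name[i])
    # and total H (implicit) matches the formula's hydrogen count
    expect_equal(sum(g$n_h), unname(counts["H"]), info = fx$name[i])
  }
})

test_that("invalid and multi-fragment SMILES are rejected with clear errors", {
  expect_error(parse_smiles("notasmiles("), "parse error.*notasmiles")
  expect_error(parse_smiles(""), "parse error")
  expect_error(parse_smiles("[Na+].CC(=O)[O-]"), "multi-fragment")
  g <- parse_smiles("[Na+].CC(=O)[O-]", strip_salts = TRUE)
  expect_equal(g$n_atoms, 4L)  # acetate kept, sodium dropped
  expect_equal(sum(g$charge), -1L)
})

test_that("formal charge and hydrogen-count features come from bracket atoms", {
  g <- parse_smiles("CC(=O)[O-]")
  o_minus <- which(g$charge == -1L)
  expect_length(o_minus, 1L)
  expect_equal(g$element[o_minus], "O")
  lay <- feature_layout()
  charge_col <- length(lay$elements) + 6 + 7 + 1
  expect_equal(g$atom_features[o_minus, charge_col], -1)
})
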