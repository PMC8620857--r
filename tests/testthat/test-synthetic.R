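# Synthetic group-contribution data: exactness, determinism, and agreement
# between the generator's hidden truth and the package's own group matcher.

test_that("with zero noise the RT is exactly the linear group model", {
  spec <- synthetic_spec(n = 30, noise_sd = 0, seed = 17)
  d <- generate_molecules(spec)
  expect_equal(d$rt_min, d$rt_true)
  expected <- spec$intercept +
    d$n_phosphate * spec$effects["phosphate"] +
    d$n_carboxylic_acid * spec$effects["carboxylic_acid"] +
    d$n_amide * spec$effects["amide"] +
    d$n_amine * spec$effects["amine"] +
    d$n_hydroxyl * spec$effects["hydroxyl"]
  expect_equal(d$rt_true, unname(expected))
})

test_that("generation is deterministic under the seed", {
  d1 <- generate_molecules(synthetic_spec(n = 25, seed = 3))
  d2 <- generate_molecules(synthetic_spec(n = 25, seed = 3))
  expect_identical(d1, d2)
  d3 <- generate_molecules(synthetic_spec(n = 25, seed = 4))
  expect_false(identical(d1$smiles, d3$smiles))
})

test_that("every generated SMILES parses and matcher counts equal the truth", {
  d <- generate_molecules(synthetic_spec(n = 50, seed = 19))
  for (i in seq_len(nrow(d))) {
    g <- parse_smiles(d$smiles[i])
    counts <- count_groups(g)
    truth <- c(phosphate = d$n_phosphate[i],
               carboxylic_acid = d$n_carboxylic_acid[i],
               amide = d$n_amide[i],
               amine = d$n_amine[i],
               hydroxyl = d$n_hydroxyl[i])
    expect_equal(counts, truth, info = d$smiles[i])
  }
})

test_that("the dataset RT spread matches the analytic sampling variance", {
  spec <- synthetic_spec(n = 300, seed = 23)
  d <- generate_molecules(spec)
  # closed-form variance of the linear model under the decoration sampling
  # distribution: phosphate~B(1,.4)*15, acid~B(2,.3)*4, amide~B(1,.35)*(-7),
  # amine~B(1,.3)*(-3), hydroxyl~B(3,.35)*0.5, noise sd 0.5
  v <- 0.4 * 0.6 * 15^2 + 2 * 0.3 * 0.7 * 4^2 + 0.35 * 0.65 * 7^2 +
    0.3 * 0.7 * 3^2 + 3 * 0.35 * 0.65 * 0.5^2 + 0.5^2
  expect_lt(stats::sd(d$rt_min), 3 * sqrt(v))
  expect_gt(stats::sd(d$rt_min), sqrt(v) / 3)
})

test_that("the linear baseline recovers the group coefficients", {
  spec <- synthetic_spec(n = 200, seed = 29)
  d <- generate_molecules(spec)
  X <- as.matrix(d[, c("n_phosphate", "n_carboxylic_acid", "n_amide",
                       "n_amine", "n_hydroxyl")])
  fit <- stats::lm(d$rt_min ~ X)
  est <- stats::coef(fit)[-1]
  se <- summary(fit)$coefficients[-1, 2]
  truth <- spec$effects[c("phosphate", "carboxylic_acid", "amide", "amine",
                          "hydroxyl")]
  expect_true(all(abs(est - truth) < 2 * se + 0.2))
})

test_that("the synthetic feature table crosses its designed thresholds exactly", {
  ft <- generate_feature_table(n_features = 12, n_true_hits = 5, seed = 37)
  kept <- filter_features(ft$features)
  expect_equal(nrow(kept), 5L)
  expect_setequal(kept$true_name, paste0("true0", 1:5))
  # with the oracle model, the true candidate ranks 1 for every feature
  oracle <- rt_oracle(ft$db$smiles, ft$db$rt_db)
  for (fi in seq_len(nrow(kept))) {
    m <- match_and_rank(kept[fi, ], ft$db, oracle)
    expect_gt(nrow(m), 1L)  # decoys share the exact mass
    expect_equal(m$name[m$rank == 1], kept$true_name[fi])
  }
})

test_that("decoys share the formula but not the structure or RT", {
  ft <- generate_feature_table(n_features = 6, n_true_hits = 3, seed = 41)
  db <- ft$db
  for (base in unique(sub("_decoy.*", "", db$name))) {
    fam <- db[startsWith(db$name, base), ]
    expect_equal(length(unique(fam$formula)), 1L)
    cans <- vapply(fam$smiles, function(s) parse_smiles(s)$smiles_canonical, "")
    expect_equal(anyDuplicated(cans), 0L)
    if (nrow(fam) > 1)
      expect_gte(min(abs(fam$rt_db[-1] - fam$rt_db[1])), 4)
  }
})

test_that("synthetic calibration has known linearity and detection limit", {
  cal <- generate_calibration(seed = 43)
  expect_length(cal$amounts, 13L)
  expect_equal(unique(round(cal$amounts[-1] / cal$amounts[-13], 9)), 3)
  expect_equal(linearity_r2(cal$amounts, cal$responses[, 1]), 1.0)
  expect_equal(llod(cal$amounts, cal$sn), cal$analytic_llod_pmole)
  # raising the noise floor raises the detection limit
  cal2 <- generate_calibration(noise_floor = 1e6, seed = 43)
  expect_gte(cal2$analytic_llod_pmole, cal$analytic_llod_pmole)
})
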