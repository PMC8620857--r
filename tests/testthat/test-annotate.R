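# Mass matching and retention-based candidate ranking.

test_that("ppm_error matches its definition and is antisymmetric near equality", {
  expect_equal(ppm_error(100.0001, 100.0), 1.0, tolerance = 1e-9)
  expect_equal(ppm_error(52.1, 52.1), 0)
  expect_equal(ppm_error(188.0567, 188.0564), 1.595, tolerance = 1e-3)
  set.seed(41)
  for (r in 1:20) {
    a <- stats::runif(1, 60, 900)
    b <- a * (1 + stats::runif(1, -5e-6, 5e-6))
    expect_equal(ppm_error(a, b), -ppm_error(b, a), tolerance = 1e-4)
  }
  expect_error(ppm_error(-1, 100), "positive")
})

test_that("theoretical m/z from formulas matches standard isotope masses", {
  # glucose [M-H]-: 180.063388 - 1.007276
  expect_equal(theoretical_mz("C6H12O6", "[M-H]-"), 179.056112,
               tolerance = 1e-4)
  expect_equal(theoretical_mz(100.0, list(shift = 0)), 100.0)
  # n-acetylglutamate's formula: within 2 ppm of the observed 188.0567
  mz <- theoretical_mz("C7H11NO5", "[M-H]-")
  expect_equal(mz, 188.0564, tolerance = 1e-4)
  expect_lt(abs(ppm_error(188.0567, mz)), 2)
  expect_error(theoretical_mz("C6H12Xx2"), "unknown element")
  expect_error(theoretical_mz("C6H12O6", "[M+H]+"), "unknown adduct")
})

test_that("feature filtering applies strict thresholds and sorts by p", {
  tab <- data.frame(
    mz = c(100, 200, 300, 400, 500),
    rt_min = 1:5,
    intensity = c(2e6, 2e6, 2e6, 9e5, 2e6),
    p_value = c(0.005, 0.01, 0.001, 0.002, 0.5),
    fold_change = c(3, 3, 2.5, 3, 3))
  out <- filter_features(tab)
  # row2 fails p (boundary, strict), row4 fails intensity, row5 fails p
  expect_equal(out$mz, c(300, 100))   # sorted by ascending p
  expect_equal(nrow(filter_features(tab, p_max = 1, fc_min = 0,
                                    intensity_min = 0)), 5L)
  # boundary on fold change is strict too
  tab$fold_change[1] <- 2
  expect_false(100 %in% filter_features(tab)$mz)
  expect_error(filter_features(tab[, -1]), "missing column.*mz")
})

test_that("candidates are ranked by predicted-RT proximity", {
  db <- data.frame(
    name = c("isoA", "isoB", "isoC"),
    formula = rep("C6H12O6", 3),
    smiles = c("OCC1OC(O)C(O)C(O)C1O",        # glucose
               "OCC1(O)OCC(O)C(O)C1O",        # fructose
               "OCC(O)C(O)C(O)C(O)C=O"),      # open-chain aldose
    stringsAsFactors = FALSE)
  oracle <- rt_oracle(db$smiles, c(10, 20, 30))
  feature <- list(mz = theoretical_mz("C6H12O6", "[M-H]-"), rt_min = 19)
  m <- match_and_rank(feature, db, oracle)
  expect_equal(m$name[m$rank == 1], "isoB")
  expect_equal(m$rt_delta, sort(m$rt_delta))
  # rank 1 minimizes rt_delta (property on random fixtures)
  set.seed(42)
  for (r in 1:5) {
    rts <- sample(5:45, 3)
    orc <- rt_oracle(db$smiles, rts)
    obs <- stats::runif(1, 5, 45)
    mm <- match_and_rank(list(mz = feature$mz, rt_min = obs), db, orc)
    expect_equal(mm$rt_delta[1], min(abs(rts - obs)), tolerance = 1e-9)
  }
})

test_that("empty databases and non-matching masses give empty results", {
  oracle <- rt_oracle("CCO", 8)
  expect_equal(nrow(match_and_rank(list(mz = 100, rt_min = 5),
                                   NULL, oracle)), 0L)
  db <- data.frame(name = "ethanol", formula = "C2H6O", smiles = "CCO",
                   stringsAsFactors = FALSE)
  expect_equal(nrow(match_and_rank(list(mz = 500, rt_min = 5), db, oracle)),
               0L)
})

test_that("chloride adducts are matched and labelled", {
  # threonate-like candidate observable only as [M+Cl]-
  db <- data.frame(name = "threonate", formula = "C4H8O5",
                   smiles = "OCC(O)C(O)C(=O)O", stringsAsFactors = FALSE)
  oracle <- rt_oracle(db$smiles, 23)
  mz_cl <- theoretical_mz("C4H8O5", "[M+Cl]-")
  m <- match_and_rank(list(mz = mz_cl, rt_min = 23), db, oracle)
  expect_equal(nrow(m), 1L)
  expect_equal(m$adduct, "[M+Cl]-")
})

test_that("tightening the ppm tolerance never adds candidates", {
  set.seed(43)
  db <- data.frame(
    name = paste0("cand", 1:6),
    formula = rep(c("C6H12O6", "C6H13O9P"), 3),
    smiles = rep(c("OCC1OC(O)C(O)C(O)C1O",
                   "OP(=O)(O)OCC1OC(O)C(O)C(O)C1O"), 3),
    stringsAsFactors = FALSE)
  oracle <- rt_oracle(db$smiles[1:2], c(10, 30))
  feat <- list(mz = theoretical_mz("C6H12O6", "[M-H]-") * (1 + 2e-6),
               rt_min = 12)
  tols <- c(10, 5, 3, 1, 0.5)
  ns <- vapply(tols, function(tt)
    nrow(match_and_rank(feat, db, oracle, ppm_tol = tt)), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("unparseable candidate SMILES are skipped with a warning", {
  db <- data.frame(name = c("good", "bad"),
                   formula = c("C2H6O", "C2H6O"),
                   smiles = c("CCO", "C1CC"), stringsAsFactors = FALSE)
  fit <- small_fit()
  feat <- list(mz = theoretical_mz("C2H6O", "[M-H]-"), rt_min = 8)
  expect_warning(m <- match_and_rank(feat, db, fit), "bad")
  expect_equal(m$name, "good")
})
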