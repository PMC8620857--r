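# The message-passing network: forward/backward correctness, invariances,
# training behaviour, serialization.

test_that("analytic gradients match numerical gradients", {
  set.seed(42)
  cfg <- mmrt_config(hidden_dim = 32, epochs = 1)
  g <- parse_smiles("CC(=O)OC1=CC=CC=C1C(=O)O")
  lay <- feature_layout()
  par <- mmrt:::.mpnn_init(cfg$hidden_dim, lay$atom_len, lay$bond_len)
  par$w2 <- stats::rnorm(32) * 0.3
  fw <- mmrt:::.mpnn_forward(par, g, cfg, keep_cache = TRUE)
  gr <- list2env(mmrt:::.zero_like(par), parent = emptyenv())
  mmrt:::.mpnn_backward(par, g, cfg, fw$cache, 1.0, gr)
  eps <- 1e-5
  for (nm in c("Wb", "bb", "Wz", "Un", "bn", "Sz", "Tn", "cr", "W1", "w2", "b2")) {
    x <- par[[nm]]
    idx <- if (length(x) > 1) sample(length(x), 4) else 1L
    for (i in idx) {
      p2 <- par
      p2[[nm]][i] <- p2[[nm]][i] + eps
      y1 <- mmrt:::.mpnn_forward(p2, g, cfg)$ys
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      y0 <- mmrt:::.mpnn_forward(p2, g, cfg)$ys
      num <- (y1 - y0) / (2 * eps)
      ana <- gr[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("a zero-head model predicts the de-scaled bias for every molecule", {
  fit <- small_fit()
  fit$params$w2[] <- 0
  fit$params$b2 <- 0.25
  pred <- predict(fit, c("CCO", "OP(=O)(O)OCC", "c1ccccc1"))
  expect_equal(pred,
               rep(0.25 * fit$scaling$sd + fit$scaling$mean, 3),
               tolerance = 1e-12)
})

test_that("predictions are invariant to atom reindexing", {
  fit <- small_fit()
  set.seed(99)
  mols <- generate_molecules(synthetic_spec(n = 20, seed = 21))$smiles
  for (smi in mols) {
    g <- parse_smiles(smi)
    p0 <- predict(fit, list(g))
    for (r in 1:5) {
      p <- sample(g$n_atoms)
      expect_lt(abs(predict(fit, list(permute_graph(g, p))) - p0), 1e-5)
    }
  }
})

test_that("training on a constant target converges to the constant", {
  smi <- c("CCO", "CCCO", "CC(=O)O", "OCCO", "CCN", "CCCC")
  expect_warning(
    fit <- mmrt(graphs = smi, rt = rep(17.3, 6),
                config = mmrt_config(hidden_dim = 32, epochs = 5,
                                     batch_size = 64, seed = 2)),
    "smaller batch")
  expect_true(all(abs(predict(fit, smi) - 17.3) < 0.1))
})

test_that("training separates two RT groups and reduces the loss", {
  groupA <- c("CCO", "CCCO", "CCCCO", "OCCO")
  groupB <- c("OP(=O)(O)OCC", "OP(=O)(O)OCCC", "OP(=O)(O)OCCCC",
              "OP(=O)(O)OCC(O)C")
  fit <- mmrt(graphs = c(groupA, groupB), rt = c(rep(5, 4), rep(40, 4)),
              config = mmrt_config(hidden_dim = 32, epochs = 30,
                                   batch_size = 8, seed = 3))
  pa <- predict(fit, groupA)
  pb <- predict(fit, groupB)
  expect_lt(max(pa), min(pb))
  expect_lte(fit$loss[length(fit$loss)], fit$loss[1])
})

test_that("training is deterministic given data, config and seed", {
  d <- generate_molecules(synthetic_spec(n = 10, seed = 8))
  cfg <- mmrt_config(hidden_dim = 32, epochs = 3, batch_size = 4, seed = 9)
  f1 <- mmrt(graphs = d$smiles, rt = d$rt_min, config = cfg)
  f2 <- mmrt(graphs = d$smiles, rt = d$rt_min, config = cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loss, f2$loss)
})

test_that("non-finite retention times are rejected", {
  expect_error(mmrt(graphs = c("CCO", "CCC"), rt = c(1, NA),
                    config = mmrt_config(hidden_dim = 32, epochs = 1)),
               "non-finite")
})

test_that("the formula interface matches the graphs/rt interface", {
  d <- generate_molecules(synthetic_spec(n = 8, seed = 4))
  cfg <- mmrt_config(hidden_dim = 32, epochs = 2, batch_size = 4, seed = 1)
  f1 <- mmrt(rt_min ~ smiles, d, config = cfg)
  f2 <- mmrt(graphs = d$smiles, rt = d$rt_min, config = cfg)
  expect_identical(f1$params, f2$params)
  expect_s3_class(summary(f1), "summary.mmrt")
  expect_equal(residuals(f1), d$rt_min - f1$fitted.values)
  expect_named(coef(f1), names(f1$params))
})

test_that("models round-trip through save/load with identical predictions", {
  fit <- small_fit()
  probe <- c("CCO", "OP(=O)(O)OCC(O)C(=O)O", "NC(CCC(N)=O)C(=O)O")
  p0 <- predict(fit, probe)
  path <- tempfile(fileext = ".rds")
  mmrt_save(fit, path)
  fit2 <- mmrt_load(path)
  expect_equal(predict(fit2, probe), p0, tolerance = 1e-6)
  expect_identical(fit2$params, fit$params)

  # tampered feature-layout version must fail loudly
  obj <- readRDS(path)
  obj$model$layout_version <- "mmrt-feat-0"
  path2 <- tempfile(fileext = ".rds")
  saveRDS(obj, path2)
  expect_error(mmrt_load(path2), "layout version mismatch")

  # corrupt file
  writeLines("not a model", path2)
  expect_error(mmrt_load(path2), "model file")
})
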