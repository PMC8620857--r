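# Shared fixtures and small oracles used across test files.

# 20 metabolite-like molecules with formulas for the parser cross-check
fixture_molecules <- function() {
  data.frame(
    name = c("ethanol", "acetate", "glycine", "alanine", "pyruvate",
             "lactate", "succinate", "fumarate", "malate", "citrate",
             "glucose", "fructose", "ribose", "glycerol", "g3p",
             "pep", "akg", "glutamate", "glutamine", "benzoate"),
    smiles = c("CCO", "CC(=O)O", "NCC(=O)O", "CC(N)C(=O)O", "CC(=O)C(=O)O",
               "CC(O)C(=O)O", "OC(=O)CCC(=O)O", "OC(=O)/C=C/C(=O)O",
               "OC(=O)CC(O)C(=O)O", "OC(=O)CC(O)(CC(=O)O)C(=O)O",
               "OCC1OC(O)C(O)C(O)C1O", "OCC1(O)OCC(O)C(O)C1O",
               "OCC1OC(O)C(O)C1O", "OCC(O)CO", "OCC(O)COP(=O)(O)O",
               "OC(=O)C(=C)OP(=O)(O)O", "OC(=O)CCC(=O)C(=O)O",
               "NC(CCC(=O)O)C(=O)O", "NC(CCC(N)=O)C(=O)O",
               "OC(=O)c1ccccc1"),
    formula = c("C2H6O", "C2H4O2", "C2H5NO2", "C3H7NO2", "C3H4O3",
                "C3H6O3", "C4H6O4", "C4H4O4", "C4H6O5", "C6H8O7",
                "C6H12O6", "C6H12O6", "C5H10O5", "C3H8O3", "C3H9O6P",
                "C3H5O6P", "C5H6O5", "C5H9NO4", "C5H10N2O3", "C7H6O2"),
    stringsAsFactors = FALSE)
}

# permute the atoms of a graph (new atom a is old atom p[a]); used to test
# permutation invariance without going through SMILES re-rooting
permute_graph <- function(g, p) {
  gp <- g
  gp$atom_features <- g$atom_features[p, , drop = FALSE]
  map <- integer(g$n_atoms)
  map[p] <- seq_len(g$n_atoms)
  bi <- map[g$bonds[, 1L]]
  bj <- map[g$bonds[, 2L]]
  gp$bonds <- cbind(i = pmin(bi, bj), j = pmax(bi, bj))
  gp$element <- g$element[p]
  gp$aromatic <- g$aromatic[p]
  gp$bond_order <- g$bond_order
  gp$bond_in_ring <- g$bond_in_ring
  gp
}

# exhaustive connected-subset enumeration oracle (independent of the ESU
# implementation): all atom subsets of size <= max_atoms whose induced bonds
# contain no ring bond and which are connected under the induced bonds
brute_subgraph_count <- function(graph, max_atoms = 5L) {
  n <- graph$n_atoms
  b <- graph$bonds
  cnt <- 0L
  for (sz in seq_len(min(max_atoms, n))) {
    cmb <- utils::combn(n, sz)
    for (ci in seq_len(ncol(cmb))) {
      s <- cmb[, ci]
      be <- which(b[, 1L] %in% s & b[, 2L] %in% s)
      if (any(graph$bond_in_ring[be])) next
      if (sz > 1L) {
        reach <- s[1L]
        repeat {
          add <- unique(c(b[be, 2L][b[be, 1L] %in% reach],
                          b[be, 1L][b[be, 2L] %in% reach]))
          add <- setdiff(intersect(add, s), reach)
          if (length(add) == 0) break
          reach <- c(reach, add)
        }
        if (length(reach) != sz) next
      }
      cnt <- cnt + 1L
    }
  }
  cnt
}

# small trained model cached across test files (16 molecules, fast)
small_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      d <- generate_molecules(synthetic_spec(n = 24, seed = 5))
      fit <<- mmrt(graphs = d$smiles, rt = d$rt_min,
                   config = mmrt_config(hidden_dim = 32, epochs = 8,
                                        batch_size = 8, seed = 5))
    }
    fit
  }
})
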