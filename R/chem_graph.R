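# Heavy-atom connectivity graphs from SMILES.
#
# Canonicalization is delegated to Open Babel (ChemmineOB); tokenization and
# featurization of the canonical SMILES are done here so that per-atom
# degree / valence / hybridization / aromaticity features are fully
# specified and deterministic.

# Feature-vector layout, versioned so serialized models fail loudly when the
# featurization changes.
.ELEM_VOCAB <- c("C", "N", "O", "P", "S", "F", "Cl", "Br", "I", "other")
.HYB_VOCAB <- c("sp", "sp2", "sp3", "sp3d", "sp3d2", "other")
.BOND_VOCAB <- c("single", "double", "triple", "aromatic")

#' Feature layout used by the graph featurizer
#'
#' Describes the block structure of atom and bond feature vectors: element
#' one-hot over \{C,N,O,P,S,F,Cl,Br,I,other\}, degree one-hot 0--5, total
#' valence one-hot 0--6, formal charge (scalar, clipped to \[-2, 2\]),
#' radical-electron count (scalar), hybridization one-hot, aromaticity flag;
#' bond-type one-hot \{single,double,triple,aromatic\}, conjugation flag,
#' in-ring flag. The version tag is stored in trained models and checked at
#' prediction and load time.
#'
#' @return A list with elements `version`, `atom_len`, `bond_len` and the
#'   block vocabularies.
#' @export
feature_layout <- function() {
  list(
    version = "mmrt-feat-1",
    atom_len = length(.ELEM_VOCAB) + 6L + 7L + 1L + 1L + length(.HYB_VOCAB) + 1L,
    bond_len = length(.BOND_VOCAB) + 2L,
    elements = .ELEM_VOCAB,
    hybridizations = .HYB_VOCAB,
    bond_types = .BOND_VOCAB
  )
}

# default valences for implicit-H assignment (organic subset rules)
.DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

.canonical_smiles <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) ""
  )
  out <- sub("[\t ].*$", "", out)
  out <- gsub("[\r\n]", "", out)
  out
}

# --- SMILES tokenizer -------------------------------------------------------

.tokenize_smiles <- function(s) {
  tokens <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("SMILES parse error: unclosed bracket in '", s, "'")
      tokens[[length(tokens) + 1L]] <- list(type = "atom", tok = substr(s, i, i + j - 1L))
      i <- i + j
    } else if (ch %in% c("C", "B") && i < n && substr(s, i + 1L, i + 1L) %in% c("l", "r") &&
               substr(s, i, i + 1L) %in% c("Cl", "Br")) {
      tokens[[length(tokens) + 1L]] <- list(type = "atom", tok = substr(s, i, i + 1L))
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                         "b", "c", "n", "o", "p", "s")) {
      tokens[[length(tokens) + 1L]] <- list(type = "atom", tok = ch)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      tokens[[length(tokens) + 1L]] <- list(type = "bond", tok = ch)
      i <- i + 1L
    } else if (ch == "%") {
      tokens[[length(tokens) + 1L]] <- list(type = "ring", tok = substr(s, i + 1L, i + 2L))
      i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      tokens[[length(tokens) + 1L]] <- list(type = "ring", tok = ch)
      i <- i + 1L
    } else if (ch %in% c("(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, tok = ch)
      i <- i + 1L
    } else if (ch == ".") {
      tokens[[length(tokens) + 1L]] <- list(type = "dot", tok = ".")
      i <- i + 1L
    } else {
      stop("SMILES parse error: unexpected character '", ch, "' in '", s, "'")
    }
  }
  tokens
}

.parse_bracket_atom <- function(tok, smiles) {
  body <- substr(tok, 2L, nchar(tok) - 1L)
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H[0-9]*)?((?:\\+[0-9]*|-[0-9]*|\\++|-+))?$",
    body))[[1]]
  if (length(m) == 0)
    stop("SMILES parse error: cannot parse bracket atom '", tok, "' in '", smiles, "'")
  sym <- m[3]
  aromatic <- sym %in% c("c", "n", "o", "p", "s", "b", "se", "as")
  elem <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
  htok <- m[5]
  nh <- if (htok == "") 0L else if (htok == "H") 1L else as.integer(substr(htok, 2, nchar(htok)))
  ctok <- m[6]
  charge <- 0L
  if (ctok != "") {
    if (grepl("^\\++$", ctok)) charge <- nchar(ctok)
    else if (grepl("^-+$", ctok)) charge <- -nchar(ctok)
    else if (grepl("^\\+[0-9]+$", ctok)) charge <- as.integer(substr(ctok, 2, nchar(ctok)))
    else if (grepl("^-[0-9]+$", ctok)) charge <- -as.integer(substr(ctok, 2, nchar(ctok)))
  }
  list(elem = elem, aromatic = aromatic, charge = charge, nh = nh, explicit_h = TRUE)
}

# --- graph construction -----------------------------------------------------

.parse_smiles_one <- function(s) {
  tokens <- .tokenize_smiles(s)
  atoms <- list()
  bonds <- list()     # list(i, j, sym)
  stack <- integer(0)
  prev <- NA_integer_
  pending_bond <- ""
  ring_open <- list() # label -> list(atom, sym)

  add_bond <- function(i, j, sym) {
    bonds[[length(bonds) + 1L]] <<- list(i = i, j = j, sym = sym)
  }

  for (tk in tokens) {
    if (tk$type == "atom") {
      tok <- tk$tok
      if (startsWith(tok, "[")) {
        a <- .parse_bracket_atom(tok, s)
      } else {
        aromatic <- tok %in% c("b", "c", "n", "o", "p", "s")
        a <- list(elem = toupper(tok), aromatic = aromatic, charge = 0L,
                  nh = NA_integer_, explicit_h = FALSE)
      }
      atoms[[length(atoms) + 1L]] <- a
      idx <- length(atoms)
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- ""
      prev <- idx
    } else if (tk$type == "bond") {
      pending_bond <- tk$tok
    } else if (tk$type == "ring") {
      lab <- tk$tok
      if (!is.null(ring_open[[lab]])) {
        op <- ring_open[[lab]]
        sym <- if (pending_bond != "") pending_bond else op$sym
        add_bond(op$atom, prev, sym)
        ring_open[[lab]] <- NULL
      } else {
        ring_open[[lab]] <- list(atom = prev, sym = pending_bond)
      }
      pending_bond <- ""
    } else if (tk$type == "(") {
      stack <- c(stack, prev)
    } else if (tk$type == ")") {
      if (length(stack) == 0) stop("SMILES parse error: unbalanced ')' in '", s, "'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tk$type == "dot") {
      stop("SMILES parse error: unexpected fragment separator in '", s, "'")
    }
  }
  if (length(ring_open) > 0 && any(!vapply(ring_open, is.null, logical(1))))
    stop("SMILES parse error: unmatched ring closure in '", s, "'")
  if (length(atoms) == 0) stop("SMILES parse error: no atoms in '", s, "'")
  list(atoms = atoms, bonds = bonds)
}

# bridges (bonds not in any cycle) by DFS; ring bonds are the non-bridges
.ring_bonds <- function(n_atoms, bond_i, bond_j) {
  nb <- vector("list", n_atoms)
  for (e in seq_along(bond_i)) {
    nb[[bond_i[e]]] <- c(nb[[bond_i[e]]], e)
    nb[[bond_j[e]]] <- c(nb[[bond_j[e]]], e)
  }
  disc <- rep(NA_integer_, n_atoms)
  low <- rep(0L, n_atoms)
  is_bridge <- rep(FALSE, length(bond_i))
  timer <- 0L
  visit <- function(u, pe) {
    timer <<- timer + 1L
    disc[u] <<- timer
    low[u] <<- timer
    for (e in nb[[u]]) {
      if (e == pe) next
      v <- if (bond_i[e] == u) bond_j[e] else bond_i[e]
      if (is.na(disc[v])) {
        visit(v, e)
        low[u] <<- min(low[u], low[v])
        if (low[v] > disc[u]) is_bridge[e] <<- TRUE
      } else {
        low[u] <<- min(low[u], disc[v])
      }
    }
  }
  for (u in seq_len(n_atoms)) if (is.na(disc[u])) visit(u, -1L)
  !is_bridge
}

.smallest_valence_geq <- function(elem, x) {
  vs <- .DEFAULT_VALENCE[[elem]]
  if (is.null(vs)) return(NA_real_)
  ok <- vs[vs >= x]
  if (length(ok) == 0) x else ok[1]
}

.one_hot <- function(value, vocab) {
  v <- numeric(length(vocab))
  k <- match(value, vocab)
  if (is.na(k)) k <- length(vocab)  # 'other' bucket is last
  v[k] <- 1
  v
}

.build_graph <- function(parsed, smiles_canonical, name = NA_character_) {
  atoms <- parsed$atoms
  n <- length(atoms)
  bond_i <- vapply(parsed$bonds, function(b) min(b$i, b$j), integer(1))
  bond_j <- vapply(parsed$bonds, function(b) max(b$i, b$j), integer(1))
  bond_sym <- vapply(parsed$bonds, function(b) b$sym, character(1))
  if (any(bond_i == bond_j)) stop("SMILES parse error: self-bond in '", smiles_canonical, "'")

  elem <- vapply(atoms, function(a) a$elem, character(1))
  aromatic_atom <- vapply(atoms, function(a) a$aromatic, logical(1))
  charge <- vapply(atoms, function(a) as.integer(a$charge), integer(1))

  # bond orders: explicit symbol wins; otherwise aromatic when both ends are
  # aromatic atoms, else single ('/' and '\' are directional single bonds)
  n_b <- length(bond_i)
  order <- numeric(n_b)
  bond_arom <- logical(n_b)
  for (e in seq_len(n_b)) {
    sym <- bond_sym[e]
    if (sym == "=") order[e] <- 2
    else if (sym == "#") order[e] <- 3
    else if (sym == ":") { order[e] <- 1.5; bond_arom[e] <- TRUE }
    else if (sym %in% c("-", "/", "\\")) order[e] <- 1
    else {
      if (aromatic_atom[bond_i[e]] && aromatic_atom[bond_j[e]]) {
        order[e] <- 1.5; bond_arom[e] <- TRUE
      } else order[e] <- 1
    }
  }

  ring <- if (n_b > 0) .ring_bonds(n, bond_i, bond_j) else logical(0)

  degree <- integer(n)
  bondsum <- numeric(n)
  n_double <- integer(n)
  n_triple <- integer(n)
  for (e in seq_len(n_b)) {
    for (u in c(bond_i[e], bond_j[e])) {
      degree[u] <- degree[u] + 1L
      bondsum[u] <- bondsum[u] + order[e]
      if (order[e] == 2) n_double[u] <- n_double[u] + 1L
      if (order[e] == 3) n_triple[u] <- n_triple[u] + 1L
    }
  }
  bondsum_i <- as.integer(ceiling(bondsum - 1e-9))

  nh <- integer(n)
  radicals <- integer(n)
  for (k in seq_len(n)) {
    if (atoms[[k]]$explicit_h) {
      nh[k] <- atoms[[k]]$nh
      vadj <- .smallest_valence_geq(elem[k], bondsum_i[k] + nh[k])
      if (!is.na(vadj)) {
        vadj <- vadj + charge[k]
        radicals[k] <- max(0L, as.integer(vadj) - bondsum_i[k] - nh[k])
      }
    } else {
      vd <- .smallest_valence_geq(elem[k], bondsum_i[k])
      nh[k] <- if (is.na(vd)) 0L else max(0L, as.integer(vd) - bondsum_i[k])
    }
  }
  valence <- bondsum_i + nh

  hyb <- character(n)
  for (k in seq_len(n)) {
    hyb[k] <- if (aromatic_atom[k]) "sp2"
      else if (n_triple[k] > 0 || n_double[k] >= 2) "sp"
      else if (n_double[k] > 0 && elem[k] %in% c("C", "N", "O")) "sp2"
      else if (elem[k] %in% c("P") && valence[k] >= 5) "sp3"
      else if (elem[k] %in% c("S") && valence[k] >= 5) "sp3d"
      else "sp3"
  }

  # conjugation: aromatic bond, or single bond joining two unsaturated atoms
  unsat <- aromatic_atom | n_double > 0 | n_triple > 0
  conj <- logical(n_b)
  for (e in seq_len(n_b)) {
    conj[e] <- bond_arom[e] || (unsat[bond_i[e]] && unsat[bond_j[e]])
  }

  lay <- feature_layout()
  atom_feat <- matrix(0, nrow = n, ncol = lay$atom_len)
  for (k in seq_len(n)) {
    atom_feat[k, ] <- c(
      .one_hot(elem[k], .ELEM_VOCAB),
      .one_hot(as.character(min(degree[k], 5L)), as.character(0:5)),
      .one_hot(as.character(min(valence[k], 6L)), as.character(0:6)),
      max(-2L, min(2L, charge[k])),
      radicals[k],
      .one_hot(hyb[k], .HYB_VOCAB),
      as.numeric(aromatic_atom[k])
    )
  }
  bond_feat <- matrix(0, nrow = n_b, ncol = lay$bond_len)
  for (e in seq_len(n_b)) {
    btype <- if (bond_arom[e]) "aromatic"
      else if (order[e] == 2) "double"
      else if (order[e] == 3) "triple" else "single"
    bond_feat[e, ] <- c(.one_hot(btype, .BOND_VOCAB), as.numeric(conj[e]),
                        as.numeric(ring[e]))
  }

  structure(list(
    n_atoms = n,
    atom_features = atom_feat,
    bond_features = bond_feat,
    bonds = cbind(i = bond_i, j = bond_j),
    element = elem,
    aromatic = aromatic_atom,
    charge = charge,
    n_h = nh,
    degree = degree,
    valence = valence,
    hybridization = hyb,
    bond_order = order,
    bond_in_ring = ring,
    ghost = rep(FALSE, n),
    smiles_canonical = smiles_canonical,
    name = name,
    layout_version = lay$version
  ), class = "mmrt_graph")
}

#' Parse a SMILES string into a featurized heavy-atom graph
#'
#' The SMILES is first canonicalized with Open Babel, then tokenized and
#' featurized. Hydrogens are never graph nodes: implicit-hydrogen information
#' enters only through the valence and degree features. Stereochemistry is
#' ignored by the featurization (the canonical SMILES retains it for
#' bookkeeping only), so enantiomers receive identical feature matrices.
#'
#' @param smiles A single SMILES string describing one covalent unit.
#' @param name Optional molecule name stored on the graph.
#' @param strip_salts If `TRUE`, a multi-fragment SMILES (e.g. a salt) is
#'   reduced to its largest fragment by heavy-atom count instead of being
#'   rejected.
#' @return An object of class `mmrt_graph`: atom feature matrix (one row per
#'   heavy atom), bond feature matrix, bond index table (1-based, i < j),
#'   per-atom chemistry annotations and the canonical SMILES.
#' @examples
#' g <- parse_smiles("CCO")
#' g$n_atoms          # 3
#' nrow(g$bonds)      # 2
#' @export
parse_smiles <- function(smiles, name = NA_character_, strip_salts = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(trimws(smiles)))
    stop("SMILES parse error: empty input")
  can <- .canonical_smiles(smiles)
  if (!nzchar(can))
    stop("SMILES parse error: invalid SMILES '", smiles, "'")
  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  if (length(frags) > 1L) {
    if (!strip_salts)
      stop("multi-fragment SMILES '", smiles,
           "' rejected; use strip_salts = TRUE to keep the largest fragment")
    parsed <- lapply(frags, .parse_smiles_one)
    sizes <- vapply(parsed, function(p) length(p$atoms), integer(1))
    keep <- which.max(sizes)
    can <- .canonical_smiles(frags[keep])
    return(.build_graph(.parse_smiles_one(can), can, name))
  }
  .build_graph(.parse_smiles_one(can), can, name)
}

#' Replace an atom by a ghost atom
#'
#' Zeroes the feature vector of atom `i`, creating a "ghost" atom with no
#' properties of its own while leaving the bond list and every other atom
#' untouched. This is the perturbation underlying atom-level retention-time
#' attribution.
#'
#' @param graph An `mmrt_graph`.
#' @param i Atom index (1-based).
#' @return A copy of `graph` with atom `i`'s features zeroed and its `ghost`
#'   flag set.
#' @export
ghost_atom <- function(graph, i) {
  stopifnot(inherits(graph, "mmrt_graph"))
  if (!is.numeric(i) || length(i) != 1L || is.na(i) || i < 1 || i > graph$n_atoms)
    stop("atom index out of range: ", i, " (molecule has ", graph$n_atoms, " atoms)")
  g <- graph
  g$atom_features[i, ] <- 0
  g$ghost[i] <- TRUE
  g
}

#' @export
print.mmrt_graph <- function(x, ...) {
  cat("<mmrt_graph> ", x$smiles_canonical, "\n", sep = "")
  cat("  heavy atoms: ", x$n_atoms, " (", paste(x$element, collapse = ""),
      ")\n  bonds: ", nrow(x$bonds),
      "  ring bonds: ", sum(x$bond_in_ring), "\n", sep = "")
  if (any(x$ghost)) cat("  ghost atoms at:", which(x$ghost), "\n")
  invisible(x)
}

# heavy-atom count from a molecular formula, used as an independent
# cross-check on the parser in the test suite
.formula_heavy_atoms <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  total <- 0L
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    cnt <- gsub("[^0-9]", "", t)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (el != "H") total <- total + cnt
  }
  total
}
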