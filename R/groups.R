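# Functional-group detection on heavy-atom graphs. Used by the descriptor
# baseline, by the attribution summaries, and to verify the synthetic
# generator's ground truth. Pattern definitions are deliberately simple and
# documented; they are a stand-in for a full substructure-query language.

.neighbors_of <- function(graph, k) {
  b <- graph$bonds
  c(b[b[, 1L] == k, 2L], b[b[, 2L] == k, 1L])
}

.bond_order_between <- function(graph, a, b) {
  hit <- (graph$bonds[, 1L] == min(a, b)) & (graph$bonds[, 2L] == max(a, b))
  if (!any(hit)) return(0)
  graph$bond_order[which(hit)[1L]]
}

# carbonyl carbon: C with a double bond to O
.is_carbonyl_c <- function(graph, k) {
  if (graph$element[k] != "C") return(FALSE)
  for (nb in .neighbors_of(graph, k))
    if (graph$element[nb] == "O" && .bond_order_between(graph, k, nb) == 2)
      return(TRUE)
  FALSE
}

#' Locate functional-group instances in a molecule
#'
#' Finds occurrences of five groups relevant to mixed-mode retention:
#' phosphate (P plus its O neighbors), carboxylic acid (carbonyl C with a
#' single-bonded terminal O and no N neighbor), amide (carbonyl C with an N
#' neighbor), amine (non-aromatic N with no carbonyl-carbon neighbor), and
#' hydroxyl (terminal single-bonded O on a non-carbonyl C that is not part
#' of a phosphate or acid).
#'
#' @param graph An `mmrt_graph`.
#' @return A data frame with columns `group` and `atoms` (a list column of
#'   1-based atom index vectors, one row per instance).
#' @export
match_groups <- function(graph) {
  stopifnot(inherits(graph, "mmrt_graph"))
  out_group <- character(0)
  out_atoms <- list()
  add <- function(group, atoms) {
    out_group[[length(out_group) + 1L]] <<- group
    out_atoms[[length(out_atoms) + 1L]] <<- sort(unique(atoms))
  }
  el <- graph$element
  for (k in seq_len(graph$n_atoms)) {
    nbs <- .neighbors_of(graph, k)
    if (el[k] == "P") {
      oxy <- nbs[el[nbs] == "O"]
      if (length(oxy) >= 3) add("phosphate", c(k, oxy))
    } else if (el[k] == "C" && .is_carbonyl_c(graph, k)) {
      o_dbl <- nbs[el[nbs] == "O" &
                     vapply(nbs, function(nb)
                       .bond_order_between(graph, k, nb) == 2, logical(1))]
      o_sgl <- nbs[el[nbs] == "O" & graph$degree[nbs] == 1L &
                     vapply(nbs, function(nb)
                       .bond_order_between(graph, k, nb) == 1, logical(1))]
      n_nb <- nbs[el[nbs] == "N"]
      if (length(n_nb) >= 1) {
        add("amide", c(k, o_dbl[1L], n_nb[1L]))
      } else if (length(o_sgl) >= 1) {
        add("carboxylic_acid", c(k, o_dbl[1L], o_sgl[1L]))
      }
    } else if (el[k] == "N" && !graph$aromatic[k]) {
      carbonyl_nb <- any(vapply(nbs, function(nb) .is_carbonyl_c(graph, nb),
                                logical(1)))
      if (!carbonyl_nb) add("amine", k)
    } else if (el[k] == "O" && graph$degree[k] == 1L && graph$n_h[k] >= 1L) {
      nb <- nbs[1L]
      if (el[nb] == "C" && !.is_carbonyl_c(graph, nb)) add("hydroxyl", k)
    }
  }
  data.frame(group = out_group, atoms = I(out_atoms),
             stringsAsFactors = FALSE)
}

#' Count functional groups per molecule
#'
#' @param graph An `mmrt_graph`.
#' @return Named integer vector over
#'   phosphate/carboxylic_acid/amide/amine/hydroxyl.
#' @export
count_groups <- function(graph) {
  m <- match_groups(graph)
  grps <- c("phosphate", "carboxylic_acid", "amide", "amine", "hydroxyl")
  out <- stats::setNames(integer(length(grps)), grps)
  if (nrow(m) > 0) {
    tb <- table(m$group)
    out[names(tb)] <- as.integer(tb)
  }
  out
}
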