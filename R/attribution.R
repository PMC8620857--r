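# Ghost-atom attribution: per-atom retention effects and subgraph-level
# functional-group effect ranking.

#' Per-atom retention-time effects by ghost-atom perturbation
#'
#' For each atom i the molecule is re-run through the model with that atom's
#' feature vector zeroed (a "ghost" atom), and the effect is the drop in
#' predicted retention time: epsilon_i = E_T - E_Ti, the difference of two
#' forward passes. Positive epsilon means the atom increases retention.
#'
#' @param model A fitted `mmrt` model (or any object with a `predict` method
#'   accepting `mmrt_graph` input).
#' @param graph An `mmrt_graph`.
#' @return A data frame with one row per atom: `atom` (1-based index),
#'   `element`, `epsilon_min`.
#' @export
atom_effects <- function(model, graph) {
  stopifnot(inherits(graph, "mmrt_graph"))
  e_t <- predict(model, list(graph))
  eps <- vapply(seq_len(graph$n_atoms), function(i)
    e_t - predict(model, list(ghost_atom(graph, i))), numeric(1))
  data.frame(atom = seq_len(graph$n_atoms),
             element = graph$element,
             epsilon_min = eps)
}

# --- subgraph enumeration ---------------------------------------------------

# label used in fragment keys: element, aromatic flag, formal charge
.atom_label <- function(graph, k) {
  el <- graph$element[k]
  if (graph$aromatic[k]) el <- tolower(el)
  ch <- graph$charge[k]
  if (ch != 0) {
    sign <- if (ch > 0) "+" else "-"
    el <- paste0("[", el, sign, if (abs(ch) > 1) abs(ch) else "", "]")
  }
  el
}

.bond_token <- function(order) {
  if (order == 2) "=" else if (order == 3) "#" else ""
}

# canonical key for a fragment of <= ~6 atoms: lexicographic minimum over
# permutations of a string encoding of labels and the induced bond matrix
.fragment_canonical <- function(labels, bonds) {
  n <- length(labels)
  if (n == 1L) return(list(key = labels, order = 1L))
  perms <- .permutations(n)
  best <- NULL
  best_p <- NULL
  for (pi in seq_len(nrow(perms))) {
    p <- perms[pi, ]
    pos <- integer(n); pos[p] <- seq_len(n)
    bcodes <- character(nrow(bonds))
    for (e in seq_len(nrow(bonds))) {
      a <- pos[bonds[e, 1L]]; b <- pos[bonds[e, 2L]]
      bcodes[e] <- sprintf("%d-%d%s", min(a, b), max(a, b),
                           .bond_token(bonds[e, 3L]))
    }
    key <- paste(paste(labels[p], collapse = "|"),
                 paste(sort(bcodes), collapse = ","), sep = ";")
    if (is.null(best) || key < best) { best <- key; best_p <- p }
  }
  list(key = best, order = best_p)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (s in seq_len(nrow(sub))) {
      out[r, ] <- c(k, rest[sub[s, ]])
      r <- r + 1L
    }
  }
  out
}

# readable SMILES for an acyclic fragment, written from a canonical atom
# order (fragments never contain ring bonds, so they are trees)
.fragment_smiles <- function(labels, bonds, order) {
  n <- length(labels)
  if (n == 1L) return(labels[1L])
  adj <- vector("list", n)
  for (e in seq_len(nrow(bonds))) {
    a <- bonds[e, 1L]; b <- bonds[e, 2L]
    adj[[a]] <- rbind(adj[[a]], c(b, bonds[e, 3L]))
    adj[[b]] <- rbind(adj[[b]], c(a, bonds[e, 3L]))
  }
  root <- order[1L]
  pos <- integer(n); pos[order] <- seq_len(n)
  visited <- rep(FALSE, n)
  write_atom <- function(k) {
    visited[k] <<- TRUE
    kids <- adj[[k]]
    kids <- kids[!visited[kids[, 1L]], , drop = FALSE]
    if (nrow(kids) > 0) kids <- kids[order(pos[kids[, 1L]]), , drop = FALSE]
    s <- labels[k]
    if (nrow(kids) > 0) {
      parts <- character(nrow(kids))
      for (c_i in seq_len(nrow(kids)))
        parts[c_i] <- paste0(.bond_token(kids[c_i, 2L]),
                             write_atom(kids[c_i, 1L]))
      if (length(parts) > 1)
        s <- paste0(s, paste0("(", parts[-length(parts)], ")", collapse = ""),
                    parts[length(parts)])
      else s <- paste0(s, parts)
    }
    s
  }
  write_atom(root)
}

#' Enumerate connected acyclic subgraphs of a molecule
#'
#' Lists every connected subgraph with at most `max_atoms` heavy atoms whose
#' induced bonds are all acyclic: any subgraph containing an in-ring bond is
#' excluded (ring systems contribute only their single-atom subgraphs).
#' Uniqueness within a molecule is by atom-index set; the canonical fragment
#' key (and a readable fragment SMILES) identifies the same chemical
#' fragment across molecules.
#'
#' @param graph An `mmrt_graph`.
#' @param max_atoms Maximum fragment size (default 5).
#' @return A data frame with list column `atoms` (sorted 1-based indices)
#'   and columns `key` (canonical fragment key) and `fragment`
#'   (fragment SMILES).
#' @export
enumerate_subgraphs <- function(graph, max_atoms = 5L) {
  stopifnot(inherits(graph, "mmrt_graph"), max_atoms >= 1)
  n <- graph$n_atoms
  b <- graph$bonds
  acyclic <- !graph$bond_in_ring
  # adjacency over non-ring bonds only
  adj <- vector("list", n)
  for (e in which(acyclic)) {
    adj[[b[e, 1L]]] <- c(adj[[b[e, 1L]]], b[e, 2L])
    adj[[b[e, 2L]]] <- c(adj[[b[e, 2L]]], b[e, 1L])
  }
  # any ring bond inside the subset disqualifies it
  ring_pairs <- b[graph$bond_in_ring, , drop = FALSE]

  subsets <- list()
  # ESU enumeration: each connected subset is reached exactly once, rooted
  # at its smallest vertex and extended only with larger vertices that are
  # not yet in the exclusive neighborhood of the growing subgraph
  for (root in seq_len(n)) {
    extend <- function(sub, ext) {
      subsets[[length(subsets) + 1L]] <<- sub
      if (length(sub) == max_atoms) return(invisible(NULL))
      nbr_sub <- unique(unlist(adj[sub]))
      while (length(ext) > 0L) {
        w <- ext[1L]
        ext <- ext[-1L]
        new_nb <- adj[[w]]
        new_nb <- new_nb[new_nb > root & !(new_nb %in% sub) &
                           !(new_nb %in% nbr_sub)]
        extend(c(sub, w), unique(c(ext, new_nb)))
      }
    }
    ext0 <- adj[[root]]
    extend(root, ext0[ext0 > root])
  }

  keep <- vapply(subsets, function(s) {
    if (nrow(ring_pairs) == 0) return(TRUE)
    !any(ring_pairs[, 1L] %in% s & ring_pairs[, 2L] %in% s)
  }, logical(1))
  subsets <- subsets[keep]

  keys <- character(length(subsets))
  frags <- character(length(subsets))
  for (si in seq_along(subsets)) {
    s <- sort(subsets[[si]])
    subsets[[si]] <- s
    labels <- vapply(s, function(k) .atom_label(graph, k), "")
    be <- which(b[, 1L] %in% s & b[, 2L] %in% s)
    bonds <- cbind(match(b[be, 1L], s), match(b[be, 2L], s),
                   graph$bond_order[be])
    can <- .fragment_canonical(labels, bonds)
    keys[si] <- can$key
    frags[si] <- .fragment_smiles(labels, bonds, can$order)
  }
  data.frame(atoms = I(subsets), key = keys, fragment = frags,
             stringsAsFactors = FALSE)
}

#' Rank functional-group subgraphs by their effect on retention time
#'
#' Computes ghost-atom effects once per molecule, assigns each subgraph
#' occurrence the sum of its constituent atom effects, pools occurrences
#' across the dataset by canonical fragment key, keeps fragments observed at
#' least `min_count` times (counting occurrences, not molecules), and ranks
#' by the mean per-occurrence effect, most positive first.
#'
#' @param model A fitted `mmrt` model (or compatible predictor).
#' @param graphs List of `mmrt_graph` objects or SMILES strings.
#' @param max_atoms Maximum fragment size (default 5).
#' @param min_count Minimum occurrences across the dataset (default 30).
#' @return A data frame ranked by `mean_effect_min` (descending):
#'   `fragment`, `n_occurrences`, `mean_effect_min`, `sd_effect_min`,
#'   `total_effect_min`.
#' @export
dataset_subgraph_effects <- function(model, graphs, max_atoms = 5L,
                                     min_count = 30L) {
  graphs <- .as_graph_list(graphs)
  key_vals <- new.env(parent = emptyenv())
  key_frag <- new.env(parent = emptyenv())
  for (g in graphs) {
    eff <- atom_effects(model, g)$epsilon_min
    sg <- enumerate_subgraphs(g, max_atoms)
    for (si in seq_len(nrow(sg))) {
      tot <- sum(eff[sg$atoms[[si]]])
      k <- sg$key[si]
      key_vals[[k]] <- c(if (!is.null(key_vals[[k]])) key_vals[[k]], tot)
      if (is.null(key_frag[[k]])) key_frag[[k]] <- sg$fragment[si]
    }
  }
  keys <- ls(key_vals)
  rows <- lapply(keys, function(k) {
    v <- key_vals[[k]]
    data.frame(fragment = key_frag[[k]],
               n_occurrences = length(v),
               mean_effect_min = mean(v),
               sd_effect_min = if (length(v) > 1) stats::sd(v) else 0,
               total_effect_min = sum(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(fragment = character(0),
                                      n_occurrences = integer(0),
                                      mean_effect_min = numeric(0),
                                      sd_effect_min = numeric(0),
                                      total_effect_min = numeric(0))
  out <- out[out$n_occurrences >= min_count, , drop = FALSE]
  out <- out[order(-out$mean_effect_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a molecule with atoms colored by retention effect
#'
#' Writes a 2D depiction (force-directed layout) with a diverging red/blue
#' scale: red atoms increase the predicted retention time, blue atoms
#' decrease it. A color bar gives the effect scale in minutes.
#'
#' @param graph An `mmrt_graph`.
#' @param effects Data frame from [atom_effects()] (or a numeric vector of
#'   per-atom effects in minutes).
#' @param path Output PNG path.
#' @param width,height Image size in pixels.
#' @return `path`, invisibly.
#' @export
render_atom_colormap <- function(graph, effects, path, width = 900,
                                 height = 700) {
  stopifnot(inherits(graph, "mmrt_graph"))
  eps <- if (is.data.frame(effects)) effects$epsilon_min else as.numeric(effects)
  stopifnot(length(eps) == graph$n_atoms)
  xy <- .force_layout(graph)
  lim <- max(abs(eps), 1e-9)
  # diverging blue-white-red
  ramp <- grDevices::colorRamp(c("#2166ac", "#f7f7f7", "#b2182b"))
  cols <- grDevices::rgb(ramp((eps / lim + 1) / 2), maxColorValue = 255)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::layout(matrix(1:2, ncol = 2), widths = c(5, 1))
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
                 main = graph$smiles_canonical, asp = 1)
  for (e in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds[e, 1L]; b <- graph$bonds[e, 2L]
    graphics::segments(xy[a, 1], xy[a, 2], xy[b, 1], xy[b, 2],
                       lwd = if (graph$bond_order[e] >= 2) 4 else 2,
                       col = "grey40")
  }
  graphics::points(xy, pch = 21, bg = cols, cex = 4)
  graphics::text(xy, labels = graph$element, cex = 0.9)
  graphics::par(mar = c(3, 1, 3, 3))
  zseq <- seq(-lim, lim, length.out = 100)
  graphics::image(1, zseq, t(matrix(zseq)), col = grDevices::rgb(
    ramp((zseq / lim + 1) / 2), maxColorValue = 255),
    axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, las = 1)
  graphics::mtext("effect (min)", side = 3, line = 0.5, cex = 0.8)
  invisible(path)
}

# deterministic Fruchterman-Reingold-style layout
.force_layout <- function(graph, iters = 300L) {
  n <- graph$n_atoms
  set.seed(n * 1000L + nrow(graph$bonds))
  xy <- matrix(stats::runif(2 * n), ncol = 2)
  if (n == 1L) return(xy)
  k <- 1 / sqrt(n)
  b <- graph$bonds
  for (it in seq_len(iters)) {
    disp <- matrix(0, n, 2)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- xy[i, ] - xy[j, ]
      dist2 <- max(sum(d^2), 1e-6)
      f <- k^2 / dist2
      disp[i, ] <- disp[i, ] + d * f
      disp[j, ] <- disp[j, ] - d * f
    }
    for (e in seq_len(nrow(b))) {
      d <- xy[b[e, 1L], ] - xy[b[e, 2L], ]
      dist <- sqrt(max(sum(d^2), 1e-12))
      f <- dist / k
      disp[b[e, 1L], ] <- disp[b[e, 1L], ] - d / dist * f * k * 0.5
      disp[b[e, 2L], ] <- disp[b[e, 2L], ] + d / dist * f * k * 0.5
    }
    t_cool <- 0.1 * (1 - it / iters) + 0.01
    len <- sqrt(rowSums(disp^2)) + 1e-12
    xy <- xy + disp / len * pmin(len, t_cool)
  }
  xy
}

#' Aggregate ghost-atom effects over functional-group instances
#'
#' Locates functional-group instances with [match_groups()], assigns each
#' instance the sum of its atoms' ghost-atom effects, and averages across
#' all instances of each group in the dataset. The result estimates each
#' group's contribution to retention time in minutes.
#'
#' @param model A fitted `mmrt` model (or compatible predictor).
#' @param graphs List of `mmrt_graph` objects or SMILES strings.
#' @return Data frame ordered by decreasing effect: `group`, `n_instances`,
#'   `mean_effect_min`, `sd_effect_min`.
#' @export
group_effects <- function(model, graphs) {
  graphs <- .as_graph_list(graphs)
  vals <- list()
  for (g in graphs) {
    eff <- atom_effects(model, g)$epsilon_min
    inst <- match_groups(g)
    for (i in seq_len(nrow(inst))) {
      grp <- inst$group[i]
      vals[[grp]] <- c(vals[[grp]], sum(eff[inst$atoms[[i]]]))
    }
  }
  out <- do.call(rbind, lapply(names(vals), function(grp)
    data.frame(group = grp,
               n_instances = length(vals[[grp]]),
               mean_effect_min = mean(vals[[grp]]),
               sd_effect_min = if (length(vals[[grp]]) > 1)
                 stats::sd(vals[[grp]]) else 0,
               stringsAsFactors = FALSE)))
  if (is.null(out))
    return(data.frame(group = character(0), n_instances = integer(0),
                      mean_effect_min = numeric(0), sd_effect_min = numeric(0)))
  out <- out[order(-out$mean_effect_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group effects by whole-group occlusion
#'
#' Like [group_effects()], but ghosts all atoms of each functional-group
#' instance simultaneously and reports E_T minus the prediction for the
#' fully ghosted group. Single-atom occlusion can underestimate a group
#' whose atoms are redundant cues for a well-converged network (ghosting
#' one phosphate oxygen leaves four atoms that still signal phosphate);
#' occluding the whole instance removes the cue entirely and recovers the
#' group's full contribution.
#'
#' @param model A fitted `mmrt` model (or compatible predictor).
#' @param graphs List of `mmrt_graph` objects or SMILES strings.
#' @return Data frame ordered by decreasing effect: `group`, `n_instances`,
#'   `mean_effect_min`, `sd_effect_min`.
#' @export
group_occlusion_effects <- function(model, graphs) {
  graphs <- .as_graph_list(graphs)
  vals <- list()
  for (g in graphs) {
    inst <- match_groups(g)
    if (nrow(inst) == 0) next
    e_t <- predict(model, list(g))
    for (i in seq_len(nrow(inst))) {
      gg <- g
      for (a in inst$atoms[[i]]) gg <- ghost_atom(gg, a)
      grp <- inst$group[i]
      vals[[grp]] <- c(vals[[grp]], e_t - predict(model, list(gg)))
    }
  }
  out <- do.call(rbind, lapply(names(vals), function(grp)
    data.frame(group = grp,
               n_instances = length(vals[[grp]]),
               mean_effect_min = mean(vals[[grp]]),
               sd_effect_min = if (length(vals[[grp]]) > 1)
                 stats::sd(vals[[grp]]) else 0,
               stringsAsFactors = FALSE)))
  if (is.null(out))
    return(data.frame(group = character(0), n_instances = integer(0),
                      mean_effect_min = numeric(0), sd_effect_min = numeric(0)))
  out <- out[order(-out$mean_effect_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}
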