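# Molecular augmentations for contrastive pretraining: node dropping,
# random-walk subgraph sampling, functional-group transformation and BRICS
# substructure removal, gated by an RMSD acceptance loop.

.infeasible <- function(...) {
  stop(structure(class = c("molembed_augment_infeasible", "error",
                           "condition"),
                 list(message = paste0(...), call = NULL)))
}

.AUG_KINDS <- c("node_drop", "subgraph", "chem_transform",
                "substructure_removal")

#' Augmentation result
#'
#' @param graph the augmented `mol_graph` (with regenerated coordinates).
#' @param kind one of `"node_drop"`, `"subgraph"`, `"chem_transform"`,
#'   `"substructure_removal"`.
#' @param dissimilarity MCS-mapped, Kabsch-aligned coordinate RMSD to the
#'   original molecule (Angstrom), or `Inf`.
#' @param accepted whether `dissimilarity` is below the acceptance threshold.
#' @param attempts number of candidates drawn before this one was returned.
#' @return an object of class `augmentation_result`.
#' @export
augmentation_result <- function(graph, kind, dissimilarity, accepted,
                                attempts = 1L) {
  kind <- match.arg(kind, .AUG_KINDS)
  stopifnot(is.finite(dissimilarity) || is.infinite(dissimilarity),
            dissimilarity >= 0)
  structure(list(graph = graph, kind = kind,
                 dissimilarity = dissimilarity,
                 accepted = isTRUE(accepted),
                 attempts = as.integer(attempts)),
            class = "augmentation_result")
}

#' @exportS3Method base::print
print.augmentation_result <- function(x, ...) {
  cat(sprintf("<augmentation:%s> %d atoms, rmsd %.3f A, %s (attempts %d)\n",
              x$kind, atom_count(x$graph), x$dissimilarity,
              if (x$accepted) "accepted" else "rejected", x$attempts))
  invisible(x)
}

# Rebuild a graph from a subset of atoms (or an edited atom/bond table):
# the MOL block goes through Open Babel so implicit hydrogens are re-filled
# (valence repair) and aromaticity re-perceived.
.rebuild_graph <- function(atoms, bonds) {
  tmp <- structure(list(atoms = atoms, bonds = bonds,
                        edge_features = encode_bond_features(bonds),
                        coords = NULL, smiles = NULL),
                   class = "mol_graph")
  g <- .with_obmol("MOL", .graph_molblock(tmp),
                   function(mol) .graph_from_obmol(mol, with_coords = FALSE))
  g$smiles <- canonical_smiles_of(g)
  validate_valences(g)
  g
}

.induced_subgraph_mol <- function(graph, keep) {
  keep <- sort(keep)
  idx <- match(seq_len(atom_count(graph)), keep)  # old -> new or NA
  atoms <- graph$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- graph$bonds
  sel <- !is.na(idx[b$i]) & !is.na(idx[b$j])
  bonds <- b[sel, , drop = FALSE]
  bonds$i <- idx[bonds$i]
  bonds$j <- idx[bonds$j]
  rownames(bonds) <- NULL
  .rebuild_graph(atoms, bonds)
}

.is_connected_subset <- function(graph, keep) {
  if (length(keep) == 1) return(TRUE)
  sub <- igraph::induced_subgraph(.as_igraph(graph), keep)
  igraph::is_connected(sub)
}

.ensure_coords <- function(graph, seed) {
  if (is.null(graph$coords)) generate_conformer(graph, seed = seed)
  else graph
}

# ---------------------------------------------------------------------------
# Kabsch superposition and the MCS-mapped dissimilarity

# Optimal rigid superposition RMSD of two point sets (rows correspond).
.kabsch_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  D <- P %*% t(R) - Q
  sqrt(mean(rowSums(D^2)))
}

# Correspondences of the smaller graph into the larger: element+charge vertex
# colors, bond-order edge colors (aromatic bonds pooled). When no full
# embedding exists the pattern is greedily peeled (lowest-degree atom first)
# until one is found or fewer than `min_atoms` atoms remain.
.mcs_mappings <- function(small, big, min_atoms = 3L, max_maps = 200L) {
  vc <- function(g) {
    el <- match(g$atoms$element, .ELEMENT_VOCAB)
    el[is.na(el)] <- length(.ELEMENT_VOCAB)
    el * 16L + (pmax(pmin(g$atoms$charge, 7L), -7L) + 8L)
  }
  ec <- function(g) ifelse(g$bonds$aromatic, 9L, g$bonds$order)
  keep <- seq_len(atom_count(small))
  while (length(keep) >= min_atoms) {
    pat <- if (length(keep) == atom_count(small)) small
           else .induced_subgraph_mol(small, keep)
    # igraph's vf2 wrapper takes (target, pattern); color1/edge.color1
    # belong to the target graph
    iso <- tryCatch(
      igraph::subgraph_isomorphisms(
        pattern = .as_igraph(pat), target = .as_igraph(big), method = "vf2",
        vertex.color1 = vc(big), vertex.color2 = vc(pat),
        edge.color1 = ec(big), edge.color2 = ec(pat)),
      error = function(e) list())
    if (length(iso) > 0) {
      maps <- utils::head(iso, max_maps)
      return(list(pattern_atoms = keep,
                  maps = lapply(maps, as.integer)))
    }
    # peel the lowest-degree atom (ties: highest index), keep the largest
    # connected remainder
    deg <- igraph::degree(igraph::induced_subgraph(.as_igraph(small), keep))
    drop_i <- keep[which(deg == min(deg))]
    drop_i <- drop_i[length(drop_i)]
    keep2 <- setdiff(keep, drop_i)
    comp <- igraph::components(
      igraph::induced_subgraph(.as_igraph(small), keep2))
    main <- which.max(tabulate(comp$membership))
    keep <- keep2[comp$membership == main]
  }
  NULL
}

#' Structural dissimilarity between two conformers
#'
#' Atom correspondence is taken from a maximum-common-substructure match
#' (the smaller molecule embedded into the larger, greedily reduced when no
#' full embedding exists; at least 3 mapped atoms required), then the mapped
#' coordinates are superposed by the Kabsch algorithm and the RMSD (Angstrom)
#' returned, minimized over candidate correspondences. `Inf` when no
#' qualifying correspondence exists.
#'
#' @param original,augmented `mol_graph`s with coordinates.
#' @return non-negative RMSD in Angstrom, or `Inf`.
#' @export
dissimilarity <- function(original, augmented) {
  if (is.null(original$coords) || is.null(augmented$coords)) {
    stop("both molecules need coordinates (generate_conformer)",
         call. = FALSE)
  }
  swap <- atom_count(augmented) > atom_count(original)
  small <- if (swap) original else augmented
  big <- if (swap) augmented else original
  mm <- .mcs_mappings(small, big)
  if (is.null(mm)) return(Inf)
  P <- small$coords[mm$pattern_atoms, , drop = FALSE]
  best <- Inf
  for (map in mm$maps) {
    r <- .kabsch_rmsd(P, big$coords[map, , drop = FALSE])
    if (r < best) best <- r
  }
  best
}

# ---------------------------------------------------------------------------
# The four augmentations

#' Node dropping
#'
#' Removes exactly `ceiling(fraction * a)` atoms chosen uniformly at random,
#' resampling (up to 20 times) until the remaining induced subgraph is
#' connected; valences are repaired by implicit hydrogens and coordinates
#' regenerated.
#'
#' @param graph a `mol_graph` with at least 3 atoms.
#' @param fraction fraction of atoms to drop (default 0.1, a conservative
#'   tenth of the graph).
#' @param seed integer seed.
#' @return an [augmentation_result()].
#' @export
node_drop <- function(graph, fraction = 0.1, seed = 1L) {
  a <- atom_count(graph)
  if (a < 3) .infeasible("node_drop needs at least 3 atoms")
  ndrop <- ceiling(fraction * a)
  graph <- .ensure_coords(graph, .child_seed(seed, "orig"))
  if (ndrop == 0) {
    return(augmentation_result(graph, "node_drop", 0, TRUE))
  }
  if (a - ndrop < 1) .infeasible("node_drop would remove every atom")
  keep <- .with_seed(.child_seed(seed, "drop"), {
    res <- NULL
    for (r in 1:20) {
      cand <- sort(sample.int(a, a - ndrop))
      if (.is_connected_subset(graph, cand)) {
        res <- cand
        break
      }
    }
    res
  })
  if (is.null(keep)) .infeasible("no connected node_drop found in 20 draws")
  out <- .induced_subgraph_mol(graph, keep)
  out <- generate_conformer(out, seed = .child_seed(seed, "conf"))
  d <- dissimilarity(graph, out)
  augmentation_result(out, "node_drop", d, d < 3.0)
}

#' Random-walk subgraph sampling
#'
#' A seeded random walk from a uniform start visits nodes until
#' `ceiling(target_fraction * a)` distinct atoms are collected (or `10 * a`
#' steps elapse); the induced subgraph on the visited set (connected by
#' construction) is returned with fresh coordinates.
#'
#' @inheritParams node_drop
#' @param target_fraction fraction of atoms the walk aims to visit.
#' @return an [augmentation_result()].
#' @export
subgraph_sample <- function(graph, target_fraction = 0.8, seed = 1L) {
  a <- atom_count(graph)
  if (a < 3) .infeasible("subgraph_sample needs at least 3 atoms")
  graph <- .ensure_coords(graph, .child_seed(seed, "orig"))
  target <- max(1L, ceiling(target_fraction * a))
  adj <- .sorted_adj(graph)
  visited <- .with_seed(.child_seed(seed, "walk"), {
    cur <- sample.int(a, 1)
    vis <- cur
    steps <- 0
    while (length(vis) < target && steps < 10 * a) {
      steps <- steps + 1
      nb <- adj[[cur]]
      if (length(nb) == 0) break
      cur <- nb[sample.int(length(nb), 1)]
      vis <- union(vis, cur)
    }
    sort(vis)
  })
  out <- if (length(visited) == a) graph
         else .induced_subgraph_mol(graph, visited)
  if (is.null(out$coords)) {
    out <- generate_conformer(out, seed = .child_seed(seed, "conf"))
  }
  d <- if (length(visited) == a) 0 else dissimilarity(graph, out)
  augmentation_result(out, "subgraph", d, d < 3.0)
}

# functional-group catalog: element added/removed via a single bond
.FG_CATALOG <- data.frame(
  group = c("methyl", "hydroxyl", "fluoro", "chloro", "amino"),
  element = c("C", "O", "F", "Cl", "N"),
  nH_terminal = c(3L, 1L, 0L, 0L, 2L),
  stringsAsFactors = FALSE
)

# legal attachment sites: atoms with >= 1 implicit hydrogen to give up
.attach_sites <- function(graph) which(graph$atoms$nH >= 1)

# legal removal sites for a group: terminal atoms matching element and
# hydrogen count, joined by a single non-ring bond
.removal_sites <- function(graph, element, nH_terminal) {
  cand <- which(graph$atoms$element == element &
                  graph$atoms$degree == 1 &
                  graph$atoms$nH == nH_terminal &
                  graph$atoms$charge == 0)
  if (length(cand) == 0) return(integer(0))
  ok <- vapply(cand, function(k) {
    b <- graph$bonds[graph$bonds$i == k | graph$bonds$j == k, ]
    nrow(b) == 1 && b$order[1] == 1 && !b$ring[1]
  }, logical(1))
  cand[ok]
}

#' Chemical transformation: add or remove a functional group
#'
#' One transformation is sampled from a fixed catalog (add/remove methyl,
#' hydroxyl, fluoro, chloro or amino) at a uniformly chosen legal site; the
#' product is valence-validated and re-embedded in 3D.
#'
#' @inheritParams node_drop
#' @param ops which operations to sample from (`"add"`, `"remove"`).
#' @return an [augmentation_result()].
#' @export
chemical_transform <- function(graph, seed = 1L, ops = c("add", "remove")) {
  graph <- .ensure_coords(graph, .child_seed(seed, "orig"))
  moves <- list()
  if ("add" %in% ops) {
    sites <- .attach_sites(graph)
    for (gi in seq_len(nrow(.FG_CATALOG))) {
      for (s in sites) moves[[length(moves) + 1]] <- list(op = "add", gi = gi,
                                                          site = s)
    }
  }
  if ("remove" %in% ops) {
    for (gi in seq_len(nrow(.FG_CATALOG))) {
      for (s in .removal_sites(graph, .FG_CATALOG$element[gi],
                               .FG_CATALOG$nH_terminal[gi])) {
        moves[[length(moves) + 1]] <- list(op = "remove", gi = gi, site = s)
      }
    }
  }
  if (length(moves) == 0) .infeasible("no legal functional-group move")
  mv <- .with_seed(.child_seed(seed, "move"),
                   moves[[sample.int(length(moves), 1)]])
  if (mv$op == "add") {
    atoms <- rbind(graph$atoms,
                   data.frame(element = .FG_CATALOG$element[mv$gi],
                              charge = 0L,
                              nH = .FG_CATALOG$nH_terminal[mv$gi],
                              aromatic = FALSE, degree = 1L))
    bonds <- rbind(graph$bonds,
                   data.frame(i = mv$site, j = nrow(atoms), order = 1L,
                              aromatic = FALSE, ring = FALSE,
                              conjugated = FALSE))
    out <- .rebuild_graph(atoms, bonds)
  } else {
    out <- .induced_subgraph_mol(graph,
                                 setdiff(seq_len(atom_count(graph)),
                                         mv$site))
  }
  out <- generate_conformer(out, seed = .child_seed(seed, "conf"))
  d <- dissimilarity(graph, out)
  augmentation_result(out, "chem_transform", d, d < 3.0)
}

# ---------------------------------------------------------------------------
# BRICS bond detection (Degen et al. rule set, matched per atom with Open
# Babel SMARTS; dummy-atom and explicit-H alternatives dropped since graphs
# are heavy-atom only)

.BRICS_ENV <- c(
  L1 = "[C;D3]([#6,#7,#8])(=O)",
  L3 = "[O;D2]-;!@[#6]",
  L4 = "[C;!D1;!$(C=*)]-;!@[#6]",
  L5 = "[N;!D1;!$(N=*);!$(N-[!#6;!#16])]",
  L6 = "[C;D3;!R](=O)-;!@[#6,#7,#8]",
  L7 = "[C;D2,D3]-[#6]",
  L8 = "[C;!R;!D1;!$(C!-*)]",
  L9 = "[n;+0;$(n(:[c,n,o,s]):[c,n,o,s])]",
  L10 = "[N;R;$(N(@C(=O))@[C,N,O,S])]",
  L11 = "[S;D2](-;!@[#6])",
  L12 = "[S;D4]([#6])(=O)(=O)",
  L13 = "[C;$(C(-;@[C,N,O,S])-;@[N,O,S])]",
  L14 = "[c;$(c(:[c,n,o,s]):[n,o,s])]",
  L15 = "[C;$(C(-;@C)-;@C)]",
  L16 = "[c;$(c(:c):c)]"
)

# allowed (Li, Lj) link pairs; all cleave single acyclic bonds except 7-7
# (double acyclic)
.BRICS_PAIRS <- rbind(
  c(1, 3), c(1, 5), c(1, 10),
  c(3, 4), c(3, 13), c(3, 14), c(3, 15), c(3, 16),
  c(4, 5), c(4, 11),
  c(5, 12), c(5, 13), c(5, 14), c(5, 15), c(5, 16),
  c(6, 13), c(6, 14), c(6, 15), c(6, 16),
  c(7, 7),
  c(8, 9), c(8, 10), c(8, 13), c(8, 14), c(8, 15), c(8, 16),
  c(9, 13), c(9, 14), c(9, 15), c(9, 16),
  c(10, 13), c(10, 14), c(10, 15), c(10, 16),
  c(11, 13), c(11, 14), c(11, 15), c(11, 16),
  c(13, 14), c(13, 15), c(13, 16),
  c(14, 14), c(14, 15), c(14, 16),
  c(15, 16),
  c(16, 16)
)

#' Find BRICS-cleavable bonds
#'
#' Bond endpoints are labelled with the BRICS chemical environments they
#' match; a bond is cleavable when it is an acyclic single bond (double for
#' the 7-7 alkene link) whose endpoint labels form an allowed link pair.
#'
#' @param graph a `mol_graph`.
#' @return data.frame with columns `i`, `j` (atom indices) and `rule`.
#' @export
brics_bonds <- function(graph) {
  envs <- .with_obmol("MOL", .graph_molblock(graph), function(mol) {
    match_fn <- .ob("OBAtom_MatchesSMARTS")
    get_atom <- .ob("OBMol_GetAtom")
    lapply(seq_len(atom_count(graph)), function(k) {
      at <- get_atom(mol, k)
      names(.BRICS_ENV)[vapply(.BRICS_ENV,
                               function(sm) isTRUE(match_fn(at, sm)),
                               logical(1))]
    })
  })
  env_num <- lapply(envs, function(e) as.integer(sub("^L", "", e)))
  out <- data.frame(i = integer(0), j = integer(0), rule = character(0))
  for (k in seq_len(nrow(graph$bonds))) {
    b <- graph$bonds[k, ]
    if (b$ring || b$aromatic) next
    for (p in seq_len(nrow(.BRICS_PAIRS))) {
      li <- .BRICS_PAIRS[p, 1]; lj <- .BRICS_PAIRS[p, 2]
      need_order <- if (li == 7 && lj == 7) 2L else 1L
      if (b$order != need_order) next
      hit <- (li %in% env_num[[b$i]] && lj %in% env_num[[b$j]]) ||
        (lj %in% env_num[[b$i]] && li %in% env_num[[b$j]])
      if (hit) {
        out <- rbind(out, data.frame(i = b$i, j = b$j,
                                     rule = paste0("L", li, "-L", lj)))
        break
      }
    }
  }
  out
}

#' Substructure removal by BRICS decomposition
#'
#' One BRICS-cleavable bond is chosen uniformly among those whose cleavage
#' leaves a connected retained fragment of at least 3 atoms; the smaller
#' fragment is removed, the open valence capped with an implicit hydrogen and
#' coordinates regenerated.
#'
#' @inheritParams node_drop
#' @return an [augmentation_result()].
#' @export
substructure_remove <- function(graph, seed = 1L) {
  bb <- brics_bonds(graph)
  if (nrow(bb) == 0) .infeasible("molecule has no BRICS-cleavable bond")
  graph <- .ensure_coords(graph, .child_seed(seed, "orig"))
  a <- atom_count(graph)
  ig <- .as_igraph(graph)
  cands <- list()
  for (k in seq_len(nrow(bb))) {
    ig2 <- igraph::delete_edges(
      ig, igraph::get_edge_ids(ig, c(bb$i[k], bb$j[k])))
    comp <- igraph::components(ig2)
    if (comp$no != 2) next
    sizes <- tabulate(comp$membership)
    keep_comp <- which.max(sizes)
    keep <- which(comp$membership == keep_comp)
    if (length(keep) >= 3 && length(keep) < a) {
      cands[[length(cands) + 1]] <- list(keep = keep, rule = bb$rule[k])
    }
  }
  if (length(cands) == 0) {
    .infeasible("no BRICS cleavage keeps a connected fragment of >= 3 atoms")
  }
  ch <- .with_seed(.child_seed(seed, "cleave"),
                   cands[[sample.int(length(cands), 1)]])
  out <- .induced_subgraph_mol(graph, ch$keep)
  out <- generate_conformer(out, seed = .child_seed(seed, "conf"))
  d <- dissimilarity(graph, out)
  augmentation_result(out, "substructure_removal", d, d < 3.0)
}

# ---------------------------------------------------------------------------
# Acceptance loop and the four-view set

.run_kind <- function(graph, kind, seed, fraction = 0.1,
                      target_fraction = 0.8) {
  switch(kind,
         node_drop = node_drop(graph, fraction = fraction, seed = seed),
         subgraph = subgraph_sample(graph, target_fraction = target_fraction,
                                    seed = seed),
         chem_transform = chemical_transform(graph, seed = seed),
         substructure_removal = substructure_remove(graph, seed = seed),
         stop("unknown augmentation kind '", kind, "'", call. = FALSE))
}

#' RMSD-gated augmentation
#'
#' Draws augmentation candidates until one measures a dissimilarity below
#' `threshold` (default 3.0 Angstrom RMSD); after `max_tries` failures the
#' minimum-dissimilarity candidate is returned with `accepted = FALSE`.
#'
#' @param graph a `mol_graph`.
#' @param kind augmentation kind (see [augmentation_result()]).
#' @param threshold acceptance threshold in Angstrom (> 0).
#' @param max_tries maximum candidates to draw (>= 1).
#' @param seed integer seed; candidates use derived sub-seeds.
#' @return an [augmentation_result()] with `attempts` recorded.
#' @export
augment_accepted <- function(graph, kind, threshold = 3.0, max_tries = 10L,
                             seed = 1L) {
  stopifnot(threshold > 0, max_tries >= 1)
  kind <- match.arg(kind, .AUG_KINDS)
  best <- NULL
  for (t in seq_len(max_tries)) {
    cand <- .run_kind(graph, kind, seed = .child_seed(seed, kind, t))
    if (cand$dissimilarity < threshold) {
      cand$accepted <- TRUE
      cand$attempts <- t
      return(cand)
    }
    if (is.null(best) || cand$dissimilarity < best$dissimilarity) best <- cand
  }
  best$accepted <- FALSE
  best$attempts <- max_tries
  best
}

#' Build the four augmented views of a molecule
#'
#' One accepted (or best-effort) result per augmentation kind. When a
#' chemistry-dependent kind is infeasible (no functional-group move, no BRICS
#' bond) it falls back to node dropping under a distinct sub-seed so the set
#' always holds exactly four members; the original molecule is never included.
#'
#' @inheritParams augment_accepted
#' @return an `augmentation_set`: list with `members` (G1..G4).
#' @export
build_augmentation_set <- function(graph, seed = 1L, threshold = 3.0,
                                   max_tries = 10L) {
  members <- vector("list", 4)
  names(members) <- paste0("G", 1:4)
  for (ki in seq_along(.AUG_KINDS)) {
    kind <- .AUG_KINDS[ki]
    members[[ki]] <- tryCatch(
      augment_accepted(graph, kind, threshold = threshold,
                       max_tries = max_tries,
                       seed = .child_seed(seed, "set", kind)),
      molembed_augment_infeasible = function(e) {
        augment_accepted(graph, "node_drop", threshold = threshold,
                         max_tries = max_tries,
                         seed = .child_seed(seed, "fallback", kind))
      })
  }
  structure(list(members = members, seed = as.integer(seed)),
            class = "augmentation_set")
}

#' @exportS3Method base::print
print.augmentation_set <- function(x, ...) {
  cat("<augmentation_set>\n")
  for (nm in names(x$members)) {
    m <- x$members[[nm]]
    cat(sprintf("  %s %-20s rmsd %.3f %s\n", nm, m$kind, m$dissimilarity,
                if (m$accepted) "accepted" else "rejected"))
  }
  invisible(x)
}
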