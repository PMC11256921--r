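#' Molecular graph data model
#'
#' A `mol_graph` is the package's heavy-atom molecular graph: atoms carry
#' element, formal charge, implicit-hydrogen count, degree and aromaticity;
#' bonds are stored once as an undirected edge list with a fixed-width binary
#' feature vector per bond (see [edge_feature_schema()]); 3D coordinates (in
#' Angstrom) are optional and attached by [generate_conformer()] or read from
#' SDF. Atom indices are 1-based.
#'
#' @param atoms data.frame with columns `element`, `charge`, `nH`,
#'   `aromatic`, `degree`.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices,
#'   `i < j`), `order`, `aromatic`, `ring`, `conjugated`.
#' @param coords optional numeric matrix with one row per atom and 3 columns.
#' @param smiles canonical SMILES for the molecule, when known.
#' @return An object of class `mol_graph`.
#' @export
mol_graph <- function(atoms, bonds, coords = NULL, smiles = NULL) {
  g <- structure(
    list(
      atoms = atoms,
      bonds = bonds,
      edge_features = encode_bond_features(bonds),
      coords = coords,
      smiles = smiles
    ),
    class = "mol_graph"
  )
  validate_mol_graph(g)
  g
}

#' @exportS3Method base::print
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds%s%s\n",
              atom_count(x), nrow(x$bonds),
              if (!is.null(x$coords)) ", 3D coords" else "",
              if (!is.null(x$smiles)) paste0("  ", x$smiles) else ""))
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param graph a `mol_graph`.
#' @return integer atom count.
#' @export
atom_count <- function(graph) nrow(graph$atoms)

# Structural invariants: valid endpoints, no self loops or duplicate
# undirected edges, uniform feature width, coords shaped a x 3 and finite.
validate_mol_graph <- function(g) {
  a <- nrow(g$atoms)
  b <- g$bonds
  if (nrow(b) > 0) {
    if (any(b$i < 1 | b$i > a | b$j < 1 | b$j > a)) {
      stop("bond endpoints out of range", call. = FALSE)
    }
    if (any(b$i == b$j)) stop("self-loop bond", call. = FALSE)
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) stop("duplicate undirected bond", call. = FALSE)
  }
  if (ncol(g$edge_features) != edge_feature_schema()$k_edge) {
    stop("edge feature width does not match schema", call. = FALSE)
  }
  if (!is.null(g$coords)) {
    if (!is.matrix(g$coords) || nrow(g$coords) != a || ncol(g$coords) != 3 ||
        any(!is.finite(g$coords))) {
      stop("coords must be a finite ", a, " x 3 matrix", call. = FALSE)
    }
  }
  invisible(g)
}

#' Bond feature schema
#'
#' Fixed binary featurization of a chemical bond: one-hot bond order
#' (single / double / triple / aromatic), an in-ring flag and a conjugation
#' flag, giving `k_edge = 6`. Aromatic bonds set the aromatic slot (not the
#' kekulized order slot).
#'
#' @return list with `slots` (slot names) and `k_edge` (total width).
#' @export
edge_feature_schema <- function() {
  list(slots = c("single", "double", "triple", "aromatic", "ring",
                 "conjugated"),
       k_edge = 6L)
}

# Bond table -> binary feature matrix (one row per bond).
encode_bond_features <- function(bonds) {
  sch <- edge_feature_schema()
  m <- matrix(0, nrow = nrow(bonds), ncol = sch$k_edge,
              dimnames = list(NULL, sch$slots))
  if (nrow(bonds) == 0) return(m)
  arom <- bonds$aromatic
  m[cbind(seq_len(nrow(bonds)),
          ifelse(arom, 4L, pmin(bonds$order, 3L)))] <- 1
  m[, "ring"] <- as.numeric(bonds$ring)
  m[, "conjugated"] <- as.numeric(bonds$conjugated)
  m
}

# ---------------------------------------------------------------------------
# Open Babel extraction

.ELEMENTS <- c("1" = "H", "5" = "B", "6" = "C", "7" = "N", "8" = "O",
               "9" = "F", "14" = "Si", "15" = "P", "16" = "S", "17" = "Cl",
               "35" = "Br", "53" = "I")

.element_symbol <- function(z) {
  s <- .ELEMENTS[as.character(z)]
  ifelse(is.na(s), paste0("El", z), s)
}

# Pull atoms, bonds and (optionally) coordinates out of an OBMol. Hydrogens
# are deleted first: all package graphs are heavy-atom graphs.
.graph_from_obmol <- function(mol, with_coords = FALSE) {
  .ob("OBMol_DeleteHydrogens")(mol)
  na <- .ob("OBMol_NumAtoms")(mol)
  if (na < 1) stop("molecule has no heavy atoms", call. = FALSE)
  nb <- .ob("OBMol_NumBonds")(mol)
  get_atom <- .ob("OBMol_GetAtom")
  atoms <- data.frame(
    element = character(na), charge = integer(na), nH = integer(na),
    aromatic = logical(na), degree = integer(na),
    stringsAsFactors = FALSE
  )
  coords <- if (with_coords) matrix(NA_real_, na, 3) else NULL
  for (k in seq_len(na)) {
    at <- get_atom(mol, k)
    atoms$element[k] <- .element_symbol(.ob("OBAtom_GetAtomicNum")(at))
    atoms$charge[k] <- .ob("OBAtom_GetFormalCharge")(at)
    atoms$nH[k] <- .ob("OBAtom_GetImplicitHCount")(at)
    atoms$aromatic[k] <- as.logical(.ob("OBAtom_IsAromatic")(at))
    if (with_coords) {
      coords[k, ] <- c(.ob("OBAtom_GetX")(at), .ob("OBAtom_GetY")(at),
                       .ob("OBAtom_GetZ")(at))
    }
  }
  bonds <- data.frame(i = integer(nb), j = integer(nb), order = integer(nb),
                      aromatic = logical(nb), ring = logical(nb),
                      conjugated = logical(nb))
  get_bond <- .ob("OBMol_GetBond")
  for (k in seq_len(nb)) {
    bd <- get_bond(mol, k - 1L)
    i <- .ob("OBBond_GetBeginAtomIdx")(bd)
    j <- .ob("OBBond_GetEndAtomIdx")(bd)
    bonds$i[k] <- min(i, j)
    bonds$j[k] <- max(i, j)
    bonds$order[k] <- .ob("OBBond_GetBondOrder")(bd)
    bonds$aromatic[k] <- as.logical(.ob("OBBond_IsAromatic")(bd))
    bonds$ring[k] <- as.logical(.ob("OBBond_IsInRing")(bd))
  }
  # conjugation: aromatic, or both end atoms participate in a multiple bond
  multi <- bonds$order > 1 | bonds$aromatic
  in_multi <- rep(FALSE, na)
  in_multi[unique(c(bonds$i[multi], bonds$j[multi]))] <- TRUE
  bonds$conjugated <- bonds$aromatic |
    (in_multi[bonds$i] & in_multi[bonds$j])
  atoms$degree <- tabulate(c(bonds$i, bonds$j), nbins = na)
  if (with_coords && all(coords == 0) && na > 1) coords <- NULL
  mol_graph(atoms, bonds, coords = coords)
}

# ---------------------------------------------------------------------------
# SMILES / SDF I/O

#' Parse a SMILES string into a molecular graph
#'
#' Hydrogens are kept implicit; atom order follows the SMILES atom order and
#' is deterministic for a fixed input. Valences are validated after parsing.
#'
#' @param smiles a single non-empty SMILES string.
#' @return a [mol_graph()] without coordinates.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (!nzchar(trimws(smiles))) stop("empty SMILES string", call. = FALSE)
  g <- tryCatch(
    .with_obmol("SMILES", smiles,
                function(mol) .graph_from_obmol(mol, with_coords = FALSE)),
    error = function(e) {
      stop("unparsable SMILES '", smiles, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (atom_count(g) == 0) stop("unparsable SMILES '", smiles, "'",
                               call. = FALSE)
  g$smiles <- canonical_smiles_of(g)
  validate_valences(g)
  g
}

# V2000 MOL block for a graph (kekulized orders; formal charges as M CHG).
.graph_molblock <- function(graph, title = "") {
  a <- atom_count(graph)
  nb <- nrow(graph$bonds)
  xyz <- graph$coords %||% matrix(0, a, 3)
  lines <- c(
    title, " molembed", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", a, nb),
    vapply(seq_len(a), function(k) {
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              xyz[k, 1], xyz[k, 2], xyz[k, 3], graph$atoms$element[k])
    }, character(1)),
    if (nb > 0) vapply(seq_len(nb), function(k) {
      sprintf("%3d%3d%3d  0  0  0  0", graph$bonds$i[k], graph$bonds$j[k],
              graph$bonds$order[k])
    }, character(1))
  )
  chg <- which(graph$atoms$charge != 0)
  if (length(chg) > 0) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, graph$atoms$charge[grp]),
               collapse = "")))
    }
  }
  paste(c(lines, "M  END"), collapse = "\n")
}

#' Canonical SMILES of a molecular graph
#' @param graph a `mol_graph`.
#' @return canonical SMILES string.
#' @export
canonical_smiles_of <- function(graph) {
  out <- ChemmineOB::convertFormat("MOL", "CAN", .graph_molblock(graph))
  smi <- strsplit(trimws(out), "[ \t\n]")[[1]][1]
  if (is.na(smi) || !nzchar(smi)) stop("canonicalization failed",
                                       call. = FALSE)
  smi
}

#' Write a molecular graph to an SDF (MOL V2000) file
#'
#' @param graph a `mol_graph`; coordinates are written when present
#'   (zero-plane otherwise).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(graph, path) {
  writeLines(c(.graph_molblock(graph, title = graph$smiles %||% ""),
               "$$$$"), path)
  invisible(path)
}

#' Read the first record of an SDF file as a molecular graph
#'
#' @param path SDF/MOL file path.
#' @return a [mol_graph()]; coordinates are attached unless the record is a
#'   flat zero-plane 2D block, which is flagged by absent coords.
#' @export
read_sdf <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) < 4) {
    stop("malformed SDF '", path, "': fewer than 4 header lines (line ",
         length(txt) + 1L, ")", call. = FALSE)
  }
  counts <- substr(txt[4], 1, 6)
  if (is.na(suppressWarnings(as.integer(substr(counts, 1, 3))))) {
    stop("malformed SDF '", path, "': bad counts line (line 4)",
         call. = FALSE)
  }
  g <- .with_obmol("SDF", paste0(paste(txt, collapse = "\n"), "\n"),
                   function(mol) .graph_from_obmol(mol, with_coords = TRUE))
  g$smiles <- canonical_smiles_of(g)
  g
}

#' Round-trip a graph through SDF on disk
#'
#' Writes `graph` to `path` and reads it back; elements, bond orders and
#' coordinates survive at SDF V2000 precision (4 decimals).
#'
#' @inheritParams write_sdf
#' @return the re-read `mol_graph`.
#' @export
sdf_roundtrip <- function(graph, path) {
  write_sdf(graph, path)
  read_sdf(path)
}

# ---------------------------------------------------------------------------
# Conformers

#' Generate 3D coordinates with the MMFF94 force field
#'
#' Coordinates come from a seeded distance-geometry embedding followed by
#' MMFF94 minimization (RDKit's implementation, behind a persistent worker).
#' Heavy-atom coordinates are attached to the graph in its own atom order.
#' Identical `(graph, seed)` yields identical coordinates.
#'
#' @param graph a `mol_graph` with valid valences.
#' @param seed integer seed for the embedding.
#' @param attempts maximum number of embedding attempts before failing.
#' @return the graph with `coords` populated.
#' @export
generate_conformer <- function(graph, seed = 1L, attempts = 10L) {
  stopifnot(atom_count(graph) >= 1)
  validate_valences(graph)
  if (atom_count(graph) == 1) {
    graph$coords <- matrix(0, 1, 3)
    return(graph)
  }
  res <- .rdkit_conformer(.graph_molblock(graph), seed, attempts)
  if (!isTRUE(res$ok)) {
    stop("conformer generation failed",
         if (!is.null(res$attempts)) paste0(" after ", res$attempts,
                                            " attempts"),
         ": ", res$error %||% "unknown error", call. = FALSE)
  }
  coords <- matrix(as.numeric(res$coords), ncol = 3)
  if (nrow(coords) != atom_count(graph) || any(!is.finite(coords)) ||
      min(stats::dist(coords)) <= 0) {
    stop("conformer generation returned degenerate coordinates",
         call. = FALSE)
  }
  graph$coords <- coords
  graph
}

# ---------------------------------------------------------------------------
# Valence validation

.MAX_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 5, S = 6,
                  Cl = 1, Br = 1, I = 1)

#' Validate heavy-atom valences
#'
#' Checks that the kekulized bond-order sum plus implicit hydrogens does not
#' exceed the element's allowed valence (charge-adjusted for N, O, C).
#'
#' @param graph a `mol_graph`.
#' @return the graph, invisibly; errors on violation.
#' @export
validate_valences <- function(graph) {
  a <- atom_count(graph)
  bsum <- rep(0, a)
  if (nrow(graph$bonds) > 0) {
    for (k in seq_len(nrow(graph$bonds))) {
      o <- graph$bonds$order[k]
      bsum[graph$bonds$i[k]] <- bsum[graph$bonds$i[k]] + o
      bsum[graph$bonds$j[k]] <- bsum[graph$bonds$j[k]] + o
    }
  }
  for (k in seq_len(a)) {
    el <- graph$atoms$element[k]
    if (!el %in% names(.MAX_VALENCE)) next
    allowed <- .MAX_VALENCE[[el]]
    ch <- graph$atoms$charge[k]
    if (el == "N") allowed <- allowed + min(ch, 1) - max(-ch, 0)
    if (el == "O") allowed <- allowed + min(ch, 1) - max(-ch, 0)
    if (el == "C" && ch != 0) allowed <- 3
    if (bsum[k] + graph$atoms$nH[k] > allowed + 1e-9) {
      stop(sprintf("valence violation at atom %d (%s): %g bonds + %d H > %g",
                   k, el, bsum[k], graph$atoms$nH[k], allowed),
           call. = FALSE)
    }
  }
  invisible(graph)
}

# ---------------------------------------------------------------------------
# Graph machinery consumed by the structural encodings

# igraph view of the heavy-atom skeleton.
.as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$bonds[, c("i", "j"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = seq_len(atom_count(graph)))
  )
}

#' Shortest-path-distance matrix
#'
#' Unweighted (bond-count) all-pairs shortest path distances. Unreachable
#' pairs carry the sentinel value `a` (the atom count), which exceeds any
#' real path length.
#'
#' @param graph a `mol_graph`.
#' @return symmetric integer a x a matrix with zero diagonal.
#' @export
spd_matrix <- function(graph) {
  a <- atom_count(graph)
  if (a == 1) return(matrix(0L, 1, 1))
  d <- igraph::distances(.as_igraph(graph))
  d[!is.finite(d)] <- a
  m <- matrix(as.integer(d), a, a)
  m
}

# adjacency list with neighbors sorted ascending (tie-break contract)
.sorted_adj <- function(graph) {
  a <- atom_count(graph)
  adj <- vector("list", a)
  for (k in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[k]; j <- graph$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}

# Deterministic BFS shortest path from s to t expanding neighbors in
# ascending index order; returns atom index sequence or NULL if unreachable.
.bfs_path <- function(graph, s, t) {
  if (s == t) return(s)
  a <- atom_count(graph)
  adj <- .sorted_adj(graph)
  parent <- rep(NA_integer_, a)
  seen <- rep(FALSE, a)
  seen[s] <- TRUE
  queue <- s
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (!seen[v]) {
        seen[v] <- TRUE
        parent[v] <- u
        if (v == t) {
          path <- t
          while (path[1] != s) path <- c(parent[path[1]], path)
          return(path)
        }
        queue <- c(queue, v)
      }
    }
  }
  NULL
}

#' Edge feature vectors along the canonical shortest path
#'
#' Returns the bond feature vectors along the deterministic shortest path
#' between atoms `i` and `j`. The query is normalized to
#' `(min(i,j), max(i,j))`, so the result is symmetric in its arguments; ties
#' between equal-length paths are broken by breadth-first search expanding
#' neighbors in ascending index order from the smaller index.
#'
#' @param graph a `mol_graph`.
#' @param i,j 1-based atom indices.
#' @return list of numeric feature vectors, of length `spd(i, j)`; empty for
#'   `i == j` or unreachable pairs.
#' @export
shortest_path_edge_features <- function(graph, i, j) {
  a <- atom_count(graph)
  if (i < 1 || i > a || j < 1 || j > a) {
    stop("atom index out of range [1, ", a, "]", call. = FALSE)
  }
  if (i == j) return(list())
  s <- min(i, j); t <- max(i, j)
  path <- .bfs_path(graph, s, t)
  if (is.null(path)) return(list())
  key <- paste(graph$bonds$i, graph$bonds$j)
  out <- vector("list", length(path) - 1)
  for (k in seq_len(length(path) - 1)) {
    u <- min(path[k], path[k + 1]); v <- max(path[k], path[k + 1])
    idx <- match(paste(u, v), key)
    out[[k]] <- graph$edge_features[idx, ]
  }
  out
}

#' Permute the atom order of a molecular graph
#'
#' Relabels atoms so that new index `k` holds old atom `perm[k]`. Used for
#' permutation-invariance checks of the encoder.
#'
#' @param graph a `mol_graph`.
#' @param perm a permutation of `1:atom_count(graph)`.
#' @return the relabelled `mol_graph`.
#' @export
permute_graph <- function(graph, perm) {
  stopifnot(length(perm) == atom_count(graph),
            all(sort(perm) == seq_len(atom_count(graph))))
  inv <- order(perm)  # inv[old] = new
  atoms <- graph$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- graph$bonds
  bi <- inv[bonds$i]; bj <- inv[bonds$j]
  bonds$i <- pmin(bi, bj); bonds$j <- pmax(bi, bj)
  ord <- order(bonds$i, bonds$j)
  bonds <- bonds[ord, , drop = FALSE]
  rownames(bonds) <- NULL
  coords <- if (!is.null(graph$coords)) graph$coords[perm, , drop = FALSE]
  mol_graph(atoms, bonds, coords = coords, smiles = graph$smiles)
}
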