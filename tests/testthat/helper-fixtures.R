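# Shared fixtures built in code. Conformers and corpora are cached per test
# session since they are deterministic for a fixed seed.

.fix <- new.env(parent = emptyenv())

fix_graph <- function(smiles, seed = 1L, conformer = TRUE) {
  key <- paste0(smiles, "|", seed, "|", conformer)
  if (is.null(.fix[[key]])) {
    g <- parse_smiles(smiles)
    if (conformer) g <- generate_conformer(g, seed = seed)
    .fix[[key]] <- g
  }
  .fix[[key]]
}

fix_aspirin <- function() fix_graph("CC(=O)Oc1ccccc1C(=O)O")
fix_benzene <- function() fix_graph("c1ccccc1")
fix_caffeine <- function() fix_graph("Cn1cnc2c1c(=O)n(C)c(=O)n2C")

# independent Floyd-Warshall oracle for shortest path distances
floyd_warshall <- function(a, bonds, sentinel) {
  d <- matrix(Inf, a, a)
  diag(d) <- 0
  for (k in seq_len(nrow(bonds))) {
    d[bonds$i[k], bonds$j[k]] <- 1
    d[bonds$j[k], bonds$i[k]] <- 1
  }
  for (m in seq_len(a)) {
    for (i in seq_len(a)) {
      for (j in seq_len(a)) {
        if (d[i, m] + d[m, j] < d[i, j]) d[i, j] <- d[i, m] + d[m, j]
      }
    }
  }
  d[!is.finite(d)] <- sentinel
  matrix(as.integer(d), a, a)
}

# random connected molecular-looking graph (carbon skeleton) for property
# tests: a random tree plus a few extra edges
random_carbon_graph <- function(n, extra = 1L) {
  bonds <- data.frame(i = integer(0), j = integer(0))
  for (v in 2:n) {
    u <- sample.int(v - 1, 1)
    bonds <- rbind(bonds, data.frame(i = u, j = v))
  }
  tries <- 0
  while (extra > 0 && tries < 20) {
    tries <- tries + 1
    u <- sample.int(n, 1); v <- sample.int(n, 1)
    if (u != v && !any((bonds$i == min(u, v)) & (bonds$j == max(u, v)))) {
      bonds <- rbind(bonds, data.frame(i = min(u, v), j = max(u, v)))
      extra <- extra - 1
    }
  }
  deg <- tabulate(c(bonds$i, bonds$j), nbins = n)
  if (any(deg > 4)) return(NULL)  # not a valid carbon skeleton; caller redraws
  atoms <- data.frame(element = rep("C", n), charge = 0L,
                      nH = pmax(0L, 4L - deg), aromatic = FALSE, degree = deg)
  bonds$order <- 1L
  bonds$aromatic <- FALSE
  bonds$ring <- FALSE
  bonds$conjugated <- FALSE
  mol_graph(atoms, bonds)
}

draw_carbon_graph <- function(n, extra = 1L) {
  repeat {
    g <- random_carbon_graph(n, extra)
    if (!is.null(g)) return(g)
  }
}

rigid_transform <- function(coords, seed) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]),
                 cos(th[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0, -sin(th[2]), 0,
                 cos(th[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0, 0,
                 0, 1), 3, 3, byrow = TRUE)
  shift <- matrix(stats::runif(3, -10, 10), nrow(coords), 3, byrow = TRUE)
  coords %*% (Rx %*% Ry %*% Rz) + shift
}

random_unit_rows <- function(n, d) {
  m <- matrix(stats::rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

make_embedding_batch <- function(N, d = 6, nt = 3) {
  contrastive_batch(lapply(seq_len(N), function(i) {
    list(G = matrix(stats::rnorm(4 * d), 4, d),
         T = matrix(stats::rnorm(nt * d), nt, d))
  }))
}
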