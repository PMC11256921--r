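test_that("parse_smiles builds correct heavy-atom graphs", {
  g1 <- parse_smiles("C")
  expect_equal(atom_count(g1), 1)
  expect_equal(nrow(g1$bonds), 0)
  expect_null(g1$coords)

  g2 <- parse_smiles("CC")
  expect_equal(atom_count(g2), 2)
  expect_equal(nrow(g2$bonds), 1)
  expect_equal(unname(g2$edge_features[1, "single"]), 1)
  expect_equal(sum(g2$edge_features[1, c("double", "triple", "aromatic")]), 0)

  gb <- parse_smiles("c1ccccc1")
  expect_equal(atom_count(gb), 6)
  expect_equal(nrow(gb$bonds), 6)
  expect_true(all(gb$bonds$aromatic))
  expect_true(all(gb$atoms$degree == 2))
  expect_equal(sum(gb$edge_features[, "aromatic"]), 6)
})

test_that("parse_smiles is idempotent through canonicalization", {
  for (smi in c("CC(=O)Oc1ccccc1C(=O)O", "OC(=O)c1ccccc1O", "C[N+](C)(C)C",
                "Cn1cnc2c1c(=O)n(C)c(=O)n2C")) {
    g <- parse_smiles(smi)
    g2 <- parse_smiles(g$smiles)
    expect_equal(g2$smiles, g$smiles)
    expect_equal(atom_count(g2), atom_count(g))
    expect_equal(nrow(g2$bonds), nrow(g$bonds))
    expect_equal(sort(table(g2$atoms$element)), sort(table(g$atoms$element)))
  }
})

test_that("parse errors are informative", {
  expect_error(parse_smiles(""), "empty")
  expect_error(parse_smiles("C(#@!"), "unparsable")
  expect_error(parse_smiles("C(C)(C)(C)(C)C"), "valence violation")
})

test_that("spd_matrix matches a Floyd-Warshall oracle on random graphs", {
  set.seed(42)
  for (r in 1:30) {
    n <- sample(2:12, 1)
    g <- draw_carbon_graph(n, extra = sample(0:2, 1))
    expect_equal(spd_matrix(g), floyd_warshall(n, g$bonds, sentinel = n))
  }
})

test_that("spd_matrix handles trivial and disconnected cases", {
  expect_equal(spd_matrix(parse_smiles("C")), matrix(0L, 1, 1))
  m <- spd_matrix(parse_smiles("CCC"))
  expect_equal(m[1, 3], 2L)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0L, 3))
  # two disconnected atoms: sentinel equals atom count
  atoms <- data.frame(element = c("C", "C"), charge = 0L, nH = 4L,
                      aromatic = FALSE, degree = 0L)
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                      aromatic = logical(0), ring = logical(0),
                      conjugated = logical(0))
  g <- mol_graph(atoms, bonds)
  expect_equal(spd_matrix(g)[1, 2], 2L)
})

test_that("shortest_path_edge_features follows the canonical-path contract", {
  g <- parse_smiles("CCC")
  adj <- shortest_path_edge_features(g, 1, 2)
  expect_length(adj, 1)
  expect_equal(unname(adj[[1]]["single"]), 1)
  expect_length(shortest_path_edge_features(g, 2, 2), 0)
  expect_error(shortest_path_edge_features(g, 0, 2), "out of range")

  # symmetry by (min, max) normalization on a fused-ring molecule
  gn <- parse_smiles("c1ccc2ccccc2c1")
  for (pair in list(c(1, 6), c(2, 9), c(3, 10))) {
    expect_identical(shortest_path_edge_features(gn, pair[1], pair[2]),
                     shortest_path_edge_features(gn, pair[2], pair[1]))
  }

  # 4-cycle with a marked bond: both 2-step paths exist between opposite
  # corners; BFS expanding ascending neighbors must take the one through
  # atom 2, whose first bond is the double bond
  gc4 <- parse_smiles("C1=CCC1")
  feats <- shortest_path_edge_features(gc4, 1, 3)
  expect_length(feats, 2)
  expect_equal(unname(feats[[1]]["double"]), 1)  # bond 1=2
  expect_equal(unname(feats[[2]]["single"]), 1)  # bond 2-3
})

test_that("conformers are deterministic, seeded and physically plausible", {
  g <- parse_smiles("CC")
  c1 <- generate_conformer(g, seed = 11)
  c2 <- generate_conformer(g, seed = 11)
  expect_identical(c1$coords, c2$coords)
  len <- sqrt(sum((c1$coords[1, ] - c1$coords[2, ])^2))
  expect_gt(len, 1.2)
  expect_lt(len, 1.8)

  c3 <- generate_conformer(g, seed = 12)
  expect_false(isTRUE(all.equal(c1$coords, c3$coords)))

  m <- generate_conformer(parse_smiles("C"), seed = 7)
  expect_equal(dim(m$coords), c(1, 3))

  asp1 <- generate_conformer(fix_aspirin(), seed = 5)
  asp2 <- generate_conformer(fix_aspirin(), seed = 5)
  expect_identical(asp1$coords, asp2$coords)
})

test_that("sdf files round-trip elements, orders and coordinates", {
  g <- generate_conformer(parse_smiles("c1ccccc1"), seed = 2)
  path <- withr::local_tempfile(fileext = ".sdf")
  rt <- sdf_roundtrip(g, path)
  expect_identical(rt$atoms$element, g$atoms$element)
  expect_identical(sort(rt$bonds$order), sort(g$bonds$order))
  expect_lt(max(abs(rt$coords - g$coords)), 1e-4)

  # 2D record: zero-plane coordinates read back as absent
  g2d <- parse_smiles("CCO")
  path2 <- withr::local_tempfile(fileext = ".sdf")
  rt2 <- sdf_roundtrip(g2d, path2)
  expect_null(rt2$coords)

  empty <- withr::local_tempfile(fileext = ".sdf")
  writeLines("", empty)
  expect_error(read_sdf(empty), "malformed SDF")
})

test_that("permute_graph relabels consistently", {
  g <- generate_conformer(fix_aspirin(), seed = 3)
  set.seed(9)
  p <- sample(atom_count(g))
  gp <- permute_graph(g, p)
  expect_identical(gp$atoms$element, g$atoms$element[p])
  expect_identical(gp$coords, g$coords[p, ])
  expect_equal(nrow(gp$bonds), nrow(g$bonds))
  # degree sequence and spd spectrum are permutation invariants
  expect_equal(sort(gp$atoms$degree), sort(g$atoms$degree))
  expect_equal(sort(as.vector(spd_matrix(gp))), sort(as.vector(spd_matrix(g))))
})
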