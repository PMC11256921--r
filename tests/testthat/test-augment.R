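test_that("dissimilarity is an aligned RMSD with an MCS correspondence", {
  g <- generate_conformer(fix_aspirin(), seed = 1)
  expect_lt(dissimilarity(g, g), 1e-8)
  g2 <- g
  g2$coords <- rigid_transform(g$coords, seed = 3)
  expect_lt(dissimilarity(g, g2), 1e-6)
  # fewer than 3 atoms in common: no qualifying correspondence
  benz <- generate_conformer(fix_benzene(), seed = 1)
  meth <- generate_conformer(parse_smiles("C"), seed = 1)
  expect_equal(dissimilarity(benz, meth), Inf)
  expect_error(dissimilarity(parse_smiles("CCO"), g), "coordinates")
})

test_that("the Kabsch superposition agrees with an independent oracle", {
  set.seed(11)
  for (r in 1:5) {
    P <- matrix(rnorm(21), 7, 3)
    Q <- rigid_transform(P, seed = r) + matrix(rnorm(21, sd = 0.05), 7, 3)
    ours <- molembed:::.kabsch_rmsd(P, Q)
    fit <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(Q)),
                                       mobile = as.vector(t(P))))
    oracle <- sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - Q)^2)))
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("node_drop removes exactly ceiling(fraction * a) atoms, connected", {
  g10 <- generate_conformer(parse_smiles("c1ccc2ccccc2c1"), seed = 1)
  expect_equal(atom_count(g10), 10)
  nd <- node_drop(g10, fraction = 0.1, seed = 4)
  expect_equal(atom_count(nd$graph), 9)
  expect_true(igraph::is_connected(molembed:::.as_igraph(nd$graph)))
  expect_s3_class(nd, "augmentation_result")

  nd0 <- node_drop(g10, fraction = 0, seed = 4)
  expect_equal(atom_count(nd0$graph), 10)
  expect_equal(nd0$dissimilarity, 0)

  nd2 <- node_drop(g10, fraction = 0.1, seed = 4)
  expect_identical(nd$graph$smiles, nd2$graph$smiles)
  expect_identical(nd$dissimilarity, nd2$dissimilarity)

  expect_error(node_drop(parse_smiles("CC"), seed = 1), "at least 3")
})

test_that("subgraph_sample returns connected induced subsets of the input", {
  g <- generate_conformer(fix_aspirin(), seed = 2)
  sg <- subgraph_sample(g, target_fraction = 0.8, seed = 6)
  expect_lte(atom_count(sg$graph), atom_count(g))
  expect_true(igraph::is_connected(molembed:::.as_igraph(sg$graph)))
  # element multiset of the sample is a sub-multiset of the original
  expect_true(all(table(sg$graph$atoms$element) <=
                    table(g$atoms$element)[names(table(sg$graph$atoms$element))]))
  sg2 <- subgraph_sample(g, target_fraction = 0.8, seed = 6)
  expect_identical(sg$graph$smiles, sg2$graph$smiles)
  # a full-fraction walk on a tiny chain visits every atom
  chain <- generate_conformer(parse_smiles("CCC"), seed = 1)
  for (s in 1:5) {
    expect_equal(atom_count(subgraph_sample(chain, 1.0, seed = s)$graph), 3)
  }
})

test_that("chemical_transform applies catalog moves at legal sites", {
  benz <- generate_conformer(fix_benzene(), seed = 1)
  seen_toluene <- FALSE
  for (s in 1:20) {
    ct <- chemical_transform(benz, seed = s)
    expect_true(ct$graph$smiles != benz$smiles)
    expect_silent(validate_valences(ct$graph))
    if (ct$graph$smiles == parse_smiles("Cc1ccccc1")$smiles) {
      seen_toluene <- TRUE
    }
  }
  # methyl addition to benzene yields toluene (canonical-SMILES equality)
  expect_true(seen_toluene)
  ct1 <- chemical_transform(benz, seed = 3)
  ct2 <- chemical_transform(benz, seed = 3)
  expect_identical(ct1$graph$smiles, ct2$graph$smiles)
  # heavy-atom methane offers nothing to remove
  meth <- generate_conformer(parse_smiles("C"), seed = 1)
  expect_error(chemical_transform(meth, seed = 1, ops = "remove"),
               class = "molembed_augment_infeasible")
})

test_that("brics_bonds reproduces the reference decomposition bond sets", {
  # expected cleavable bonds computed with the reference BRICS
  # implementation on these exact SMILES (1-based atom indices)
  cases <- list(
    list("CC(=O)Oc1ccccc1C(=O)O", rbind(c(2, 4), c(4, 5), c(10, 11))),
    list("Cn1cnc2c1c(=O)n(C)c(=O)n2C", NULL),
    list("CC(C)Cc1ccc(cc1)C(C)C(=O)O", rbind(c(4, 5), c(8, 11))),
    list("CC(=O)Nc1ccc(O)cc1", rbind(c(2, 4), c(4, 5))),
    list("CCO", NULL),
    list("c1ccc(cc1)C(=O)OCC", rbind(c(4, 7), c(7, 9), c(9, 10))),
    list("CN1CCC[C@H]1c1cccnc1", rbind(c(6, 7))),
    list("CCN(CC)CC", rbind(c(2, 3), c(3, 4), c(3, 6))),
    list("COc1ccc(CC(C)N)cc1", rbind(c(2, 3), c(6, 7)))
  )
  for (cs in cases) {
    bb <- brics_bonds(parse_smiles(cs[[1]]))
    got <- if (nrow(bb)) unname(as.matrix(bb[order(bb$i, bb$j),
                                             c("i", "j")])) else NULL
    if (is.null(cs[[2]])) {
      expect_null(got, label = cs[[1]])
    } else {
      expect_equal(got, unname(cs[[2]]), label = cs[[1]])
    }
  }
})

test_that("substructure_remove keeps the larger connected fragment", {
  eth <- generate_conformer(parse_smiles("CC"), seed = 1)
  expect_error(substructure_remove(eth, seed = 1),
               class = "molembed_augment_infeasible")
  g <- generate_conformer(fix_aspirin(), seed = 1)
  sr <- substructure_remove(g, seed = 4)
  expect_lt(atom_count(sr$graph), atom_count(g))
  expect_gte(atom_count(sr$graph), 3)
  expect_true(igraph::is_connected(molembed:::.as_igraph(sr$graph)))
  expect_silent(validate_valences(sr$graph))
  sr2 <- substructure_remove(g, seed = 4)
  expect_identical(sr$graph$smiles, sr2$graph$smiles)
})

test_that("augment_accepted enforces the RMSD gate", {
  g <- generate_conformer(fix_aspirin(), seed = 1)
  res <- augment_accepted(g, "node_drop", seed = 12)
  if (res$accepted) expect_lt(res$dissimilarity, 3.0)
  expect_gte(res$attempts, 1)

  everything <- augment_accepted(g, "subgraph", threshold = Inf, seed = 12)
  expect_true(everything$accepted)
  expect_equal(everything$attempts, 1L)

  r1 <- augment_accepted(g, "chem_transform", seed = 8)
  r2 <- augment_accepted(g, "chem_transform", seed = 8)
  expect_identical(r1$graph$smiles, r2$graph$smiles)
  expect_identical(r1$dissimilarity, r2$dissimilarity)
})

test_that("build_augmentation_set always yields four valid, embedded views", {
  g <- generate_conformer(fix_caffeine(), seed = 1)
  aset <- build_augmentation_set(g, seed = 15)
  expect_length(aset$members, 4)
  expect_setequal(names(aset$members), paste0("G", 1:4))
  for (m in aset$members) {
    expect_s3_class(m$graph, "mol_graph")
    expect_false(is.null(m$graph$coords))
    expect_silent(validate_valences(m$graph))
    if (m$accepted) expect_lt(m$dissimilarity, 3.0)
  }
  aset2 <- build_augmentation_set(g, seed = 15)
  expect_identical(vapply(aset$members, function(m) m$graph$smiles, ""),
                   vapply(aset2$members, function(m) m$graph$smiles, ""))
  # caffeine has no BRICS bonds: the substructure slot must fall back while
  # the set stays at exactly four members
  expect_equal(nrow(brics_bonds(g)), 0)
  expect_equal(unname(vapply(aset$members, function(m) m$kind, ""))[4],
               "node_drop")
})
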