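# A two-bond chain with one single and one double bond, built directly so
# the bond feature vectors are known one-hots.
chain_sd <- function() {
  atoms <- data.frame(element = c("C", "C", "C"), charge = 0L,
                      nH = c(3L, 1L, 2L), aromatic = FALSE,
                      degree = c(1L, 2L, 1L))
  bonds <- data.frame(i = c(1L, 2L), j = c(2L, 3L), order = c(1L, 2L),
                      aromatic = FALSE, ring = FALSE,
                      conjugated = FALSE)
  mol_graph(atoms, bonds)
}

test_that("edge_encoding averages path features and applies w_edge", {
  g <- parse_smiles("CC")
  p <- encoding_params(w_edge = c(2, 0, 0, 0, 0, 0))
  m <- edge_encoding(g, p)
  expect_equal(m[1, 2], 2)
  expect_equal(m[2, 1], 2)
  expect_equal(diag(m), rep(0, 2))

  # path 1-2-3 with one single + one double bond: the element-wise average
  # of two disjoint one-hots sums to 1 under an all-ones weight
  g3 <- chain_sd()
  p1 <- encoding_params(w_edge = rep(1, 6))
  m3 <- edge_encoding(g3, p1)
  expect_equal(m3[1, 3], 1.0)
  expect_equal(m3, t(m3))
  expect_error(edge_encoding(g3, encoding_params(w_edge = rep(1, 4),
                                                 k_edge = 4)),
               "k_edge")
})

test_that("spd_encoding scales the distance matrix, sentinel included", {
  g <- parse_smiles("CCC")
  m <- spd_encoding(g, encoding_params(w_spd = 1.5))
  expect_equal(m[1, 3], 3.0)
  expect_true(all(spd_encoding(g, encoding_params(w_spd = 0)) == 0))

  atoms <- data.frame(element = c("C", "C"), charge = 0L, nH = 4L,
                      aromatic = FALSE, degree = 0L)
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                      aromatic = logical(0), ring = logical(0),
                      conjugated = logical(0))
  g2 <- mol_graph(atoms, bonds)
  expect_equal(spd_encoding(g2, encoding_params(w_spd = 1))[1, 2], 2)
})

test_that("kernel_vector implements the decay and gaussian forms", {
  p <- encoding_params(K = 8)
  expect_equal(kernel_vector(0, p), rep(1, 8))
  expect_equal(kernel_vector(p$sigmas[3], p)[3], exp(-1))
  d <- seq(0, 8, by = 0.5)
  vals <- vapply(d, function(x) kernel_vector(x, p)[1], numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(kernel_vector(2.5, p) > 0 & kernel_vector(2.5, p) <= 1))
  expect_error(kernel_vector(-1, p), ">= 0")

  pg <- encoding_params(K = 4, sigmas = rep(1, 4), kernel_form = "gaussian",
                        d_max = 6)
  kv <- kernel_vector(2, pg)
  expect_equal(kv[2], exp(-(2 - 2)^2 / 2))  # center grid 0,2,4,6
  expect_length(kv, 4)
})

test_that("distance3d_encoding matches a straight-line oracle and is rigid", {
  g <- generate_conformer(fix_aspirin(), seed = 4)
  set.seed(5)
  K <- 6
  p <- encoding_params(K = K, sigmas = exp(seq(log(0.5), log(10),
                                               length.out = K)),
                       W1 = matrix(rnorm(K * K), K), w2 = rnorm(K))
  m <- distance3d_encoding(g, p)
  # independent re-evaluation, pair by pair, composed step by step
  a <- atom_count(g)
  for (idx in list(c(1, 5), c(3, 9), c(2, 2), c(7, 13))) {
    i <- idx[1]; j <- idx[2]
    d <- sqrt(sum((g$coords[i, ] - g$coords[j, ])^2))
    psi <- exp(-d / p$sigmas)
    expect_equal(m[i, j], sum(pmax(as.numeric(psi %*% p$W1), 0) * p$w2))
  }
  expect_equal(m, t(m))

  # exact invariance under rigid motion
  for (r in 1:10) {
    g2 <- g
    g2$coords <- rigid_transform(g$coords, seed = r)
    expect_lt(max(abs(distance3d_encoding(g2, p) - m)), 1e-10)
  }

  # W1 = I, w2 = 1, d = 0 diagonal entries equal K
  p4 <- encoding_params(K = 4, sigmas = rep(1, 4))
  expect_equal(diag(distance3d_encoding(g, p4)), rep(4, a))

  expect_error(distance3d_encoding(parse_smiles("CC"), p), "coordinates")
})

test_that("combined_bias is the sum of its components and linear in weights", {
  g <- generate_conformer(fix_caffeine(), seed = 6)
  set.seed(8)
  p <- encoding_params(W1 = matrix(rnorm(64), 8), w2 = rnorm(8),
                       w_edge = rnorm(6), w_spd = rnorm(1))
  b3 <- combined_bias(g, p, "3D")
  expect_equal(unclass(b3),
               edge_encoding(g, p) + spd_encoding(g, p) +
                 distance3d_encoding(g, p))
  b2 <- combined_bias(g, p, "2D")
  expect_equal(unclass(b3) - unclass(b2), distance3d_encoding(g, p))

  p0 <- encoding_params(w_edge = rep(0, 6), w_spd = 0, w2 = rep(0, 8))
  expect_true(all(combined_bias(g, p0, "3D") == 0))

  # doubling the linear weights doubles the matrix
  p2 <- p
  p2$w_edge <- 2 * p$w_edge
  p2$w_spd <- 2 * p$w_spd
  p2$w2 <- 2 * p$w2
  expect_equal(unclass(combined_bias(g, p2, "3D")), 2 * unclass(b3))
})

test_that("every encoding matrix is symmetric and finite on random graphs", {
  set.seed(33)
  for (r in 1:12) {
    n <- sample(3:12, 1)
    g <- draw_carbon_graph(n, extra = sample(0:2, 1))
    g$coords <- matrix(rnorm(3 * n, sd = 2), n, 3)
    p <- encoding_params(w_edge = rnorm(6), w_spd = rnorm(1),
                         W1 = matrix(rnorm(64), 8), w2 = rnorm(8))
    b <- unclass(combined_bias(g, p, "3D"))
    expect_true(all(is.finite(b)))
    expect_equal(b, t(b))
  }
})
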