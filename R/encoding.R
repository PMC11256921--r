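#' Structural-encoding parameters
#'
#' Container for the learnable parameters of the three pairwise structural
#' encodings that bias the molecule encoder's attention:
#' * `w_edge` (length `k_edge`): weight vector dotted with the element-wise
#'   average of bond feature vectors along the shortest path (edge encoding);
#' * `w_spd` (scalar): weight on the shortest-path distance (SPD encoding);
#' * `sigmas` (length `K`), `W1` (`K x K`), `w2` (length `K`): kernel widths
#'   and the two-layer readout of the Gaussian-basis-kernel featurization of
#'   the 3D interatomic distance.
#'
#' `kernel_form = "decay"` evaluates kernel `k` at distance `d` (Angstrom) as
#' `exp(-d / sigma_k)`; `"gaussian"` uses `exp(-(d - mu_k)^2 / (2 sigma_k^2))`
#' with centers `mu_k` evenly spaced on `[0, d_max]`.
#'
#' @param k_edge bond feature width (default from [edge_feature_schema()]).
#' @param K number of distance kernels.
#' @param sigmas positive kernel widths; default geometric grid 0.5--10 A.
#' @param w_edge,w_spd,W1,w2 learnable weights (defaults: ones / identity).
#' @param kernel_form `"decay"` or `"gaussian"`.
#' @param d_max grid upper end for the gaussian form (Angstrom).
#' @return an object of class `encoding_params`.
#' @export
encoding_params <- function(k_edge = edge_feature_schema()$k_edge,
                            K = 8L,
                            sigmas = exp(seq(log(0.5), log(10),
                                             length.out = K)),
                            w_edge = rep(1, k_edge),
                            w_spd = 1,
                            W1 = diag(K),
                            w2 = rep(1, K),
                            kernel_form = c("decay", "gaussian"),
                            d_max = 10) {
  kernel_form <- match.arg(kernel_form)
  stopifnot(length(sigmas) == K, all(sigmas > 0),
            is.matrix(W1), all(dim(W1) == c(K, K)),
            length(w2) == K, length(w_spd) == 1)
  structure(list(w_edge = w_edge, w_spd = w_spd, K = as.integer(K),
                 sigmas = sigmas, W1 = W1, w2 = w2,
                 kernel_form = kernel_form, d_max = d_max),
            class = "encoding_params")
}

#' Edge encoding: path-averaged bond features
#'
#' Entry (i, j) is the element-wise average of the bond feature vectors along
#' the canonical shortest path between atoms i and j, dotted with `w_edge`.
#' Diagonal and unreachable pairs are 0.
#'
#' @param graph a `mol_graph`.
#' @param params an [encoding_params()].
#' @return symmetric a x a numeric matrix.
#' @export
edge_encoding <- function(graph, params) {
  if (length(params$w_edge) != ncol(graph$edge_features)) {
    stop("w_edge has length ", length(params$w_edge), " but k_edge is ",
         ncol(graph$edge_features), call. = FALSE)
  }
  a <- atom_count(graph)
  m <- matrix(0, a, a)
  if (a == 1) return(m)
  for (i in seq_len(a - 1)) {
    for (j in (i + 1):a) {
      feats <- shortest_path_edge_features(graph, i, j)
      if (length(feats) > 0) {
        avg <- Reduce(`+`, feats) / length(feats)
        m[i, j] <- m[j, i] <- sum(avg * params$w_edge)
      }
    }
  }
  m
}

#' Shortest-path-distance encoding
#'
#' `spd(i, j) * w_spd`, with the unreachable sentinel `a` included.
#'
#' @inheritParams edge_encoding
#' @return symmetric a x a numeric matrix.
#' @export
spd_encoding <- function(graph, params) {
  spd_matrix(graph) * params$w_spd
}

#' Gaussian-basis-kernel featurization of a distance
#'
#' @param d a non-negative distance in Angstrom.
#' @param params an [encoding_params()].
#' @return numeric vector of length `params$K` with entries in (0, 1].
#' @export
kernel_vector <- function(d, params) {
  if (!is.finite(d) || d < 0) stop("distance must be >= 0", call. = FALSE)
  if (params$kernel_form == "decay") {
    exp(-d / params$sigmas)
  } else {
    mu <- seq(0, params$d_max, length.out = params$K)
    exp(-(d - mu)^2 / (2 * params$sigmas^2))
  }
}

#' 3D distance encoding
#'
#' Entry (i, j) is `ReLU(psi(i, j) %*% W1) . w2` where `psi` is the
#' Gaussian-basis-kernel featurization of the Euclidean distance between
#' atoms i and j. Depends on coordinates only through pairwise distances, so
#' it is exactly invariant under rigid-body motion.
#'
#' @inheritParams edge_encoding
#' @return symmetric a x a numeric matrix.
#' @export
distance3d_encoding <- function(graph, params) {
  if (is.null(graph$coords)) {
    stop("graph has no 3D coordinates; run generate_conformer() first",
         call. = FALSE)
  }
  a <- atom_count(graph)
  dmat <- as.matrix(stats::dist(graph$coords))
  # psi for all pairs at once: rows index (i,j) pairs, columns kernels
  psi <- t(vapply(as.vector(dmat), kernel_vector, numeric(params$K),
                  params = params))
  h <- pmax(psi %*% params$W1, 0)
  matrix(h %*% params$w2, a, a)
}

#' Combined 2D/3D attention-bias matrix
#'
#' Linear combination of the pairwise structural encodings: edge + SPD
#' (+ 3D distance in `"3D"` mode). The result is added to the attention
#' logits of every head of the molecule encoder before the softmax.
#'
#' @inheritParams edge_encoding
#' @param mode `"3D"` (all three terms; requires coordinates) or `"2D"`.
#' @return a symmetric a x a matrix of class `bias_matrix`.
#' @export
combined_bias <- function(graph, params, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  m <- edge_encoding(graph, params) + spd_encoding(graph, params)
  if (mode == "3D") m <- m + distance3d_encoding(graph, params)
  structure(m, class = c("bias_matrix", class(m)))
}
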