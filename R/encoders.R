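#' Encoder configuration
#'
#' Dimensions of the molecule and text Transformer encoders. The defaults are
#' desk-scale: 2 layers, 4 heads and width 64 keep a forward pass cheap, while
#' the joint embedding width stays at 768 and text truncation at 256 tokens
#' for interface fidelity with the full-scale setting.
#'
#' @param layers number of Transformer layers.
#' @param heads attention heads; must divide `model_dim`.
#' @param model_dim hidden width of the encoders.
#' @param embed_dim width of the joint latent space (default 768).
#' @param max_tokens text truncation limit (default 256).
#' @param vocab_size size of the hashed token vocabulary.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(layers = 2L, heads = 4L, model_dim = 64L,
                           embed_dim = 768L, max_tokens = 256L,
                           vocab_size = 4096L) {
  stopifnot(model_dim %% heads == 0, embed_dim > 0, max_tokens > 0,
            layers >= 1, vocab_size >= 2)
  structure(list(layers = as.integer(layers), heads = as.integer(heads),
                 model_dim = as.integer(model_dim),
                 embed_dim = as.integer(embed_dim),
                 max_tokens = as.integer(max_tokens),
                 vocab_size = as.integer(vocab_size)),
            class = "encoder_config")
}

.ELEMENT_VOCAB <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "B",
                    "Si", "*")

.rand_mat <- function(nr, nc, scale) {
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

.init_layer <- function(d, scale) {
  list(Wq = .rand_mat(d, d, scale), Wk = .rand_mat(d, d, scale),
       Wv = .rand_mat(d, d, scale), Wo = .rand_mat(d, d, scale),
       ln1_g = rep(1, d), ln1_b = rep(0, d),
       ff_W1 = .rand_mat(d, 2 * d, scale), ff_b1 = rep(0, 2 * d),
       ff_W2 = .rand_mat(2 * d, d, scale), ff_b2 = rep(0, d),
       ln2_g = rep(1, d), ln2_b = rep(0, d))
}

#' Initialize encoder weights
#'
#' Seeded random initialization of the molecule encoder, the text encoder,
#' the two joint-space projections and the learnable structural-encoding
#' parameters. The text encoder is weight-agnostic: any list with the same
#' shapes (e.g. converted pretrained weights) can be substituted.
#'
#' @param config an [encoder_config()].
#' @param seed integer seed.
#' @param enc structural-encoding parameter template; learnable entries are
#'   re-drawn from the seed.
#' @return a weight list with components `mol`, `text`, `proj_mol`,
#'   `proj_text`, `enc`.
#' @export
init_weights <- function(config = encoder_config(), seed = 1L,
                         enc = encoding_params()) {
  .with_seed(seed, {
    d <- config$model_dim
    scale <- 1 / sqrt(d)
    enc$w_edge <- stats::rnorm(length(enc$w_edge), sd = 0.5)
    enc$w_spd <- stats::rnorm(1, sd = 0.1)
    enc$W1 <- .rand_mat(enc$K, enc$K, 1 / sqrt(enc$K))
    enc$w2 <- stats::rnorm(enc$K, sd = 0.5)
    list(
      mol = list(
        emb_element = .rand_mat(length(.ELEMENT_VOCAB), d, 1),
        emb_degree = .rand_mat(8L, d, 1),
        emb_charge = .rand_mat(5L, d, 1),
        layers = lapply(seq_len(config$layers),
                        function(i) .init_layer(d, scale))
      ),
      text = list(
        emb_token = .rand_mat(config$vocab_size, d, 1),
        emb_pos = .rand_mat(config$max_tokens, d, 0.1),
        layers = lapply(seq_len(config$layers),
                        function(i) .init_layer(d, scale))
      ),
      proj_mol = .rand_mat(d, config$embed_dim, 1 / sqrt(d)),
      proj_text = .rand_mat(d, config$embed_dim, 1 / sqrt(d)),
      enc = enc
    )
  })
}

#' Scaled dot-product attention with an additive bias
#'
#' `softmax(Q K' / sqrt(d) + bias) V`, the standard attention with the
#' combined structural encoding added to the logits before the softmax.
#'
#' @param Q,K,V query/key/value matrices with equal row counts.
#' @param bias square matrix matching the row count (e.g. a
#'   [combined_bias()]), or NULL for standard attention.
#' @return matrix shaped like `V`.
#' @export
biased_attention <- function(Q, K, V, bias = NULL) {
  n <- nrow(Q)
  if (nrow(K) != n || nrow(V) != n) {
    stop("Q, K, V must have equal row counts", call. = FALSE)
  }
  logits <- tcrossprod(Q, K) / sqrt(ncol(Q))
  if (!is.null(bias)) {
    if (!all(dim(bias) == c(n, n))) {
      stop("bias must be ", n, " x ", n, call. = FALSE)
    }
    logits <- logits + unclass(bias)
  }
  w <- exp(logits - apply(logits, 1, max))
  w <- w / rowSums(w)
  w %*% V
}

.layernorm <- function(H, g, b, eps = 1e-5) {
  mu <- rowMeans(H)
  v <- rowMeans((H - mu)^2)
  ((H - mu) / sqrt(v + eps)) * rep(g, each = nrow(H)) +
    rep(b, each = nrow(H))
}

# One pre-norm-free Transformer block: multi-head biased attention with
# residual + layernorm, then a 2-layer GELU-free (ReLU) feed-forward with
# residual + layernorm. H is n x d.
.transformer_layer <- function(H, lp, bias, heads) {
  d <- ncol(H)
  dh <- d %/% heads
  Q <- H %*% lp$Wq; K <- H %*% lp$Wk; V <- H %*% lp$Wv
  out <- matrix(0, nrow(H), d)
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    out[, idx] <- biased_attention(Q[, idx, drop = FALSE],
                                   K[, idx, drop = FALSE],
                                   V[, idx, drop = FALSE], bias)
  }
  H <- .layernorm(H + out %*% lp$Wo, lp$ln1_g, lp$ln1_b)
  ff <- pmax(H %*% lp$ff_W1 + rep(lp$ff_b1, each = nrow(H)), 0) %*%
    lp$ff_W2 + rep(lp$ff_b2, each = nrow(H))
  .layernorm(H + ff, lp$ln2_g, lp$ln2_b)
}

.run_stack <- function(H, layers, bias, heads) {
  for (lp in layers) H <- .transformer_layer(H, lp, bias, heads)
  H
}

# Atom input features: summed learned embeddings of element, degree, charge.
.atom_features <- function(graph, wmol) {
  el <- match(graph$atoms$element, .ELEMENT_VOCAB)
  el[is.na(el)] <- length(.ELEMENT_VOCAB)
  deg <- pmin(graph$atoms$degree, 7L) + 1L
  chg <- pmax(pmin(graph$atoms$charge, 2L), -2L) + 3L
  wmol$emb_element[el, , drop = FALSE] +
    wmol$emb_degree[deg, , drop = FALSE] +
    wmol$emb_charge[chg, , drop = FALSE]
}

# Forward pass returning the pooled penultimate representation alongside the
# projected joint-space embedding.
.encode_molecule_pooled <- function(graph, weights, config, mode = "3D") {
  H <- .atom_features(graph, weights$mol)
  bias <- combined_bias(graph, weights$enc, mode = mode)
  H <- .run_stack(H, weights$mol$layers, unclass(bias), config$heads)
  pooled <- colMeans(H)
  list(embedding = as.numeric(pooled %*% weights$proj_mol), pooled = pooled)
}

#' Encode a molecule into the joint latent space
#'
#' Runs the graph Transformer with the combined 2D/3D structural encoding
#' added to every attention head, mean-pools the atom representations and
#' projects to the joint space. Deterministic for fixed inputs, and invariant
#' under atom-order permutation (pooling is symmetric and all structural
#' encodings are pairwise).
#'
#' @param graph a `mol_graph` (with coordinates for `mode = "3D"`).
#' @param weights a weight list from [init_weights()].
#' @param config the [encoder_config()] the weights were built for.
#' @param mode `"3D"` (default) or `"2D"` (3D distance term omitted).
#' @return numeric embedding of length `config$embed_dim`.
#' @export
encode_molecule <- function(graph, weights, config = encoder_config(),
                            mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  .encode_molecule_pooled(graph, weights, config, mode)$embedding
}

# Whitespace/punctuation tokenizer with a deterministic polynomial hash into
# the fixed vocabulary.
.tokenize <- function(text, config) {
  tok <- strsplit(tolower(text), "[^a-z0-9.]+")[[1]]
  tok <- tok[nzchar(tok)]
  if (length(tok) == 0) stop("text contains no tokens", call. = FALSE)
  ids <- vapply(tok, function(t) {
    h <- 7
    for (b in utf8ToInt(t)) h <- (h * 131 + b) %% 1048573
    as.integer(h %% config$vocab_size) + 1L
  }, integer(1), USE.NAMES = FALSE)
  ids[seq_len(min(length(ids), config$max_tokens))]
}

.encode_text_pooled <- function(text, weights, config) {
  ids <- .tokenize(text, config)
  H <- weights$text$emb_token[ids, , drop = FALSE] +
    weights$text$emb_pos[seq_along(ids), , drop = FALSE]
  H <- .run_stack(H, weights$text$layers, NULL, config$heads)
  pooled <- colMeans(H)
  list(embedding = as.numeric(pooled %*% weights$proj_text), pooled = pooled)
}

#' Encode text into the joint latent space
#'
#' Tokenizes, truncates to `config$max_tokens` tokens, runs the text
#' Transformer, mean-pools and projects to the joint space.
#'
#' @param text a single non-empty string.
#' @inheritParams encode_molecule
#' @return numeric embedding of length `config$embed_dim`.
#' @export
encode_text <- function(text, weights, config = encoder_config()) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(trimws(text))) stop("empty text", call. = FALSE)
  .encode_text_pooled(text, weights, config)$embedding
}

#' Cosine similarity between two embeddings
#'
#' Embeddings are L2-normalized here, immediately before the similarity --
#' never inside the encoders.
#'
#' @param z1,z2 numeric vectors of equal length, neither the zero vector.
#' @return similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(z1, z2) {
  stopifnot(length(z1) == length(z2))
  sum(.unitize(z1) * .unitize(z2))
}
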