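# Text-prompted molecule editing: gradient optimization of a latent in an
# invertible generator's space, with losses computed in the joint
# molecule-text embedding space through a latent translator.

# ---------------------------------------------------------------------------
# Toy invertible generator: an affine-coupling flow over a standardized
# molecular-descriptor vector. It stands in for a full generative model so
# the editing loop can be exercised end to end; to_latent and from_latent
# are exact inverses.

#' Toy invertible descriptor-space generator
#'
#' Two affine coupling layers with alternating masks over a descriptor vector
#' of even dimension `dim`: `to_latent()` maps descriptors to the latent,
#' `from_latent()` inverts exactly.
#'
#' @param dim even descriptor dimension (default 8).
#' @param seed integer seed for the coupling parameters.
#' @return an object of class `toy_flow` with `to_latent` / `from_latent`.
#' @export
toy_flow <- function(dim = 8L, seed = 1L) {
  stopifnot(dim %% 2 == 0)
  h <- dim %/% 2
  pars <- .with_seed(seed, lapply(1:2, function(i) {
    list(Ws = .rand_mat(h, h, 0.3), bs = stats::rnorm(h, sd = 0.1),
         Wt = .rand_mat(h, h, 0.3), bt = stats::rnorm(h, sd = 0.1))
  }))
  masks <- list(seq_len(h), h + seq_len(h))
  couple <- function(x, inverse) {
    layers <- if (inverse) 2:1 else 1:2
    for (li in layers) {
      p <- pars[[li]]
      ma <- masks[[(li - 1) %% 2 + 1]]
      mb <- setdiff(seq_len(dim), ma)
      s <- tanh(x[ma] %*% p$Ws + p$bs) * 0.5
      t <- x[ma] %*% p$Wt + p$bt
      if (!inverse) {
        x[mb] <- x[mb] * exp(s) + t
      } else {
        x[mb] <- (x[mb] - t) * exp(-s)
      }
    }
    as.numeric(x)
  }
  structure(list(dim = as.integer(dim),
                 to_latent = function(x) couple(rbind(as.numeric(x)),
                                                inverse = FALSE),
                 from_latent = function(z) couple(rbind(as.numeric(z)),
                                                  inverse = TRUE)),
            class = "toy_flow")
}

#' Latent translator
#'
#' Maps a generator latent into the joint embedding space: either the
#' identity (requires matching dimensions) or a fixed, seeded 2-layer ReLU
#' MLP. Returns an object carrying `forward(v)` and `vjp(v, g)`, the
#' vector-Jacobian product used to backpropagate the editing losses to the
#' latent.
#'
#' @param latent_dim generator-latent dimension.
#' @param embed_dim joint-space dimension.
#' @param hidden hidden width of the MLP.
#' @param seed integer seed.
#' @param identity if TRUE use the identity translator.
#' @return an object of class `translator`.
#' @export
make_translator <- function(latent_dim, embed_dim, hidden = 64L, seed = 1L,
                            identity = FALSE) {
  if (identity) {
    stopifnot(latent_dim == embed_dim)
    return(structure(list(latent_dim = latent_dim, embed_dim = embed_dim,
                          forward = function(v) v,
                          vjp = function(v, g) g),
                     class = "translator"))
  }
  pars <- .with_seed(seed, list(
    W1 = .rand_mat(latent_dim, hidden, 1 / sqrt(latent_dim)),
    b1 = stats::rnorm(hidden, sd = 0.1),
    W2 = .rand_mat(hidden, embed_dim, 1 / sqrt(hidden)),
    b2 = rep(0, embed_dim)
  ))
  structure(list(
    latent_dim = as.integer(latent_dim), embed_dim = as.integer(embed_dim),
    forward = function(v) {
      h <- pmax(as.numeric(rbind(v) %*% pars$W1) + pars$b1, 0)
      as.numeric(rbind(h) %*% pars$W2) + pars$b2
    },
    vjp = function(v, g) {
      h_pre <- as.numeric(rbind(v) %*% pars$W1) + pars$b1
      gh <- as.numeric(pars$W2 %*% g) * (h_pre > 0)
      as.numeric(pars$W1 %*% gh)
    }),
    class = "translator")
}

#' Editing-optimization configuration
#'
#' @param steps gradient steps (default 600).
#' @param step_size initial step size (> 0); halved whenever a step would
#'   increase the loss, so the loss trace is non-increasing.
#' @param lambda_text weight of the prompt-alignment term (>= 0).
#' @param generator an invertible generator (e.g. [toy_flow()]), used to
#'   decode the optimized latent; optional for pure latent optimization.
#' @param translator a [make_translator()] mapping the latent to the joint
#'   space.
#' @return an object of class `edit_config`.
#' @export
edit_config <- function(steps = 600L, step_size = 0.05, lambda_text = 1,
                        generator = NULL, translator = NULL) {
  stopifnot(steps >= 1, step_size >= 0, lambda_text >= 0)
  structure(list(steps = as.integer(steps), step_size = step_size,
                 lambda_text = lambda_text, generator = generator,
                 translator = translator),
            class = "edit_config")
}

# editing loss and its gradient wrt the candidate embedding c:
# (1 - cos(c, zm)) + lambda * (1 - cos(c, zt))
.edit_loss <- function(cvec, zm_hat, zt_hat, lambda) {
  nc <- .l2norm(cvec)
  if (nc == 0) return(list(value = Inf, grad = cvec * 0))
  ch <- cvec / nc
  sm <- sum(ch * zm_hat)
  st <- sum(ch * zt_hat)
  gm <- (zm_hat - sm * ch) / nc
  gt <- (zt_hat - st * ch) / nc
  list(value = (1 - sm) + lambda * (1 - st), grad = -(gm + lambda * gt))
}

#' Optimize a generator latent against molecule and prompt embeddings
#'
#' The latent is initialized from seeded Gaussian noise; each step translates
#' it into the joint space, evaluates
#' `(1 - cos(c, z_mol)) + lambda * (1 - cos(c, z_text))` and backpropagates
#' the gradient through the translator to the latent. Steps that would
#' increase the loss halve the step size instead, so the recorded trace never
#' increases.
#'
#' @param mol_embedding,text_embedding joint-space embeddings of the molecule
#'   being edited and the prompt.
#' @param config an [edit_config()] with a translator.
#' @param seed integer seed for the latent initialization.
#' @return list with `latent`, `trace` (loss per step, length `steps + 1`),
#'   `candidate` (final joint-space embedding) and `decoded` (descriptor
#'   vector from the generator, when one is configured).
#' @export
edit_optimize <- function(mol_embedding, text_embedding, config, seed = 1L) {
  tr <- config$translator
  if (is.null(tr)) stop("config$translator is required", call. = FALSE)
  zm <- .unitize(mol_embedding, "molecule embedding")
  zt <- .unitize(text_embedding, "text embedding")
  v <- .with_seed(seed, stats::rnorm(tr$latent_dim))
  step <- config$step_size
  cur <- .edit_loss(tr$forward(v), zm, zt, config$lambda_text)
  trace <- numeric(config$steps + 1)
  trace[1] <- cur$value
  for (s in seq_len(config$steps)) {
    if (step > 0) {
      g <- tr$vjp(v, cur$grad)
      accepted <- FALSE
      for (h in 1:30) {
        v2 <- v - step * g
        nxt <- .edit_loss(tr$forward(v2), zm, zt, config$lambda_text)
        if (is.finite(nxt$value) && nxt$value <= cur$value) {
          v <- v2
          cur <- nxt
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted && !is.finite(cur$value)) {
        stop("non-finite editing loss at step ", s, call. = FALSE)
      }
    }
    trace[s + 1] <- cur$value
  }
  decoded <- if (!is.null(config$generator)) {
    config$generator$from_latent(v)
  }
  list(latent = v, trace = trace, candidate = tr$forward(v),
       decoded = decoded)
}

# standardized descriptor vector backing the toy generator (dim 8)
.descriptor_vector <- function(panel) {
  c(panel$tpsa, panel$hba, panel$hbd, panel$qed, panel$wclogp, panel$mw,
    panel$rotb, panel$arom)
}

#' Text-prompted editing benchmark
#'
#' Runs the latent-optimization editing loop on every molecule, decodes the
#' optimized latent back through the invertible generator to a descriptor
#' vector, realizes it as the nearest library molecule in standardized
#' descriptor space, and judges hits with the strict descriptor rules. A
#' decode failure is logged and counted as a non-hit, never fatal.
#'
#' @param graphs list of `mol_graph`s to edit (also the decode library).
#' @param prompt a prompt id from [editing_prompts()].
#' @param weights,config encoder weights and [encoder_config()].
#' @param edit an [edit_config()]; a toy generator and MLP translator are
#'   created when absent.
#' @param seed integer seed.
#' @param mode structural-bias mode for molecule encoding.
#' @param decode_fn optional override: `function(descriptor, index)` returning
#'   the edited `mol_graph` (used e.g. to force no-op edits in calibration).
#' @return list with `hit_ratio` (percent, 0--100), `mean_similarity`
#'   (Tanimoto), `results` (per-molecule data.frame) and `traces`.
#' @export
editing_benchmark <- function(graphs, prompt, weights,
                              config = encoder_config(),
                              edit = edit_config(), seed = 1L,
                              mode = "3D", decode_fn = NULL) {
  stopifnot(length(graphs) >= 1)
  pr <- editing_prompts()
  if (!prompt %in% pr$id) {
    stop("unknown prompt '", prompt, "'; valid: ",
         paste(pr$id, collapse = ", "), call. = FALSE)
  }
  panels <- lapply(graphs, property_panel)
  desc <- t(vapply(panels, .descriptor_vector, numeric(8)))
  mu <- colMeans(desc)
  sdv <- apply(desc, 2, stats::sd)
  sdv[sdv == 0] <- 1
  desc_std <- sweep(sweep(desc, 2, mu), 2, sdv, "/")
  if (is.null(edit$generator)) {
    edit$generator <- toy_flow(dim = 8L, seed = .child_seed(seed, "flow"))
  }
  if (is.null(edit$translator)) {
    edit$translator <- make_translator(edit$generator$dim, config$embed_dim,
                                       seed = .child_seed(seed, "tr"))
  }
  zt <- encode_text(pr$text[pr$id == prompt], weights, config)
  rows <- list()
  traces <- list()
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    zm <- encode_molecule(g, weights, config, mode)
    opt <- edit_optimize(zm, zt, edit, seed = .child_seed(seed, "edit", i))
    traces[[i]] <- opt$trace
    edited <- tryCatch({
      if (!is.null(decode_fn)) {
        decode_fn(opt$decoded, i)
      } else {
        # nearest library molecule in standardized descriptor space
        x <- (opt$decoded - mu) / sdv
        d2 <- rowSums(sweep(desc_std, 2, x)^2)
        graphs[[which.min(d2)]]
      }
    }, error = function(e) NULL)
    if (is.null(edited)) {
      rows[[i]] <- data.frame(molecule = i, hit = FALSE, similarity = NA_real_,
                              decode_failed = TRUE)
      next
    }
    ep <- property_panel(edited)
    rows[[i]] <- data.frame(
      molecule = i,
      hit = hit_judge(panels[[i]], ep, prompt),
      similarity = tanimoto_similarity(g, edited),
      decode_failed = FALSE)
  }
  results <- do.call(rbind, rows)
  list(hit_ratio = 100 * mean(results$hit),
       mean_similarity = mean(results$similarity, na.rm = TRUE),
       results = results, traces = traces, prompt = prompt)
}
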