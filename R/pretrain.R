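#' Contrastive-loss configuration
#'
#' @param tau temperature scaling the cosine similarities (> 0).
#' @param text_variants number of caption variants per molecule (1--3).
#' @param direction `"as_printed"` normalizes the cross-modal softmax over
#'   texts only (molecule-to-text); `"symmetric"` averages both directions.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(tau = 0.1, text_variants = 3L,
                        direction = c("as_printed", "symmetric")) {
  stopifnot(tau > 0, text_variants >= 1)
  structure(list(tau = tau, text_variants = as.integer(text_variants),
                 direction = match.arg(direction)),
            class = "loss_config")
}

#' Assemble a contrastive batch
#'
#' @param items list where each element has `G`, a 4 x d matrix of the four
#'   augmented-graph embeddings of one molecule, and `T`, a matrix (1--3 rows)
#'   of its text-variant embeddings.
#' @return the validated batch (class `contrastive_batch`).
#' @export
contrastive_batch <- function(items) {
  stopifnot(length(items) >= 1)
  d <- ncol(items[[1]]$G)
  for (it in items) {
    if (!is.matrix(it$G) || nrow(it$G) != 4 || ncol(it$G) != d) {
      stop("each item needs a 4 x d matrix of graph-view embeddings",
           call. = FALSE)
    }
    if (!is.matrix(it$T) || nrow(it$T) < 1 || ncol(it$T) != d) {
      stop("each item needs at least one text embedding of width d",
           call. = FALSE)
    }
    if (any(!is.finite(it$G)) || any(!is.finite(it$T))) {
      stop("non-finite embedding in batch", call. = FALSE)
    }
  }
  structure(items, class = "contrastive_batch")
}

# normalize rows, keeping norms for the backward pass
.norm_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("zero embedding in batch", call. = FALSE)
  list(hat = m / nrm, nrm = nrm)
}

# backward through row normalization: given grad wrt the unit rows, return
# grad wrt the raw rows
.norm_rows_bwd <- function(hat, nrm, ghat) {
  (ghat - hat * rowSums(ghat * hat)) / nrm
}

.zero_like_batch <- function(batch) {
  lapply(batch, function(it) list(G = matrix(0, nrow(it$G), ncol(it$G)),
                                  T = matrix(0, nrow(it$T), ncol(it$T))))
}

# Softmax cross-entropy over one similarity matrix S (N x N, true class on
# the diagonal): value and dL/dS for loss mean_i -log softmax(S[i,]/tau)[i].
.infonce <- function(S, tau) {
  N <- nrow(S)
  L <- S / tau
  mx <- apply(L, 1, max)
  lse <- mx + log(rowSums(exp(L - mx)))
  value <- mean(lse - diag(L))
  P <- exp(L - lse)
  dS <- (P - diag(N)) / (tau * N)
  list(value = value, dS = dS)
}

#' Cross-modal contrastive loss
#'
#' Temperature-scaled InfoNCE between each of a molecule's four augmented-view
#' embeddings and its text embeddings: the matched (graph, text) pair is
#' contrasted against the texts of the other molecules in the batch. The loss
#' is averaged over all (augmentation, text-variant) combinations, then over
#' the batch. Embeddings are L2-normalized internally before similarities.
#'
#' @param batch a [contrastive_batch()].
#' @param config a [loss_config()].
#' @param grad if TRUE also return analytic gradients with respect to the raw
#'   embeddings.
#' @return the scalar loss, or (with `grad`) a list `value`, `grad` where
#'   `grad` mirrors the batch structure.
#' @export
cross_modal_loss <- function(batch, config = loss_config(), grad = FALSE) {
  batch <- contrastive_batch(unclass(batch))
  N <- length(batch)
  Gn <- lapply(batch, function(it) .norm_rows(it$G))
  Tn <- lapply(batch, function(it) .norm_rows(it$T))
  n_txt <- vapply(batch, function(it) nrow(it$T), integer(1))
  Tmax <- min(config$text_variants, max(n_txt))
  combos <- expand.grid(a = 1:4, t = seq_len(Tmax))
  value <- 0
  gG <- lapply(Gn, function(x) x$hat * 0)
  gT <- lapply(Tn, function(x) x$hat * 0)
  M <- nrow(combos)
  for (ci in seq_len(M)) {
    a <- combos$a[ci]
    tv <- combos$t[ci]
    tidx <- ((tv - 1) %% n_txt) + 1L  # recycle missing variants
    Gh <- t(vapply(Gn, function(x) x$hat[a, ], numeric(ncol(batch[[1]]$G))))
    Th <- t(vapply(seq_len(N),
                   function(j) Tn[[j]]$hat[tidx[j], ],
                   numeric(ncol(batch[[1]]$G))))
    S <- tcrossprod(Gh, Th)
    parts <- list(.infonce(S, config$tau))
    if (config$direction == "symmetric") {
      parts <- c(parts, list(.infonce(t(S), config$tau)))
    }
    for (pi in seq_along(parts)) {
      p <- parts[[pi]]
      value <- value + p$value / (M * length(parts))
      if (grad) {
        dS <- if (pi == 1) p$dS else t(p$dS)
        dS <- dS / (M * length(parts))
        dGh <- dS %*% Th
        dTh <- crossprod(dS, Gh)
        for (i in seq_len(N)) {
          gG[[i]][a, ] <- gG[[i]][a, ] + dGh[i, ]
          gT[[i]][tidx[i], ] <- gT[[i]][tidx[i], ] + dTh[i, ]
        }
      }
    }
  }
  if (!grad) return(value)
  grads <- .zero_like_batch(batch)
  for (i in seq_len(N)) {
    grads[[i]]$G <- .norm_rows_bwd(Gn[[i]]$hat, Gn[[i]]$nrm, gG[[i]])
    grads[[i]]$T <- .norm_rows_bwd(Tn[[i]]$hat, Tn[[i]]$nrm, gT[[i]])
  }
  list(value = value, grad = grads)
}

#' Self-contrastive loss over augmented graph views
#'
#' For each molecule, the kernel over all 6 unordered pairs of its four
#' augmented-view embeddings (`sum exp(sim/tau)`) is contrasted against the
#' same pair-kernel evaluated between the molecule and every molecule in the
#' batch; the negative log ratio is averaged over the batch.
#'
#' @inheritParams cross_modal_loss
#' @return scalar loss, or a list with `value` and `grad` (G gradients only).
#' @export
self_contrastive_loss <- function(batch, config = loss_config(),
                                  grad = FALSE) {
  batch <- contrastive_batch(unclass(batch))
  N <- length(batch)
  Gn <- lapply(batch, function(it) .norm_rows(it$G))
  # Diagonal kernel: the sum over the 6 unordered pairs of an item's views.
  # Cross-item kernel: all 16 ordered view pairs scaled by 3/8, which matches
  # the diagonal's 6-term scale and, unlike a labelled a<b subset, is
  # invariant to relabelling either item's four views.
  pairs <- expand.grid(a = 1:4, b = 1:4)
  P <- nrow(pairs)
  tau <- config$tau
  d <- ncol(batch[[1]]$G)
  # E[i, j, p] = exp(sim(z_i^{a_p}, z_j^{b_p}) / tau)
  E <- array(0, c(N, N, P))
  for (p in seq_len(P)) {
    A <- t(vapply(Gn, function(x) x$hat[pairs$a[p], ], numeric(d)))
    B <- t(vapply(Gn, function(x) x$hat[pairs$b[p], ], numeric(d)))
    E[, , p] <- exp(tcrossprod(A, B) / tau)
  }
  off_diag <- pairs$a != pairs$b
  k <- apply(E, c(1, 2), sum) * (3 / 8)
  kd <- 0.5 * apply(E[, , off_diag, drop = FALSE], c(1, 2), sum)
  diag(k) <- diag(kd)
  D <- rowSums(k)
  value <- mean(-log(diag(k) / D))
  if (!grad) return(value)
  gG <- lapply(Gn, function(x) x$hat * 0)
  for (p in seq_len(P)) {
    a <- pairs$a[p]; b <- pairs$b[p]
    coef <- sweep(E[, , p], 1, (3 / 8) / D, `*`) / (tau * N)
    ddiag <- if (a != b) {
      E[cbind(1:N, 1:N, p)] * 0.5 * (1 / D - 1 / diag(k)) / (tau * N)
    } else {
      rep(0, N)
    }
    diag(coef) <- ddiag
    A <- t(vapply(Gn, function(x) x$hat[a, ], numeric(d)))
    B <- t(vapply(Gn, function(x) x$hat[b, ], numeric(d)))
    dA <- coef %*% B
    dB <- crossprod(coef, A)
    for (i in seq_len(N)) {
      gG[[i]][a, ] <- gG[[i]][a, ] + dA[i, ]
      gG[[i]][b, ] <- gG[[i]][b, ] + dB[i, ]
    }
  }
  grads <- .zero_like_batch(batch)
  for (i in seq_len(N)) {
    grads[[i]]$G <- .norm_rows_bwd(Gn[[i]]$hat, Gn[[i]]$nrm, gG[[i]])
    grads[[i]]$T <- NULL
  }
  list(value = value, grad = grads)
}

#' Combined pretraining loss
#'
#' Exact sum of [cross_modal_loss()] and [self_contrastive_loss()].
#'
#' @inheritParams cross_modal_loss
#' @return scalar, or list with `value` and combined `grad`.
#' @export
total_loss <- function(batch, config = loss_config(), grad = FALSE) {
  if (!grad) {
    return(cross_modal_loss(batch, config) +
             self_contrastive_loss(batch, config))
  }
  cm <- cross_modal_loss(batch, config, grad = TRUE)
  sc <- self_contrastive_loss(batch, config, grad = TRUE)
  grads <- cm$grad
  for (i in seq_along(grads)) {
    grads[[i]]$G <- grads[[i]]$G + sc$grad[[i]]$G
  }
  list(value = cm$value + sc$value, grad = grads)
}

# ---------------------------------------------------------------------------
# Pretraining loop

#' Contrastive pretraining over a molecule-text corpus
#'
#' Each molecule is expanded into its four accepted augmentations (the
#' original is never a training view), all views get seeded conformers and are
#' encoded along with the caption variants. The two joint-space projection
#' matrices are then trained by mini-batch gradient descent with momentum on
#' the combined contrastive loss; the Transformer bodies stay frozen at their
#' seeded initialization (linear-probe pretraining at desk scale).
#'
#' @param corpus a `toy_corpus` from [make_toy_corpus()], or any list of
#'   items with `graph` (a `mol_graph`) and `captions` (character).
#' @param weights encoder weights ([init_weights()]); initialized from
#'   `seed` when NULL.
#' @param config an [encoder_config()].
#' @param loss a [loss_config()].
#' @param epochs,batch_size,lr,momentum optimizer settings.
#' @param mode `"3D"` or `"2D"` structural bias.
#' @param seed integer seed driving augmentation, shuffling and (if needed)
#'   weight initialization.
#' @return a `molembed_fit`: trained weights, per-epoch and per-batch loss
#'   traces, and the configuration used.
#' @export
pretrain <- function(corpus, weights = NULL, config = encoder_config(),
                     loss = loss_config(), epochs = 30L, batch_size = 8L,
                     lr = 0.02, momentum = 0.9, mode = c("3D", "2D"),
                     seed = 1L) {
  mode <- match.arg(mode)
  items <- if (inherits(corpus, "toy_corpus")) corpus$pairs else corpus
  stopifnot(length(items) >= 1, batch_size <= length(items))
  if (is.null(weights)) {
    weights <- init_weights(config, seed = .child_seed(seed, "init"))
  }
  # fixed features: pooled reps of the four augmented views and the captions
  feats <- lapply(seq_along(items), function(i) {
    it <- items[[i]]
    aug <- build_augmentation_set(it$graph, seed = .child_seed(seed, "aug", i))
    PG <- t(vapply(aug$members, function(m) {
      .encode_molecule_pooled(m$graph, weights, config, mode)$pooled
    }, numeric(config$model_dim)))
    caps <- utils::head(it$captions, loss$text_variants)
    PT <- t(vapply(caps, function(tx) {
      .encode_text_pooled(tx, weights, config)$pooled
    }, numeric(config$model_dim)))
    list(PG = PG, PT = PT)
  })
  Wm <- weights$proj_mol
  Wt <- weights$proj_text
  Vm <- Wm * 0
  Vt <- Wt * 0
  epoch_trace <- numeric(epochs)
  batch_trace <- list()
  n <- length(items)
  for (ep in seq_len(epochs)) {
    ord <- .with_seed(.child_seed(seed, "shuffle", ep), sample.int(n))
    starts <- seq(1, n, by = batch_size)
    blosses <- numeric(0)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      if (length(idx) < 2) next  # a singleton batch carries no signal
      bitems <- lapply(idx, function(i) {
        list(G = feats[[i]]$PG %*% Wm, T = feats[[i]]$PT %*% Wt)
      })
      tl <- total_loss(contrastive_batch(bitems), loss, grad = TRUE)
      if (!is.finite(tl$value)) {
        stop("non-finite loss in epoch ", ep, ", batch starting at ", s,
             call. = FALSE)
      }
      dWm <- Wm * 0
      dWt <- Wt * 0
      for (bi in seq_along(idx)) {
        i <- idx[bi]
        dWm <- dWm + crossprod(feats[[i]]$PG, tl$grad[[bi]]$G)
        dWt <- dWt + crossprod(feats[[i]]$PT, tl$grad[[bi]]$T)
      }
      Vm <- momentum * Vm - lr * dWm
      Vt <- momentum * Vt - lr * dWt
      Wm <- Wm + Vm
      Wt <- Wt + Vt
      blosses <- c(blosses, tl$value)
    }
    epoch_trace[ep] <- mean(blosses)
    batch_trace[[ep]] <- blosses
  }
  weights$proj_mol <- Wm
  weights$proj_text <- Wt
  structure(list(weights = weights, config = config, loss = loss,
                 mode = mode, seed = seed,
                 epochs = epochs, batch_size = batch_size, lr = lr,
                 momentum = momentum,
                 epoch_trace = epoch_trace, batch_trace = batch_trace,
                 n_items = n),
            class = "molembed_fit")
}

#' @exportS3Method base::print
print.molembed_fit <- function(x, ...) {
  cat(sprintf(paste0("<molembed_fit> %d molecule-text pairs, %d epochs ",
                     "(batch %d, lr %g, %s bias)\n"),
              x$n_items, x$epochs, x$batch_size, x$lr, x$mode))
  cat(sprintf("  loss: %.4f (epoch 1) -> %.4f (epoch %d)\n",
              x$epoch_trace[1], x$epoch_trace[x$epochs], x$epochs))
  invisible(x)
}

#' Embeddings from a pretrained fit
#'
#' @param object a `molembed_fit`.
#' @param graphs optional list of `mol_graph`s to embed.
#' @param texts optional character vector to embed.
#' @param mode structural-bias mode; defaults to the fit's.
#' @param ... unused.
#' @return a list with matrices `molecules` and/or `texts` (rows =
#'   embeddings).
#' @export
predict.molembed_fit <- function(object, graphs = NULL, texts = NULL,
                                 mode = object$mode, ...) {
  out <- list()
  if (!is.null(graphs)) {
    out$molecules <- t(vapply(graphs, function(g) {
      encode_molecule(g, object$weights, object$config, mode)
    }, numeric(object$config$embed_dim)))
  }
  if (!is.null(texts)) {
    out$texts <- t(vapply(texts, function(tx) {
      encode_text(tx, object$weights, object$config)
    }, numeric(object$config$embed_dim)))
  }
  out
}
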