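# Downstream harnesses: molecular descriptors and the editing hit rules,
# cross-modal retrieval metrics, and the linear property-prediction head.

# ---------------------------------------------------------------------------
# Descriptors

# QED acceptor definitions (SMARTS) and structural-alert patterns follow the
# published desirability-function parameterization; patterns are evaluated by
# Open Babel SMARTS matching. Two disconnected-component patterns of the
# standard alert list (>= 4 fluorines; >= 3 ester groups) are evaluated as
# count thresholds since Open Babel SMARTS has no component logic.
.QED_ACCEPTOR_SMARTS <- c(
  "[oH0;X2]", "[OH1;X2;v2]", "[OH0;X2;v2]", "[OH0;X1;v2]", "[O-;X1]",
  "[SH0;X2;v2]", "[SH0;X1;v2]", "[S-;X1]", "[nH0;X2]", "[NH0;X1;v3]",
  "[$([N;+0;X3;v3]);!$(N[C,S]=O)]"
)

.QED_ADS <- list(
  MW = c(A = 2.817065973, B = 392.5754953, C = 290.7489764, D = 2.419764353,
         E = 49.22325677, F = 65.37051707, DMAX = 104.9805561),
  ALOGP = c(A = 3.172690585, B = 137.8624751, C = 2.534937431,
            D = 4.581497897, E = 0.822739154, F = 0.576295591,
            DMAX = 131.3186604),
  HBA = c(A = 2.948620388, B = 160.4605972, C = 3.615294657,
          D = 4.435986202, E = 0.290141953, F = 1.300669958,
          DMAX = 148.7763046),
  HBD = c(A = 1.618662227, B = 1010.051101, C = 0.985094388,
          D = 0.000000001, E = 0.713820843, F = 0.920922555,
          DMAX = 258.1632616),
  PSA = c(A = 1.876861559, B = 125.2232657, C = 62.90773554,
          D = 87.83366614, E = 12.01999824, F = 28.51324732,
          DMAX = 104.5686167),
  ROTB = c(A = 0.01, B = 272.4121427, C = 2.55837997, D = 1.565547684,
           E = 1.271567166, F = 2.758063707, DMAX = 105.4420403),
  AROM = c(A = 3.21778897, B = 957.7374108, C = 2.274627939,
           D = 0.000000001, E = 1.317690384, F = 0.375760881,
           DMAX = 312.337261),
  ALERTS = c(A = 0.01, B = 1199.094025, C = -0.09002883, D = 0.000000001,
             E = 0.185904477, F = 0.875193782, DMAX = 417.725314)
)

.QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

.qed_ads <- function(x, p) {
  v <- p[["A"]] + p[["B"]] /
    (1 + exp(-(x - p[["C"]] + p[["D"]] / 2) / p[["E"]])) *
    (1 - 1 / (1 + exp(-(x - p[["C"]] - p[["D"]] / 2) / p[["F"]])))
  v / p[["DMAX"]]
}

# alert SMARTS loaded lazily from inst/extdata (one pattern per line)
.alerts_cache <- new.env(parent = emptyenv())
.alert_smarts <- function() {
  if (is.null(.alerts_cache$pats)) {
    p <- system.file("extdata", "structural_alerts.smarts",
                     package = "molembed")
    if (!nzchar(p)) p <- file.path("inst", "extdata",
                                   "structural_alerts.smarts")
    pats <- readLines(p, warn = FALSE)
    .alerts_cache$pats <- pats[nzchar(pats) & !startsWith(pats, "#")]
  }
  .alerts_cache$pats
}

# number of aromatic rings: cycle rank of the aromatic-bond subgraph
.aromatic_ring_count <- function(graph) {
  ab <- graph$bonds[graph$bonds$aromatic, , drop = FALSE]
  if (nrow(ab) == 0) return(0L)
  verts <- sort(unique(c(ab$i, ab$j)))
  sub <- igraph::graph_from_data_frame(ab[, c("i", "j")], directed = FALSE,
                                       vertices = data.frame(name = verts))
  as.integer(nrow(ab) - length(verts) + igraph::components(sub)$no)
}

#' Molecular property panel
#'
#' The five descriptors driving the editing hit rules: Ertl topological polar
#' surface area (TPSA, Angstrom^2), Lipinski-style hydrogen-bond acceptor
#' (N + O) and donor (N-H/O-H heteroatom) counts, QED drug-likeness
#' (desirability-weighted geometric mean over eight sub-descriptors) and
#' Wildman-Crippen LogP.
#'
#' @param graph a valid `mol_graph`.
#' @return object of class `property_panel`: list with `tpsa`, `hba`, `hbd`,
#'   `qed`, `wclogp` (plus `mw`, `rotb`, `arom`, `alerts` used by QED).
#' @export
property_panel <- function(graph) {
  validate_valences(graph)
  block <- .graph_molblock(graph)
  ob <- .with_obmol("MOL", block, function(mol) {
    props <- ChemmineOB::prop_OB(list(mol))
    is_rotor <- .ob("OBBond_IsRotor")
    get_bond <- .ob("OBMol_GetBond")
    nb <- .ob("OBMol_NumBonds")(mol)
    rotb <- if (nb == 0) 0L else {
      sum(vapply(seq_len(nb) - 1L,
                 function(k) as.logical(is_rotor(get_bond(mol, k))),
                 logical(1)))
    }
    acc <- sum(vapply(.QED_ACCEPTOR_SMARTS, function(sm) {
      ChemmineOB::smartsSearch_OB(list(mol), sm, uniqueMatches = TRUE)
    }, numeric(1)))
    alerts <- sum(vapply(.alert_smarts(), function(sm) {
      ChemmineOB::smartsSearch_OB(list(mol), sm, uniqueMatches = TRUE) > 0
    }, logical(1)))
    nf <- sum(vapply("F", function(el) sum(graph$atoms$element == el),
                     numeric(1)))
    ester <- ChemmineOB::smartsSearch_OB(list(mol), "C(=O)O[#6]",
                                         uniqueMatches = TRUE)
    alerts <- alerts + (nf >= 4) + (ester >= 3)
    list(tpsa = props$TPSA, logp = props$logP, mw = props$MW,
         rotb = rotb, acc = acc, alerts = alerts)
  })
  is_no <- graph$atoms$element %in% c("N", "O")
  hba <- sum(is_no)
  hbd <- sum(is_no & graph$atoms$nH >= 1)
  x <- c(MW = ob$mw, ALOGP = ob$logp, HBA = ob$acc, HBD = hbd,
         PSA = ob$tpsa, ROTB = ob$rotb,
         AROM = .aromatic_ring_count(graph), ALERTS = ob$alerts)
  d <- vapply(names(x), function(nm) .qed_ads(x[[nm]], .QED_ADS[[nm]]),
              numeric(1))
  w <- .QED_WEIGHTS[names(x)]
  qed <- exp(sum(w * log(pmax(d, 1e-12))) / sum(w))
  structure(list(tpsa = ob$tpsa, hba = as.integer(hba),
                 hbd = as.integer(hbd), qed = qed, wclogp = ob$logp,
                 mw = ob$mw, rotb = as.integer(ob$rotb),
                 arom = .aromatic_ring_count(graph),
                 alerts = as.integer(ob$alerts)),
            class = "property_panel")
}

#' @exportS3Method base::print
print.property_panel <- function(x, ...) {
  cat(sprintf("TPSA %.2f A^2 | HBA %d | HBD %d | QED %.3f | WCLogP %.2f\n",
              x$tpsa, x$hba, x$hbd, x$qed, x$wclogp))
  invisible(x)
}

#' Tanimoto similarity of path-based fingerprints
#'
#' Intersection-over-union of hashed linear-path binary fingerprints (Open
#' Babel FP2, paths up to 7 atoms hashed to 1021 bits).
#'
#' @param g1,g2 valid `mol_graph`s.
#' @return similarity in `[0, 1]`; two empty fingerprints count as identical.
#' @export
tanimoto_similarity <- function(g1, g2) {
  fp <- function(g) {
    .with_obmol("MOL", .graph_molblock(g), function(mol) {
      ChemmineOB::fingerprint_OB(list(mol), "FP2")
    })
  }
  f1 <- fp(g1)
  f2 <- fp(g2)
  inter <- sum(f1 & f2)
  uni <- sum(f1 | f2)
  if (uni == 0) return(1)
  inter / uni
}

# ---------------------------------------------------------------------------
# Editing prompts and hit rules

#' The eight editing prompts
#'
#' Single-objective text prompts used by the molecule-editing harness, with
#' the calculated descriptor and direction that defines a satisfactory hit.
#'
#' @return data.frame with `id`, `text`, `descriptor`, `direction`.
#' @export
editing_prompts <- function() {
  data.frame(
    id = c("more_hba", "more_hbd", "drug_like", "not_drug_like",
           "high_permeability", "low_permeability", "soluble", "insoluble"),
    text = c("This molecule has more hydrogen bond acceptors.",
             "This molecule has more hydrogen bond donors.",
             "This molecule is like a drug.",
             "This molecule is not like a drug.",
             "This molecule has high permeability.",
             "This molecule has low permeability.",
             "This molecule is soluble in water.",
             "This molecule is insoluble in water."),
    descriptor = c("hba", "hbd", "qed", "qed", "tpsa", "tpsa", "wclogp",
                   "wclogp"),
    direction = c(1, 1, 1, -1, -1, 1, -1, 1),
    stringsAsFactors = FALSE
  )
}

#' Judge whether an edit satisfies a prompt
#'
#' Strict-inequality rules on the calculated descriptors: e.g. the
#' high-permeability prompt is hit when the edited molecule's TPSA is
#' strictly lower than the original's.
#'
#' @param original,edited [property_panel()]s.
#' @param prompt one of the ids in [editing_prompts()].
#' @return logical.
#' @export
hit_judge <- function(original, edited, prompt) {
  pr <- editing_prompts()
  row <- pr[pr$id == prompt, ]
  if (nrow(row) != 1) {
    stop("unknown prompt '", prompt, "'; valid: ",
         paste(pr$id, collapse = ", "), call. = FALSE)
  }
  delta <- edited[[row$descriptor]] - original[[row$descriptor]]
  (delta * row$direction) > 0
}

# ---------------------------------------------------------------------------
# Retrieval

#' Cross-modality retrieval evaluation
#'
#' Ranks, within seeded random batches, the candidates of the opposite
#' modality by cosine similarity: top-1 accuracy is the rate at which the
#' true partner ranks first, R@20 the rate at which it ranks in the top 20.
#'
#' @param mol_embeddings,text_embeddings matrices with one embedding per row
#'   (equal row counts).
#' @param pairing integer vector: molecule `i` is paired with text
#'   `pairing[i]` (a bijection; default identity).
#' @param batch_size candidates per batch (default 64).
#' @param n_batches number of seeded batches to average over.
#' @param seed integer seed.
#' @param direction `"M-T"` (molecule queries text) or `"T-M"`.
#' @return a `retrieval_report`: list with `top1_accuracy`, `recall_at_20`,
#'   `batch_size`, `n_batches`, `seed`, `direction`.
#' @export
retrieval_eval <- function(mol_embeddings, text_embeddings,
                           pairing = seq_len(nrow(mol_embeddings)),
                           batch_size = 64L, n_batches = 50L, seed = 1L,
                           direction = c("M-T", "T-M")) {
  direction <- match.arg(direction)
  n <- nrow(mol_embeddings)
  stopifnot(nrow(text_embeddings) == n, length(pairing) == n,
            all(sort(pairing) == seq_len(n)))
  if (batch_size > n) {
    stop("batch_size (", batch_size, ") exceeds corpus size (", n, ")",
         call. = FALSE)
  }
  norm_rows <- function(m) m / sqrt(rowSums(m^2))
  M <- norm_rows(mol_embeddings)
  Tx <- norm_rows(text_embeddings)
  hits1 <- hits20 <- 0
  total <- 0
  .with_seed(seed, {
    for (b in seq_len(n_batches)) {
      idx <- sample.int(n, batch_size)
      if (direction == "M-T") {
        S <- tcrossprod(M[idx, , drop = FALSE],
                        Tx[pairing[idx], , drop = FALSE])
      } else {
        S <- tcrossprod(Tx[pairing[idx], , drop = FALSE],
                        M[idx, , drop = FALSE])
      }
      # true partner of row r is column r by construction
      for (r in seq_len(batch_size)) {
        rank_true <- sum(S[r, ] > S[r, r]) + 1
        hits1 <- hits1 + (rank_true == 1)
        hits20 <- hits20 + (rank_true <= 20)
        total <- total + 1
      }
    }
  })
  structure(list(top1_accuracy = hits1 / total,
                 recall_at_20 = hits20 / total,
                 batch_size = as.integer(batch_size),
                 n_batches = as.integer(n_batches),
                 seed = as.integer(seed), direction = direction),
            class = "retrieval_report")
}

#' @exportS3Method base::print
print.retrieval_report <- function(x, ...) {
  cat(sprintf("retrieval %s: top-1 %.4f, R@20 %.4f (%d batches of %d)\n",
              x$direction, x$top1_accuracy, x$recall_at_20, x$n_batches,
              x$batch_size))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Property-prediction head

#' Train a linear property-prediction head
#'
#' Ridge-regularized logistic head on molecule embeddings with a seeded
#' 80/20 train/test split; reports AUROC on the held-out 20%.
#'
#' @param embeddings matrix, one embedding per row.
#' @param labels binary vector (0/1 or logical), both classes present.
#' @param seed integer seed for the split.
#' @param lambda ridge penalty.
#' @return list with `model` (glmnet fit), `auroc`, `test_idx`.
#' @export
train_property_head <- function(embeddings, labels, seed = 1L,
                                lambda = 1e-2) {
  labels <- as.integer(labels)
  stopifnot(nrow(embeddings) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("labels contain a single class; need both", call. = FALSE)
  }
  n <- length(labels)
  test_idx <- .with_seed(seed, sort(sample.int(n, max(1, round(0.2 * n)))))
  train_idx <- setdiff(seq_len(n), test_idx)
  if (length(unique(labels[train_idx])) < 2 ||
      length(unique(labels[test_idx])) < 2) {
    # re-draw stratified if the naive split degenerated
    test_idx <- .with_seed(.child_seed(seed, "strat"), {
      pos <- which(labels == 1)
      neg <- which(labels == 0)
      sort(c(sample(pos, max(1, round(0.2 * length(pos)))),
             sample(neg, max(1, round(0.2 * length(neg))))))
    })
    train_idx <- setdiff(seq_len(n), test_idx)
  }
  fit <- glmnet::glmnet(embeddings[train_idx, , drop = FALSE],
                        labels[train_idx], family = "binomial",
                        alpha = 0, lambda = lambda, standardize = FALSE)
  score <- as.numeric(stats::predict(
    fit, embeddings[test_idx, , drop = FALSE], type = "link"))
  auroc <- as.numeric(pROC::auc(
    pROC::roc(response = labels[test_idx], predictor = score,
              quiet = TRUE, direction = "<", levels = c(0, 1))))
  list(model = fit, auroc = auroc, test_idx = test_idx)
}
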