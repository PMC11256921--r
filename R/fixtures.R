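# Synthetic molecule-text corpus: small named drug-like molecules paired
# with templated captions computed from their own descriptors, so caption
# content genuinely correlates with structure.

.BUILTIN_SMILES <- c(
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  paracetamol = "CC(=O)Nc1ccc(O)cc1",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  salicylic_acid = "OC(=O)c1ccccc1O",
  benzoic_acid = "OC(=O)c1ccccc1",
  phenol = "Oc1ccccc1",
  toluene = "Cc1ccccc1",
  aniline = "Nc1ccccc1",
  benzamide = "NC(=O)c1ccccc1",
  acetanilide = "CC(=O)Nc1ccccc1",
  nicotine = "CN1CCCC1c1cccnc1",
  nicotinamide = "NC(=O)c1cccnc1",
  benzocaine = "CCOC(=O)c1ccc(N)cc1",
  methyl_benzoate = "COC(=O)c1ccccc1",
  anisole = "COc1ccccc1",
  styrene = "C=Cc1ccccc1",
  cinnamaldehyde = "O=CC=Cc1ccccc1",
  vanillin = "COc1cc(C=O)ccc1O",
  coumarin = "O=c1ccc2ccccc2o1",
  indole = "c1ccc2[nH]ccc2c1",
  quinoline = "c1ccc2ncccc2c1",
  naphthalene = "c1ccc2ccccc2c1",
  pyridine = "c1ccncc1",
  pyrimidine = "c1cncnc1",
  imidazole = "c1c[nH]cn1",
  furan = "c1ccoc1",
  thiophene = "c1ccsc1",
  chlorobenzene = "Clc1ccccc1",
  fluorobenzene = "Fc1ccccc1",
  benzaldehyde = "O=Cc1ccccc1",
  acetophenone = "CC(=O)c1ccccc1",
  benzylamine = "NCc1ccccc1",
  phenylalanine = "NC(Cc1ccccc1)C(=O)O",
  tyramine = "NCCc1ccc(O)cc1",
  dopamine = "NCCc1ccc(O)c(O)c1",
  serotonin_core = "NCCc1c[nH]c2ccccc12",
  ethyl_acetate = "CCOC(=O)C",
  diethylamine = "CCNCC",
  glycerol = "OCC(O)CO",
  lactic_acid = "CC(O)C(=O)O",
  valproic_core = "CCCC(CCC)C(=O)O"
)

#' Built-in fixture molecules
#'
#' @return named character vector of drug-like SMILES used by the toy corpus.
#' @export
builtin_smiles <- function() .BUILTIN_SMILES

.caption_templates <- function(panel, graph) {
  c(sprintf(
      "This molecule has %d hydrogen bond acceptors and %d hydrogen bond donors.",
      panel$hba, panel$hbd),
    sprintf(
      "A compound with topological polar surface area %.1f and logP %.2f.",
      panel$tpsa, panel$wclogp),
    sprintf(
      "Drug-likeness QED %.2f; the structure contains %d heavy atoms and %d aromatic rings.",
      panel$qed, atom_count(graph), panel$arom))
}

#' Generate a toy molecule-text corpus
#'
#' Samples `n` molecules from the built-in drug-like list (extending beyond
#' it, when `n` is larger, with seeded functional-group transforms of the
#' built-ins) and writes three caption variants per molecule from templates
#' filled with that molecule's computed [property_panel()] values.
#'
#' @param n number of molecule-text pairs (>= 1).
#' @param seed integer seed.
#' @param conformers attach 3D coordinates to every molecule (default TRUE).
#' @return a `toy_corpus`: list with `pairs` (each `graph`, `captions`,
#'   `smiles`) and `seed`.
#' @export
make_toy_corpus <- function(n = 32L, seed = 1L, conformers = TRUE) {
  stopifnot(n >= 1)
  base <- .BUILTIN_SMILES
  smis <- .with_seed(.child_seed(seed, "pick"), {
    if (n <= length(base)) {
      sample(base, n)
    } else {
      out <- sample(base, length(base))
      k <- 0
      while (length(out) < n) {
        k <- k + 1
        parent <- parse_smiles(base[[(k - 1) %% length(base) + 1]])
        tw <- tryCatch(
          chemical_transform(parent, seed = .child_seed(seed, "extend", k)),
          error = function(e) NULL)
        smi <- if (!is.null(tw)) tw$graph$smiles
        if (!is.null(smi) && !smi %in% out) out <- c(out, smi)
        if (k > 10 * n) break
      }
      # as a last resort wrap around (duplicates rather than failure)
      while (length(out) < n) out <- c(out, base[[length(out) %% length(base) + 1]])
      out[seq_len(n)]
    }
  })
  pairs <- lapply(seq_along(smis), function(i) {
    g <- parse_smiles(smis[[i]])
    if (conformers) g <- generate_conformer(g, seed = .child_seed(seed, "conf", i))
    panel <- property_panel(g)
    list(graph = g, captions = .caption_templates(panel, g),
         smiles = g$smiles)
  })
  structure(list(pairs = pairs, seed = as.integer(seed)),
            class = "toy_corpus")
}

#' @exportS3Method base::print
print.toy_corpus <- function(x, ...) {
  cat(sprintf("<toy_corpus> %d molecule-text pairs (seed %d)\n",
              length(x$pairs), x$seed))
  invisible(x)
}

#' Write a corpus as JSON lines
#'
#' One `{"smiles": ..., "captions": [...]}` object per line.
#'
#' @param corpus a `toy_corpus`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus$pairs, function(p) {
    jsonlite::toJSON(list(smiles = p$smiles, captions = p$captions),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines corpus
#'
#' @param path file written by [write_corpus_jsonl()] (or compatible).
#' @param conformers attach 3D coordinates (default TRUE).
#' @param seed seed for conformer generation.
#' @return a `toy_corpus`.
#' @export
read_corpus_jsonl <- function(path, conformers = TRUE, seed = 1L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  pairs <- lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[[i]])
    g <- parse_smiles(rec$smiles)
    if (conformers) g <- generate_conformer(g, seed = .child_seed(seed, "conf", i))
    list(graph = g, captions = as.character(rec$captions), smiles = g$smiles)
  })
  structure(list(pairs = pairs, seed = as.integer(seed)),
            class = "toy_corpus")
}
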