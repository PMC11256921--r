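# Internal helpers shared across modules.

# Open Babel low-level accessors live in ChemmineOB's namespace as SWIG
# wrappers; only a handful are re-exported. Resolve them lazily by name.
.ob <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (is.null(cache[[name]])) {
      cache[[name]] <- utils::getFromNamespace(name, "ChemmineOB")
    }
    cache[[name]]
  }
})

# Evaluate f(obmol) for a single molecule given as SMILES or SDF text.
.with_obmol <- function(format, input, f) {
  if (format %in% c("MOL", "SDF") && !grepl("\\$\\$\\$\\$", input)) {
    input <- paste0(input, "\n$$$$\n")  # record terminator for mol counting
    format <- "SDF"
  }
  out <- tryCatch(
    ChemmineOB::forEachMol(format, input, f),
    error = function(e) stop("failed to parse ", format, " input: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(out) < 1) stop("no molecule found in ", format, " input",
                            call. = FALSE)
  out[[1L]]
}

# Run code under a fixed RNG state without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a well-spread child seed from (seed, tag) staying below 2^31.
.child_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(tag)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

.l2norm <- function(x) sqrt(sum(x * x))

# L2-normalize, erroring on the zero vector.
.unitize <- function(x, what = "embedding") {
  n <- .l2norm(x)
  if (!is.finite(n) || n == 0) {
    stop(what, " has zero or non-finite norm", call. = FALSE)
  }
  x / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
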