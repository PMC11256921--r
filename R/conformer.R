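# Conformer backend: seeded distance-geometry embedding (ETKDG) followed by
# MMFF94 minimization, provided by RDKit through a small persistent worker
# process. The worker keeps the toolkit loaded so one conformer costs
# milliseconds; the line protocol is in inst/python/conformer_worker.py.

.conformer_state <- new.env(parent = emptyenv())

.worker_script <- function() {
  p <- system.file("python", "conformer_worker.py", package = "molembed")
  if (!nzchar(p)) {
    # during development the package may be sourced, not installed
    p <- file.path("inst", "python", "conformer_worker.py")
  }
  if (!file.exists(p)) stop("conformer worker script not found", call. = FALSE)
  normalizePath(p)
}

.start_worker <- function() {
  script <- .worker_script()
  for (try_i in 1:5) {
    port <- .with_seed(.child_seed(Sys.getpid(), "port", try_i),
                       sample(20000:64000, 1))
    system2("python", c(shQuote(script), port), wait = FALSE,
            stdout = FALSE, stderr = FALSE)
    con <- tryCatch(
      suppressWarnings(socketConnection(
        host = "127.0.0.1", port = port, server = TRUE, blocking = TRUE,
        open = "r+", timeout = 120)),
      error = function(e) NULL
    )
    if (!is.null(con)) {
      hello <- tryCatch(readLines(con, n = 1), error = function(e) "")
      if (identical(hello, "HELLO")) {
        .conformer_state$con <- con
        reg.finalizer(.conformer_state, function(e) {
          try(close(e$con), silent = TRUE)
        }, onexit = TRUE)
        return(invisible(con))
      }
      try(close(con), silent = TRUE)
    }
  }
  stop("could not start the conformer worker", call. = FALSE)
}

.worker_con <- function() {
  con <- .conformer_state$con
  if (!is.null(con) && isOpen(con)) return(con)
  .start_worker()
  .conformer_state$con
}

.worker_request <- function(line) {
  con <- .worker_con()
  ok <- tryCatch({
    writeLines(line, con)
    TRUE
  }, error = function(e) FALSE)
  ans <- if (ok) tryCatch(readLines(con, n = 1), error = function(e) character(0))
         else character(0)
  if (length(ans) != 1 || !nzchar(ans)) {
    # worker died; restart once and retry
    try(close(con), silent = TRUE)
    .conformer_state$con <- NULL
    con <- .worker_con()
    writeLines(line, con)
    ans <- readLines(con, n = 1)
  }
  ans
}

# molblock -> list(ok, attempts, coords) via the worker
.rdkit_conformer <- function(molblock, seed, max_attempts) {
  payload <- gsub("\n", "\x1e", molblock, fixed = TRUE)
  line <- paste("CONF", as.integer(seed), as.integer(max_attempts), payload,
                sep = "\t")
  jsonlite::fromJSON(.worker_request(line))
}
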