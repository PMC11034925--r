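`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Reverse complement of DNA strings
#'
#' Vectorised; preserves case and maps characters outside `ACGTNacgtn` to `N`.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", s)
    rawToChar(rev(charToRaw(comp)))
  }, character(1), USE.NAMES = FALSE)
}

# stderr logger with a package-level level option (debug < info < warn)
.log_levels <- c(debug = 1L, info = 2L, warn = 3L)

cne_log <- function(..., level = "info") {
  opt <- getOption("cnevol.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[opt]])
    message(sprintf("[cnevol %s] ", level), ...)
  invisible(NULL)
}

#' Derive a stage-specific RNG seed from a base seed
#'
#' Deterministic and kept below 2^31 so it is always a valid integer seed.
#'
#' @param seed base integer seed.
#' @param label stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483587)
}
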