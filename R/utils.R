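# internal helpers shared across modules

fa_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fa_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

fa_assert <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) fa_stop(class, msg, ...)
  invisible(TRUE)
}

# Evaluate expr with a local RNG stream; the caller's .Random.seed is
# untouched. All generator determinism flows through this.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# "a|b|c" -> c("a","b","c"); empty string -> character(0)
split_descriptors <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, "|", fixed = TRUE)[[1L]]
}

join_descriptors <- function(x) paste(x, collapse = "|")

#' Path to a packaged example data file
#'
#' Convenience wrapper around [system.file()] for the plain-text fixtures
#' shipped under `extdata/`: the reference indicator schema, category
#' profiles, plausibility mask, aggregation rules, reference typology and a
#' synthetic case-study table.
#'
#' @param file File name within `extdata/`; with no argument, lists the
#'   available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' fa_example()
#' fa_example("indicator_schema.csv")
#' @export
fa_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "forestarch")))
  }
  path <- system.file("extdata", file, package = "forestarch")
  fa_assert(nzchar(path), "fa_io_error", "no packaged file '%s'", file)
  path
}
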