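#' Set-overlap matching of two descriptor sets
#'
#' Two components match under the "or" rule when at least one descriptor is
#' shared, i.e. their sets intersect: `{2,3}` matches `{3}`. Matching is
#' exact-token equality — no partial or fuzzy matching.
#'
#' @param a,b Non-empty character vectors of descriptor tokens.
#' @return `TRUE` if the sets intersect, else `FALSE`.
#' @examples
#' component_match(c("2", "3"), "3")  # TRUE
#' component_match("1", "2")          # FALSE
#' @export
component_match <- function(a, b) {
  fa_assert(is.character(a) && length(a) >= 1L &&
              is.character(b) && length(b) >= 1L,
            "fa_precondition_error",
            "component_match requires two non-empty descriptor sets")
  any(a %in% b)
}

#' Generalized Hamming distance between two category profiles
#'
#' The distance is the proportion of the K components whose descriptor sets
#' fail to intersect: 0 means every component pair shares a descriptor, 1
#' means none does. With singleton sets this reduces to the classical
#' Hamming distance. The mismatch count is kept alongside the normalized
#' value so downstream tier comparisons are exact integer comparisons, free
#' of floating-point ties.
#'
#' With multi-descriptor components the measure is not a metric: the
#' triangle inequality can fail (e.g. `{1}` vs `{1,2}` vs `{2}`), and no
#' code in this package relies on metric axioms.
#'
#' @param p,q [fa_profile()] objects conforming to `schema` (same K, same
#'   indicator order — enforced at construction).
#' @param schema The shared [fa_schema()].
#' @return An object of class `fa_distance`: list with `value` (numeric in
#'   \[0,1\]), `mismatches` (integer count), `K`, and `mismatched_components`
#'   (indicator ids where the sets are disjoint, for provenance).
#' @examples
#' sch <- gen_schema(synth_config(K = 5, vocab_size = 4, seed = 1))
#' ids <- sch$indicators$id
#' mk <- function(v) fa_profile("naturalness", "x",
#'   stats::setNames(as.list(as.character(v)), ids), sch)
#' # classical worked example: [1,2,1,0,3] vs [1,2,2,0,3] -> 0.2
#' sch2 <- fa_schema(
#'   data.frame(id = paste0("i", 1:5), name = paste0("i", 1:5),
#'              group = "structural"),
#'   stats::setNames(rep(list(as.character(0:3)), 5), paste0("i", 1:5)))
#' a <- fa_profile("naturalness", "A",
#'   stats::setNames(as.list(c("1", "2", "1", "0", "3")), paste0("i", 1:5)), sch2)
#' b <- fa_profile("management", "B",
#'   stats::setNames(as.list(c("1", "2", "2", "0", "3")), paste0("i", 1:5)), sch2)
#' hamming_distance(a, b, sch2)$value  # 0.2
#' @export
hamming_distance <- function(p, q, schema) {
  check_conformance(p, q, schema)
  ids <- schema_ids(schema)
  hit <- vapply(ids, function(id)
    component_match(p$components[[id]], q$components[[id]]), logical(1))
  mism <- ids[!hit]
  structure(list(value = length(mism) / schema$K,
                 mismatches = length(mism),
                 K = schema$K,
                 mismatched_components = mism),
            class = "fa_distance")
}

#' @export
print.fa_distance <- function(x, ...) {
  cat(sprintf("Hamming distance %d/%d = %.4g\n", x$mismatches, x$K, x$value))
  if (x$mismatches > 0L)
    cat("  mismatched:", paste(x$mismatched_components, collapse = ", "), "\n")
  invisible(x)
}

check_conformance <- function(p, q, schema) {
  fa_assert(inherits(p, "fa_profile") && inherits(q, "fa_profile"),
            "fa_precondition_error", "both arguments must be fa_profile")
  fa_assert(p$K == schema$K && q$K == schema$K &&
              identical(names(p$components), schema_ids(schema)) &&
              identical(names(q$components), schema_ids(schema)),
            "fa_precondition_error",
            "profiles '%s' and '%s' do not conform to the same schema (K = %d)",
            p$code, q$code, schema$K)
  invisible(TRUE)
}

#' Brute-force distance oracle
#'
#' Computes the same quantity as [hamming_distance()] by the most naive
#' route possible — an explicit double loop over every descriptor pair of
#' every component — and is deliberately kept independent of the main
#' implementation. Used in tests as the reference the fast path is checked
#' against; not intended for analysis code.
#'
#' @inheritParams hamming_distance
#' @return A single numeric distance in \[0,1\].
#' @export
oracle_distance <- function(p, q, schema) {
  check_conformance(p, q, schema)
  mismatches <- 0L
  for (id in schema_ids(schema)) {
    a <- p$components[[id]]
    b <- q$components[[id]]
    found <- FALSE
    for (x in a) {
      for (y in b) {
        if (identical(x, y)) found <- TRUE
      }
    }
    if (!found) mismatches <- mismatches + 1L
  }
  mismatches / schema$K
}
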