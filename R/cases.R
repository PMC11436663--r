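#' Read or write case-study tables
#'
#' Case studies are literature-derived forest stands, each labelled with a
#' naturalness level and a management approach. The CSV has columns
#' `id,source,naturalness_code,management_code,notes`.
#'
#' @param path CSV file path.
#' @param cases A data frame of cases (for writing).
#' @return A data frame with the five columns above.
#' @export
read_cases <- function(path) {
  fa_assert(file.exists(path), "fa_io_error", "case file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  need <- c("id", "source", "naturalness_code", "management_code", "notes")
  fa_assert(all(need %in% names(df)), "fa_validation_error",
            "case file %s needs columns %s", path, paste(need, collapse = ","))
  fa_assert(!anyDuplicated(df$id), "fa_validation_error",
            "duplicate case id(s): %s",
            paste(df$id[duplicated(df$id)], collapse = ", "))
  df[, need]
}

#' @rdname read_cases
#' @export
write_cases <- function(cases, path) {
  utils::write.csv(cases, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Assign a case study to an archetype
#'
#' A case belongs to the unique archetype whose member cells contain its
#' (naturalness, management) pair; since cells are disjoint across
#' archetypes, uniqueness is structural. A case whose cell lies in no
#' archetype is unassigned (`NA`), never silently forced into the nearest
#' one.
#'
#' @param naturalness_code,management_code The case's category labels.
#' @param typology An [fa_typology()].
#' @param codes Optional list with `naturalness` and `management` vectors of
#'   valid codes; if given, unknown labels raise a validation error.
#' @return The archetype id (character) or `NA_character_` if unassigned.
#' @examples
#' ref <- read_typology(fa_example("typology_reference.json"))
#' assign_case("p3", "high", ref)      # "G"
#' assign_case("n4", "passive", ref)   # "B"
#' assign_case("n4", "intensive", ref) # NA: no archetype owns that cell
#' @export
assign_case <- function(naturalness_code, management_code, typology,
                        codes = NULL) {
  if (!is.null(codes)) {
    fa_assert(naturalness_code %in% codes$naturalness, "fa_validation_error",
              "unknown naturalness code '%s'", naturalness_code)
    fa_assert(management_code %in% codes$management, "fa_validation_error",
              "unknown management code '%s'", management_code)
  }
  cells <- typology_cells(typology)
  hit <- cells$archetype[cells$naturalness == naturalness_code &
                           cells$management == management_code]
  if (length(hit) == 0L) NA_character_ else hit[[1L]]
}

#' Coverage of a case-study set by a typology
#'
#' Partitions cases into assigned and unassigned, tallies cases per
#' archetype, and reports each archetype's breadth (number of distinct
#' management approaches among its member cells). When a distance matrix is
#' supplied, each unassigned case additionally gets an advisory nearest
#' archetype: the archetype whose member cells in the case's naturalness row
#' have the smallest distance (ties broken by archetype order; `NA` if no
#' archetype has a cell in that row). The advisory never changes
#' assigned/unassigned status.
#'
#' @param cases Data frame as returned by [read_cases()].
#' @param typology An [fa_typology()].
#' @param matrix Optional `fa_distmat` for nearest-archetype advisories.
#' @return A list of class `fa_coverage`: `n_total`, `n_assigned`,
#'   `n_unassigned`, `per_archetype` (data frame with `archetype`,
#'   `n_cases`, `breadth`), `assignments` (per-case data frame), and
#'   `unassigned` (subset with advisory column `nearest`).
#' @export
coverage <- function(cases, typology, matrix = NULL) {
  per <- data.frame(
    archetype = names(typology),
    n_cases = 0L,
    breadth = vapply(typology, function(a)
      length(unique(a$cells$management)), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(cases) == 0L) {
    return(structure(list(n_total = 0L, n_assigned = 0L, n_unassigned = 0L,
                          per_archetype = per,
                          assignments = cbind(cases,
                                              archetype = character(0)),
                          unassigned = cbind(cases,
                                             nearest = character(0))),
                     class = "fa_coverage"))
  }
  arch <- vapply(seq_len(nrow(cases)), function(i)
    assign_case(cases$naturalness_code[i], cases$management_code[i],
                typology), character(1))
  assignments <- cbind(cases, archetype = arch, stringsAsFactors = FALSE)
  tab <- table(arch[!is.na(arch)])
  per$n_cases <- as.integer(ifelse(per$archetype %in% names(tab),
                                   tab[per$archetype], 0L))
  un <- assignments[is.na(assignments$archetype), , drop = FALSE]
  un$nearest <- rep(NA_character_, nrow(un))
  if (!is.null(matrix) && nrow(un) > 0L) {
    for (i in seq_len(nrow(un))) {
      un$nearest[i] <- nearest_archetype(un$naturalness_code[i], typology,
                                         matrix)
    }
  }
  un$archetype <- NULL
  structure(list(n_total = nrow(cases),
                 n_assigned = sum(!is.na(arch)),
                 n_unassigned = sum(is.na(arch)),
                 per_archetype = per,
                 assignments = assignments,
                 unassigned = un),
            class = "fa_coverage")
}

# advisory only: archetype with the smallest distance among its member cells
# in the case's naturalness row
nearest_archetype <- function(naturalness_code, typology, matrix) {
  if (!naturalness_code %in% matrix$rows) return(NA_character_)
  best_id <- NA_character_
  best <- Inf
  for (a in typology) {
    in_row <- a$cells[a$cells$naturalness == naturalness_code, , drop = FALSE]
    if (nrow(in_row) == 0L) next
    d <- min(matrix$counts[naturalness_code, in_row$management])
    if (d < best) {
      best <- d
      best_id <- a$id
    }
  }
  best_id
}

#' @export
print.fa_coverage <- function(x, ...) {
  cat(sprintf("Coverage: %d cases, %d assigned, %d unassigned\n",
              x$n_total, x$n_assigned, x$n_unassigned))
  print(x$per_archetype, row.names = FALSE)
  if (nrow(x$unassigned) > 0L) {
    cat("Unassigned cases (cell, advisory nearest archetype):\n")
    print(x$unassigned[, c("id", "naturalness_code", "management_code",
                           "nearest")], row.names = FALSE)
  }
  invisible(x)
}

#' @rdname coverage
#' @param report An `fa_coverage`.
#' @param path JSON output path.
#' @export
write_coverage <- function(report, path) {
  jsonlite::write_json(
    list(n_total = report$n_total,
         n_assigned = report$n_assigned,
         n_unassigned = report$n_unassigned,
         per_archetype = report$per_archetype,
         assignments = report$assignments,
         unassigned = report$unassigned),
    path, auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  invisible(path)
}
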