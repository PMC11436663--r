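#' Indicator schemas
#'
#' An indicator schema is the ordered list of forest indicators over which
#' every category profile is expressed. Each indicator has a short `id`, a
#' human-readable `name`, a `group` placing it among the four indicator
#' classes (structural, functional, compositional, human_impact), and a
#' non-empty `vocabulary` of descriptor tokens. The number of indicators,
#' `K`, is the dimensionality of all profiles compared under the schema; the
#' reference configuration shipped with the package has K = 19. Indicator
#' order is canonical: profiles are stored keyed by indicator id and
#' re-ordered to schema order on load, so file row order never changes a
#' distance.
#'
#' Descriptor tokens are opaque, case-sensitive strings; the package attaches
#' no semantics beyond equality, and in particular no ordering. A literal
#' `"NA"` token may be placed in a vocabulary if wildcard-like behaviour is
#' wanted; it matches only itself.
#'
#' @param indicators A data frame with columns `id`, `name`, `group`.
#' @param vocabulary A named list (by indicator id) of character vectors of
#'   allowed descriptor tokens.
#' @return An object of class `fa_schema` with elements `indicators`
#'   (data frame), `vocabulary` (named list) and `K` (integer).
#' @seealso [read_schema()], [fa_profile()]
#' @export
fa_schema <- function(indicators, vocabulary) {
  fa_assert(is.data.frame(indicators) &&
              all(c("id", "name", "group") %in% names(indicators)),
            "fa_schema_error",
            "indicators must be a data frame with id, name, group columns")
  indicators <- as.data.frame(indicators, stringsAsFactors = FALSE)
  ids <- as.character(indicators$id)
  fa_assert(nrow(indicators) >= 1L, "fa_schema_error",
            "a schema needs at least one indicator")
  dup <- ids[duplicated(ids)]
  fa_assert(length(dup) == 0L, "fa_schema_error",
            "duplicate indicator id in schema: %s",
            paste(unique(dup), collapse = ", "))
  bad_group <- setdiff(unique(indicators$group), fa_indicator_groups)
  fa_assert(length(bad_group) == 0L, "fa_schema_error",
            "unknown indicator group(s): %s (allowed: %s)",
            paste(bad_group, collapse = ", "),
            paste(fa_indicator_groups, collapse = ", "))
  fa_assert(is.list(vocabulary) && setequal(names(vocabulary), ids),
            "fa_schema_error", "vocabulary must be a list named by indicator id")
  for (id in ids) {
    v <- vocabulary[[id]]
    fa_assert(is.character(v) && length(v) >= 1L && all(nzchar(v)),
              "fa_schema_error",
              "indicator '%s' has an empty vocabulary", id)
    fa_assert(!anyDuplicated(v), "fa_schema_error",
              "indicator '%s' repeats a vocabulary token", id)
  }
  structure(list(indicators = indicators[, c("id", "name", "group")],
                 vocabulary = vocabulary[ids],
                 K = nrow(indicators)),
            class = "fa_schema")
}

#' @rdname fa_schema
#' @format NULL
#' @export
fa_indicator_groups <- c("structural", "functional", "compositional",
                         "human_impact")

#' @export
print.fa_schema <- function(x, ...) {
  cat(sprintf("Indicator schema: K = %d indicators\n", x$K))
  tab <- table(factor(x$indicators$group, levels = fa_indicator_groups))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

schema_ids <- function(schema) schema$indicators$id

#' Read or write an indicator schema
#'
#' The schema file is UTF-8 CSV with one row per indicator and columns
#' `id,name,group,vocabulary`; multi-token vocabularies are `|`-separated.
#' Row order in the file is the canonical indicator order.
#'
#' @param path Path to a schema CSV file.
#' @param schema An `fa_schema` (for writing).
#' @return `read_schema()` returns an [fa_schema()]; `write_schema()` returns
#'   `path` invisibly. Reading then writing then reading is an identity.
#' @examples
#' sch <- read_schema(fa_example("indicator_schema.csv"))
#' sch$K  # 19 in the reference configuration
#' @export
read_schema <- function(path) {
  fa_assert(file.exists(path), "fa_io_error", "schema file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  fa_assert(all(c("id", "name", "group", "vocabulary") %in% names(df)),
            "fa_schema_error",
            "schema file %s must have columns id,name,group,vocabulary", path)
  vocab <- lapply(df$vocabulary, split_descriptors)
  names(vocab) <- df$id
  fa_schema(df[, c("id", "name", "group")], vocab)
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  fa_assert(inherits(schema, "fa_schema"), "fa_schema_error",
            "not an fa_schema")
  df <- schema$indicators
  df$vocabulary <- vapply(schema$vocabulary, join_descriptors, character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Category profiles
#'
#' A category profile encodes one category of forest naturalness (codes
#' `n7`..`n1`, `p4`..`p1`, most to least natural) or of forest management
#' intensity (`passive`, `low`, `medium`, `high`, `intensive`) as a vector of
#' K descriptor sets aligned with an indicator schema. Every component is a
#' non-empty set of tokens drawn from the owning indicator's vocabulary:
#' components with several descriptors mean the category is compatible with
#' any of them, and two components match when their sets intersect.
#'
#' @param axis `"naturalness"` or `"management"`.
#' @param code Category code, unique within its axis.
#' @param components Named list (by indicator id) of non-empty character
#'   vectors; names must cover the schema's indicators exactly, in any order.
#' @param schema The [fa_schema()] the profile conforms to.
#' @param scale Optional spatial-scale metadata (e.g. `"stand"`,
#'   `"landscape,stand"`); carried through but never used in computation.
#' @return An object of class `fa_profile`.
#' @export
fa_profile <- function(axis, code, components, schema, scale = NA_character_) {
  fa_assert(axis %in% c("naturalness", "management"), "fa_validation_error",
            "axis must be 'naturalness' or 'management', got '%s'", axis)
  fa_assert(inherits(schema, "fa_schema"), "fa_validation_error",
            "schema must be an fa_schema")
  ids <- schema_ids(schema)
  fa_assert(is.list(components) && !is.null(names(components)),
            "fa_validation_error",
            "profile '%s': components must be a named list", code)
  missing <- setdiff(ids, names(components))
  extra <- setdiff(names(components), ids)
  fa_assert(length(missing) == 0L && length(extra) == 0L,
            "fa_validation_error",
            "profile '%s' has %d components but schema has K = %d (missing: %s; unknown: %s)",
            code, length(components), schema$K,
            paste(missing, collapse = ","), paste(extra, collapse = ","))
  components <- components[ids]   # canonical schema order
  for (id in ids) {
    d <- components[[id]]
    fa_assert(is.character(d) && length(d) >= 1L && all(nzchar(d)),
              "fa_validation_error",
              "profile '%s': indicator '%s' has an empty descriptor set (each indicator needs at least one descriptor)",
              code, id)
    unknown <- setdiff(d, schema$vocabulary[[id]])
    fa_assert(length(unknown) == 0L, "fa_validation_error",
              "profile '%s': descriptor(s) %s not in vocabulary of indicator '%s'",
              code, paste(sQuote(unknown), collapse = ", "), id)
  }
  structure(list(axis = axis, code = code, components = components,
                 scale = scale, K = schema$K),
            class = "fa_profile")
}

#' @export
print.fa_profile <- function(x, ...) {
  cat(sprintf("Category profile '%s' (%s axis), %d components\n",
              x$code, x$axis, x$K))
  invisible(x)
}

#' Read or write category profiles
#'
#' Profile files are UTF-8 CSV with one row per indicator-within-category and
#' columns `axis,code,indicator_id,descriptors` (plus an optional `scale`
#' column of per-category metadata); multi-descriptor cells are
#' `|`-separated. Rows are grouped by category code and re-ordered to schema
#' indicator order, so row order in the file is irrelevant. Each category
#' must cover every schema indicator exactly once with a non-empty
#' descriptor set; violations raise a validation error naming the category
#' and indicator.
#'
#' @param path CSV file path.
#' @param schema The [fa_schema()] the profiles must conform to.
#' @param profiles A list of [fa_profile()] (for writing).
#' @return `read_profiles()` returns a named list of [fa_profile()] in order
#'   of first appearance in the file.
#' @examples
#' sch <- read_schema(fa_example("indicator_schema.csv"))
#' nat <- read_profiles(fa_example("naturalness_profiles.csv"), sch)
#' length(nat)  # 11 naturalness levels
#' @export
read_profiles <- function(path, schema) {
  fa_assert(file.exists(path), "fa_io_error",
            "profile file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  fa_assert(all(c("axis", "code", "indicator_id", "descriptors") %in% names(df)),
            "fa_validation_error",
            "profile file %s needs columns axis,code,indicator_id,descriptors",
            path)
  codes <- unique(df$code)
  out <- vector("list", length(codes))
  names(out) <- codes
  for (code in codes) {
    rows <- df[df$code == code, , drop = FALSE]
    axis <- unique(rows$axis)
    fa_assert(length(axis) == 1L, "fa_validation_error",
              "category '%s' appears under more than one axis", code)
    dup <- rows$indicator_id[duplicated(rows$indicator_id)]
    fa_assert(length(dup) == 0L, "fa_validation_error",
              "category '%s' repeats indicator(s): %s", code,
              paste(unique(dup), collapse = ", "))
    comps <- lapply(rows$descriptors, split_descriptors)
    names(comps) <- rows$indicator_id
    scale <- if ("scale" %in% names(rows)) rows$scale[1L] else NA_character_
    out[[code]] <- fa_profile(axis, code, comps, schema, scale = scale)
  }
  out
}

#' @rdname read_profiles
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(axis = p$axis, code = p$code,
               indicator_id = names(p$components),
               descriptors = vapply(p$components, join_descriptors,
                                    character(1)),
               scale = p$scale, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Plausibility constraint masks
#'
#' The mask encodes the expert judgment of which (naturalness, management)
#' pairings are admissible at all: delineation only ever selects cells the
#' mask allows. It is data, not code — the packaged mask is a transcription
#' of the reference typology's plausibility reasoning, and users can supply
#' their own. The mask must define every pair in the cross-product and allow
#' at least one cell per naturalness row.
#'
#' @param allowed Named list: for each naturalness code, the character vector
#'   of allowed management codes.
#' @param rows Ordered naturalness codes.
#' @param cols Ordered management codes.
#' @return An object of class `fa_mask`: a logical `rows` x `cols` matrix.
#' @export
fa_mask <- function(allowed, rows, cols) {
  fa_assert(setequal(names(allowed), rows), "fa_validation_error",
            "mask must define every naturalness row exactly once")
  m <- matrix(FALSE, length(rows), length(cols), dimnames = list(rows, cols))
  for (r in rows) {
    a <- allowed[[r]]
    unknown <- setdiff(a, cols)
    fa_assert(length(unknown) == 0L, "fa_validation_error",
              "mask row '%s' allows unknown management code(s): %s", r,
              paste(unknown, collapse = ", "))
    fa_assert(length(a) >= 1L, "fa_validation_error",
              "mask row '%s' allows no management category", r)
    m[r, a] <- TRUE
  }
  class(m) <- c("fa_mask", class(m))
  m
}

#' @rdname fa_mask
#' @param ... Unused.
#' @export
fa_mask_all <- function(rows, cols, ...) {
  fa_mask(stats::setNames(rep(list(cols), length(rows)), rows), rows, cols)
}

#' @rdname fa_mask
#' @param path JSON file with fields `rows`, `cols`, `allowed` (an object
#'   mapping each naturalness code to its admissible management codes).
#' @export
read_mask <- function(path) {
  fa_assert(file.exists(path), "fa_io_error", "mask file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fa_assert(all(c("rows", "cols", "allowed") %in% names(j)),
            "fa_validation_error",
            "mask file %s needs fields rows, cols, allowed", path)
  allowed <- lapply(j$allowed, as.character)
  fa_mask(allowed, as.character(j$rows), as.character(j$cols))
}

#' @rdname fa_mask
#' @param mask An `fa_mask` (for writing).
#' @export
write_mask <- function(mask, path) {
  rows <- rownames(mask)
  cols <- colnames(mask)
  allowed <- lapply(stats::setNames(rows, rows),
                    function(r) cols[mask[r, ]])
  jsonlite::write_json(list(rows = rows, cols = cols, allowed = allowed),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Aggregation rules
#'
#' An aggregation rule fuses the per-row selections of several naturalness
#' levels into a single archetype; the reference configuration fuses the
#' primary-forest levels n5, n6 and n7 into archetype A. Each naturalness
#' code may appear in at most one rule.
#'
#' @param rules A list of lists with fields `merged_codes` (character) and
#'   `target_archetype_id` (single token).
#' @param naturalness_codes Optional vector of valid codes to validate
#'   against.
#' @return The validated list of rules, class `fa_aggregation`.
#' @export
fa_aggregation <- function(rules, naturalness_codes = NULL) {
  fa_assert(is.list(rules), "fa_validation_error",
            "aggregation rules must be a list")
  seen <- character(0)
  for (r in rules) {
    fa_assert(is.list(r) && all(c("merged_codes", "target_archetype_id")
                                %in% names(r)),
              "fa_validation_error",
              "each rule needs merged_codes and target_archetype_id")
    fa_assert(length(r$merged_codes) >= 1L, "fa_validation_error",
              "rule '%s' merges no codes", r$target_archetype_id)
    clash <- intersect(r$merged_codes, seen)
    fa_assert(length(clash) == 0L, "fa_validation_error",
              "naturalness code(s) %s appear in more than one aggregation rule",
              paste(clash, collapse = ", "))
    seen <- c(seen, r$merged_codes)
    if (!is.null(naturalness_codes)) {
      unknown <- setdiff(r$merged_codes, naturalness_codes)
      fa_assert(length(unknown) == 0L, "fa_validation_error",
                "aggregation rule references unknown naturalness code(s): %s",
                paste(unknown, collapse = ", "))
    }
  }
  structure(rules, class = "fa_aggregation")
}

#' @rdname fa_aggregation
#' @param path JSON file holding an array of rule objects.
#' @export
read_aggregation <- function(path, naturalness_codes = NULL) {
  fa_assert(file.exists(path), "fa_io_error",
            "aggregation file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(j, function(r)
    list(merged_codes = as.character(unlist(r$merged_codes)),
         target_archetype_id = as.character(r$target_archetype_id)))
  fa_aggregation(rules, naturalness_codes)
}

#' Archetype typologies
#'
#' A typology is a list of named archetypes, each owning a set of
#' (naturalness, management) cells. Cells are pairwise disjoint across
#' archetypes, so any (naturalness, management) pair belongs to at most one
#' archetype. The packaged reference typology has nine archetypes A–I
#' covering all 11 naturalness levels.
#'
#' @param archetypes List of lists with fields `id`, `label`, and `cells` (a
#'   data frame with columns `naturalness`, `management`).
#' @return An object of class `fa_typology`.
#' @seealso [delineate()], [compare_typologies()], [assign_case()]
#' @export
fa_typology <- function(archetypes) {
  fa_assert(is.list(archetypes) && length(archetypes) >= 1L,
            "fa_validation_error",
            "a typology needs at least one archetype (empty list covers no naturalness level)")
  ids <- vapply(archetypes, function(a) as.character(a$id), character(1))
  dup <- ids[duplicated(ids)]
  fa_assert(length(dup) == 0L, "fa_validation_error",
            "duplicate archetype id(s): %s", paste(unique(dup), collapse = ", "))
  all_cells <- character(0)
  archetypes <- lapply(archetypes, function(a) {
    cells <- as.data.frame(a$cells, stringsAsFactors = FALSE)
    fa_assert(all(c("naturalness", "management") %in% names(cells)) &&
                nrow(cells) >= 1L,
              "fa_validation_error",
              "archetype '%s' needs a non-empty cells table with naturalness and management columns",
              a$id)
    cells <- cells[order(cells$naturalness, cells$management), ,
                   drop = FALSE]
    rownames(cells) <- NULL
    list(id = as.character(a$id),
         label = if (is.null(a$label)) "" else as.character(a$label),
         cells = cells[, c("naturalness", "management")])
  })
  for (a in archetypes) {
    key <- paste(a$cells$naturalness, a$cells$management, sep = "\r")
    fa_assert(!anyDuplicated(key), "fa_validation_error",
              "archetype '%s' repeats a cell", a$id)
    clash <- intersect(key, all_cells)
    fa_assert(length(clash) == 0L, "fa_validation_error",
              "cell(s) %s belong to more than one archetype",
              paste(gsub("\r", "/", clash), collapse = ", "))
    all_cells <- c(all_cells, key)
  }
  names(archetypes) <- vapply(archetypes, `[[`, character(1), "id")
  structure(archetypes, class = "fa_typology")
}

#' @export
print.fa_typology <- function(x, ...) {
  cat(sprintf("Typology with %d archetypes:\n", length(x)))
  for (a in x) {
    cells <- paste(sprintf("(%s,%s)", a$cells$naturalness,
                           a$cells$management), collapse = " ")
    cat(sprintf("  %s %s: %s\n", a$id,
                if (nzchar(a$label)) sprintf("[%s]", a$label) else "", cells))
  }
  invisible(x)
}

# all cells of a typology as one data frame (archetype id attached)
typology_cells <- function(t) {
  do.call(rbind, lapply(t, function(a)
    cbind(a$cells, archetype = a$id, stringsAsFactors = FALSE)))
}

#' Read or write a typology
#'
#' Typologies are stored as JSON: an object with an `archetypes` array whose
#' entries have `id`, `label` and `cells` (array of
#' `[naturalness, management]` pairs). `read_typology(write_typology(t))` is
#' an identity; files with overlapping cells or an empty archetype list are
#' rejected.
#'
#' @param t An [fa_typology()].
#' @param path JSON file path.
#' @examples
#' ref <- read_typology(fa_example("typology_reference.json"))
#' length(ref)  # 9 archetypes, A to I
#' @export
read_typology <- function(path) {
  fa_assert(file.exists(path), "fa_io_error",
            "typology file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  fa_assert(!is.null(j$archetypes), "fa_validation_error",
            "typology file %s needs an 'archetypes' array", path)
  arch <- lapply(j$archetypes, function(a) {
    cells <- do.call(rbind, lapply(a$cells, function(cc)
      data.frame(naturalness = as.character(cc[[1]]),
                 management = as.character(cc[[2]]),
                 stringsAsFactors = FALSE)))
    list(id = a$id, label = a$label, cells = cells)
  })
  fa_typology(arch)
}

#' @rdname read_typology
#' @export
write_typology <- function(t, path) {
  fa_assert(inherits(t, "fa_typology"), "fa_validation_error",
            "not an fa_typology")
  arch <- lapply(unname(t), function(a) {
    cells <- lapply(seq_len(nrow(a$cells)), function(i)
      c(a$cells$naturalness[i], a$cells$management[i]))
    list(id = a$id, label = a$label, cells = cells)
  })
  jsonlite::write_json(list(archetypes = arch), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
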