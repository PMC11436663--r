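#' Build the naturalness x management distance matrix
#'
#' Computes the generalized Hamming distance for every pair of one
#' naturalness profile and one management profile, populating the full
#' cross-product matrix (55 cells in the reference configuration, 11 x 5).
#' Rows keep the order of `nat`, columns the order of `man`; the reference
#' files use the canonical most-to-least-natural row order (n7..n1, p4..p1)
#' and passive-to-intensive column order.
#'
#' @param nat List of naturalness [fa_profile()]s.
#' @param man List of management [fa_profile()]s.
#' @param schema The shared [fa_schema()].
#' @return An object of class `fa_distmat`: list with `rows`, `cols`,
#'   `counts` (integer mismatch-count matrix), `values` (`counts / K`), `K`,
#'   and `mismatched` (list-matrix of mismatching indicator ids per cell,
#'   for provenance).
#' @examples
#' sch <- read_schema(fa_example("indicator_schema.csv"))
#' nat <- read_profiles(fa_example("naturalness_profiles.csv"), sch)
#' man <- read_profiles(fa_example("management_profiles.csv"), sch)
#' dm <- build_matrix(nat, man, sch)
#' dim(as.matrix(dm))  # 11 x 5
#' @export
build_matrix <- function(nat, man, schema) {
  fa_assert(length(nat) >= 1L && length(man) >= 1L, "fa_validation_error",
            "both axes need at least one profile")
  rows <- unname(vapply(nat, `[[`, character(1), "code"))
  cols <- unname(vapply(man, `[[`, character(1), "code"))
  fa_assert(!anyDuplicated(rows), "fa_validation_error",
            "duplicate naturalness code(s): %s",
            paste(rows[duplicated(rows)], collapse = ", "))
  fa_assert(!anyDuplicated(cols), "fa_validation_error",
            "duplicate management code(s): %s",
            paste(cols[duplicated(cols)], collapse = ", "))
  counts <- matrix(NA_integer_, length(rows), length(cols),
                   dimnames = list(rows, cols))
  mism <- matrix(vector("list", length(rows) * length(cols)),
                 length(rows), length(cols), dimnames = list(rows, cols))
  for (i in seq_along(rows)) {
    for (j in seq_along(cols)) {
      d <- hamming_distance(nat[[i]], man[[j]], schema)
      counts[i, j] <- d$mismatches
      mism[[i, j]] <- d$mismatched_components
    }
  }
  structure(list(rows = rows, cols = cols, counts = counts,
                 values = counts / schema$K, K = schema$K,
                 mismatched = mism),
            class = "fa_distmat")
}

#' @export
as.matrix.fa_distmat <- function(x, ...) x$values

#' @export
print.fa_distmat <- function(x, ...) {
  cat(sprintf("Distance matrix: %d naturalness x %d management (K = %d)\n",
              length(x$rows), length(x$cols), x$K))
  print(round(x$values, 3))
  invisible(x)
}

#' Read or write a distance matrix
#'
#' The matrix is written as TSV (row names in the first column, normalized
#' distances in the body) plus a JSON sidecar `<path>.counts.json` holding
#' the exact integer mismatch counts and K, so that re-loading loses no
#' precision and tier comparisons stay exact.
#'
#' @param m An `fa_distmat`.
#' @param path TSV file path; the sidecar is written next to it.
#' @return `read_matrix()` returns an `fa_distmat` (without per-cell
#'   provenance, which is not serialized).
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(naturalness = m$rows,
                   m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  side <- list(K = m$K, rows = m$rows, cols = m$cols,
               counts = unname(split(m$counts, row(m$counts))))
  jsonlite::write_json(side, paste0(path, ".counts.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  side_path <- paste0(path, ".counts.json")
  fa_assert(file.exists(path), "fa_io_error", "matrix file not found: %s", path)
  fa_assert(file.exists(side_path), "fa_io_error",
            "matrix sidecar not found: %s", side_path)
  j <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  rows <- as.character(j$rows)
  cols <- as.character(j$cols)
  counts <- j$counts
  if (is.list(counts)) counts <- do.call(rbind, lapply(counts, as.integer))
  fa_assert(length(counts) == length(rows) * length(cols), "fa_io_error",
            "matrix sidecar %s is inconsistent with its axes", side_path)
  counts <- matrix(as.integer(t(counts)), nrow = length(rows), byrow = TRUE,
                   dimnames = list(rows, cols))
  structure(list(rows = rows, cols = cols, counts = counts,
                 values = counts / j$K, K = as.integer(j$K),
                 mismatched = NULL),
            class = "fa_distmat")
}

#' Delineation configuration
#'
#' Bundles the inputs of [delineate()]: the plausibility mask, the distance
#' tier width, the aggregation rules and archetype labels. "Lower Hamming
#' distances" is operationalized as a tier: within each naturalness row, all
#' mask-allowed cells whose mismatch count is within `tier_width` units of
#' the row minimum are selected. `tier_width = 0` keeps exactly the tied row
#' minima; ties are always all kept, with no ordering preference between
#' management columns.
#'
#' @param mask An [fa_mask()] covering the matrix.
#' @param tier_width Non-negative integer, in mismatch-count units
#'   (default 0 = strict row minimum among allowed cells).
#' @param aggregation An [fa_aggregation()] (possibly empty list).
#' @param labels Named character vector mapping archetype id to label text;
#'   ids are consumed in row order for rows not covered by an aggregation
#'   rule. Defaults to `LETTERS` with empty labels.
#' @return A list of class `fa_delineation_config`.
#' @export
delineation_config <- function(mask, tier_width = 0L, aggregation = list(),
                               labels = NULL) {
  fa_assert(inherits(mask, "fa_mask"), "fa_validation_error",
            "mask must be an fa_mask")
  tier_width <- as.integer(tier_width)
  fa_assert(length(tier_width) == 1L && !is.na(tier_width) && tier_width >= 0L,
            "fa_validation_error", "tier_width must be a single integer >= 0")
  if (!inherits(aggregation, "fa_aggregation"))
    aggregation <- fa_aggregation(aggregation)
  if (is.null(labels)) labels <- stats::setNames(rep("", 26L), LETTERS)
  structure(list(mask = mask, tier_width = tier_width,
                 aggregation = aggregation, labels = labels),
            class = "fa_delineation_config")
}

#' Delineate archetypes from a distance matrix
#'
#' For each naturalness row the candidate cells are restricted to those the
#' plausibility mask allows; the minimal mismatch count m* among them is
#' found, and every allowed cell with count <= m* + `tier_width` is
#' selected. Each row initially yields one archetype; aggregation rules then
#' fuse the selections of merged rows (e.g. the primary-forest levels n5,
#' n6, n7) into a single archetype holding the union of their cells.
#' Archetype ids come from the rule's target id for merged groups and from
#' `cfg$labels` in matrix row order otherwise. The procedure is fully
#' deterministic.
#'
#' A row with no mask-allowed cells is an error naming the row: resolving
#' such a row needs expert judgment, which this package refuses to guess.
#'
#' @param matrix An `fa_distmat` from [build_matrix()] or [read_matrix()].
#' @param cfg A [delineation_config()].
#' @return An [fa_typology()] covering every naturalness row exactly once.
#' @examples
#' sch <- read_schema(fa_example("indicator_schema.csv"))
#' nat <- read_profiles(fa_example("naturalness_profiles.csv"), sch)
#' man <- read_profiles(fa_example("management_profiles.csv"), sch)
#' dm <- build_matrix(nat, man, sch)
#' cfg <- delineation_config(read_mask(fa_example("plausibility_mask.json")),
#'   tier_width = 1,
#'   aggregation = read_aggregation(fa_example("aggregation_rules.json")))
#' delineate(dm, cfg)
#' @export
delineate <- function(matrix, cfg) {
  fa_assert(inherits(matrix, "fa_distmat"), "fa_validation_error",
            "matrix must be an fa_distmat")
  fa_assert(inherits(cfg, "fa_delineation_config"), "fa_validation_error",
            "cfg must be a delineation_config")
  mask <- cfg$mask
  fa_assert(setequal(rownames(mask), matrix$rows) &&
              setequal(colnames(mask), matrix$cols),
            "fa_validation_error",
            "mask axes do not cover the matrix axes")
  agg <- fa_aggregation(unclass(cfg$aggregation), matrix$rows)

  # per-row tier selection
  selected <- stats::setNames(vector("list", length(matrix$rows)),
                              matrix$rows)
  for (r in matrix$rows) {
    ok <- colnames(mask)[mask[r, matrix$cols]]
    ok <- matrix$cols[matrix$cols %in% ok]      # matrix column order
    fa_assert(length(ok) >= 1L, "fa_delineation_error",
              "naturalness row '%s' has no mask-allowed cell; supply a plausibility judgment for it",
              r)
    cnt <- matrix$counts[r, ok]
    m_star <- min(cnt)
    selected[[r]] <- ok[cnt <= m_star + cfg$tier_width]
  }

  # group rows: aggregation rules fuse rows, anchored at the first merged
  # row's position; other rows stand alone
  merged_of <- stats::setNames(rep(NA_character_, length(matrix$rows)),
                               matrix$rows)
  for (rule in agg)
    merged_of[rule$merged_codes] <- rule$target_archetype_id
  groups <- list()
  done <- character(0)
  for (r in matrix$rows) {
    if (r %in% done) next
    if (!is.na(merged_of[[r]])) {
      rule_rows <- matrix$rows[!is.na(merged_of[matrix$rows]) &
                                 merged_of[matrix$rows] == merged_of[[r]]]
      groups[[length(groups) + 1L]] <-
        list(rows = rule_rows, id = merged_of[[r]])
      done <- c(done, rule_rows)
    } else {
      groups[[length(groups) + 1L]] <- list(rows = r, id = NA_character_)
      done <- c(done, r)
    }
  }

  # assign ids from cfg$labels in group order, skipping rule-fixed ids
  pool <- setdiff(names(cfg$labels),
                  stats::na.omit(vapply(groups, `[[`, character(1), "id")))
  archetypes <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    id <- groups[[g]]$id
    if (is.na(id)) {
      fa_assert(length(pool) >= 1L, "fa_delineation_error",
                "ran out of archetype labels; supply more in the config")
      id <- pool[1L]
      pool <- pool[-1L]
    }
    cells <- do.call(rbind, lapply(groups[[g]]$rows, function(r)
      data.frame(naturalness = r, management = selected[[r]],
                 stringsAsFactors = FALSE)))
    label <- if (id %in% names(cfg$labels)) cfg$labels[[id]] else ""
    archetypes[[g]] <- list(id = id, label = label, cells = cells)
  }
  fa_typology(archetypes)
}

#' Compare two typologies cell by cell
#'
#' Reports, per archetype id, the cells present in both typologies and the
#' symmetric difference (missing from `t2`, extra in `t2`). Used to verify a
#' delineation against a reference fixture.
#'
#' @param t1,t2 [fa_typology()] objects over the same axis codes.
#' @return A list of class `fa_typology_diff` with per-id entries
#'   (`matched`, `missing`, `extra` cell data frames) and a logical
#'   `identical` attribute; `fa_diff_empty()` tests it.
#' @export
compare_typologies <- function(t1, t2) {
  ids <- union(names(t1), names(t2))
  key <- function(cells) {
    if (is.null(cells) || nrow(cells) == 0L) return(character(0))
    paste(cells$naturalness, cells$management, sep = "\r")
  }
  unkey <- function(k) {
    if (length(k) == 0L)
      return(data.frame(naturalness = character(0),
                        management = character(0),
                        stringsAsFactors = FALSE))
    parts <- strsplit(k, "\r", fixed = TRUE)
    data.frame(naturalness = vapply(parts, `[[`, character(1), 1L),
               management = vapply(parts, `[[`, character(1), 2L),
               stringsAsFactors = FALSE)
  }
  out <- lapply(stats::setNames(ids, ids), function(id) {
    k1 <- if (id %in% names(t1)) key(t1[[id]]$cells) else character(0)
    k2 <- if (id %in% names(t2)) key(t2[[id]]$cells) else character(0)
    list(matched = unkey(intersect(k1, k2)),
         missing = unkey(setdiff(k1, k2)),
         extra = unkey(setdiff(k2, k1)))
  })
  identical_flag <- all(vapply(out, function(d)
    nrow(d$missing) == 0L && nrow(d$extra) == 0L, logical(1)))
  structure(out, identical = identical_flag, class = "fa_typology_diff")
}

#' @rdname compare_typologies
#' @param diff An `fa_typology_diff`.
#' @export
fa_diff_empty <- function(diff) isTRUE(attr(diff, "identical"))

#' @export
print.fa_typology_diff <- function(x, ...) {
  if (fa_diff_empty(x)) {
    cat("Typologies are identical.\n")
    return(invisible(x))
  }
  for (id in names(x)) {
    d <- x[[id]]
    if (nrow(d$missing) == 0L && nrow(d$extra) == 0L) next
    cat(sprintf("Archetype %s:\n", id))
    if (nrow(d$missing) > 0L)
      cat("  missing:", paste(sprintf("(%s,%s)", d$missing$naturalness,
                                      d$missing$management), collapse = " "),
          "\n")
    if (nrow(d$extra) > 0L)
      cat("  extra:  ", paste(sprintf("(%s,%s)", d$extra$naturalness,
                                      d$extra$management), collapse = " "),
          "\n")
  }
  invisible(x)
}
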