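# Member cells of the reference typology (archetypes A-I over the 11
# naturalness levels and 5 management approaches). Used by the "paper-like"
# synthetic preset as planted truth; the packaged JSON fixture carries the
# same cells plus labels.
reference_cells <- function() {
  rbind(
    data.frame(archetype = "A", naturalness = c("n5", "n6", "n7"),
               management = "passive", stringsAsFactors = FALSE),
    data.frame(archetype = "B", naturalness = "n4", management = "passive",
               stringsAsFactors = FALSE),
    data.frame(archetype = "C", naturalness = "n3", management = "low",
               stringsAsFactors = FALSE),
    data.frame(archetype = "D", naturalness = "n2",
               management = c("low", "medium"), stringsAsFactors = FALSE),
    data.frame(archetype = "E", naturalness = "n1", management = "high",
               stringsAsFactors = FALSE),
    data.frame(archetype = "F", naturalness = "p4",
               management = c("passive", "low", "medium"),
               stringsAsFactors = FALSE),
    data.frame(archetype = "G", naturalness = "p3",
               management = c("high", "intensive"), stringsAsFactors = FALSE),
    data.frame(archetype = "H", naturalness = "p2",
               management = c("high", "intensive"), stringsAsFactors = FALSE),
    data.frame(archetype = "I", naturalness = "p1",
               management = c("high", "intensive"), stringsAsFactors = FALSE)
  )
}

naturalness_order <- c("n7", "n6", "n5", "n4", "n3", "n2", "n1",
                       "p4", "p3", "p2", "p1")
management_order <- c("passive", "low", "medium", "high", "intensive")

#' Synthetic-data configuration
#'
#' Parameters of the seeded generators. Defaults mirror the reference
#' configuration: K = 19 indicators, an 11 x 5 naturalness/management
#' cross-product, and components carrying 1-3 descriptors with probability
#' `multi_descriptor_prob` of holding more than one. `planted_pairs` plants
#' block structure: on each planted (row, col) pair, at least
#' `planted_match_fraction` of the K components are forced to share a
#' descriptor, so the pair's distance is at most
#' `1 - planted_match_fraction` (exactly 0 when the fraction is 1).
#'
#' The `"paper-like"` preset sets K = 19, vocabulary size 8, the canonical
#' 11 x 5 axis codes, `multi_descriptor_prob = 0.3`,
#' `planted_match_fraction = 1`, and planted pairs equal to the member cells
#' of the packaged reference typology.
#'
#' @param K Number of indicators (>= 1).
#' @param vocab_size Descriptor vocabulary size per indicator (>= 2).
#' @param n_rows,n_cols Axis sizes.
#' @param multi_descriptor_prob Probability a component carries more than
#'   one descriptor (then 2 or 3, equiprobable).
#' @param planted_pairs `NULL`, or a data frame with columns `row`, `col`
#'   of axis codes to plant.
#' @param planted_match_fraction Fraction of components forced to match on
#'   planted pairs, in \[0,1\].
#' @param seed Integer seed; every generator is deterministic given the
#'   config.
#' @param row_codes,col_codes Axis code vectors (defaults `r1..`/`c1..`).
#' @param preset `NULL` or `"paper-like"`.
#' @return A list of class `fa_synth_config`.
#' @export
synth_config <- function(K = 19L, vocab_size = 8L, n_rows = 11L, n_cols = 5L,
                         multi_descriptor_prob = 0.3, planted_pairs = NULL,
                         planted_match_fraction = 1, seed = 1L,
                         row_codes = NULL, col_codes = NULL, preset = NULL) {
  if (!is.null(preset)) {
    fa_assert(identical(preset, "paper-like"), "fa_validation_error",
              "unknown preset '%s'", preset)
    K <- 19L; vocab_size <- 8L; n_rows <- 11L; n_cols <- 5L
    multi_descriptor_prob <- 0.3
    planted_match_fraction <- 1
    row_codes <- naturalness_order
    col_codes <- management_order
    cells <- reference_cells()
    planted_pairs <- data.frame(row = cells$naturalness,
                                col = cells$management,
                                stringsAsFactors = FALSE)
  }
  K <- as.integer(K)
  fa_assert(K >= 1L, "fa_validation_error", "K must be >= 1")
  fa_assert(vocab_size >= 2L, "fa_validation_error", "vocab_size must be >= 2")
  fa_assert(n_rows >= 1L && n_cols >= 1L, "fa_validation_error",
            "axis sizes must be >= 1")
  fa_assert(multi_descriptor_prob >= 0 && multi_descriptor_prob <= 1,
            "fa_validation_error", "multi_descriptor_prob must be in [0,1]")
  fa_assert(planted_match_fraction >= 0 && planted_match_fraction <= 1,
            "fa_validation_error",
            "planted_match_fraction must be in [0,1]")
  if (is.null(row_codes)) row_codes <- paste0("r", seq_len(n_rows))
  if (is.null(col_codes)) col_codes <- paste0("c", seq_len(n_cols))
  fa_assert(length(row_codes) == n_rows && length(col_codes) == n_cols,
            "fa_validation_error", "axis code lengths must match axis sizes")
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs, stringsAsFactors = FALSE)
    fa_assert(all(c("row", "col") %in% names(planted_pairs)),
              "fa_validation_error",
              "planted_pairs needs columns row and col")
    fa_assert(all(planted_pairs$row %in% row_codes) &&
                all(planted_pairs$col %in% col_codes),
              "fa_validation_error",
              "planted pair outside the axis code sets")
  }
  structure(list(K = K, vocab_size = as.integer(vocab_size),
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 multi_descriptor_prob = multi_descriptor_prob,
                 planted_pairs = planted_pairs,
                 planted_match_fraction = planted_match_fraction,
                 seed = as.integer(seed),
                 row_codes = row_codes, col_codes = col_codes),
            class = "fa_synth_config")
}

#' Generate a synthetic indicator schema
#'
#' Produces K indicators cycled through the four indicator groups, each with
#' the same-sized vocabulary `d1..dV`. Deterministic given the config.
#'
#' @param cfg An [synth_config()].
#' @return An [fa_schema()].
#' @export
gen_schema <- function(cfg) {
  fa_assert(inherits(cfg, "fa_synth_config"), "fa_validation_error",
            "cfg must be a synth_config")
  ids <- sprintf("ind%02d", seq_len(cfg$K))
  groups <- rep_len(fa_indicator_groups, cfg$K)
  vocab <- stats::setNames(
    rep(list(paste0("d", seq_len(cfg$vocab_size))), cfg$K), ids)
  fa_schema(data.frame(id = ids,
                       name = sprintf("synthetic indicator %d", seq_len(cfg$K)),
                       group = groups, stringsAsFactors = FALSE),
            vocab)
}

# one random descriptor set: size 1 with prob 1-p, else 2 or 3 (capped at V)
random_set <- function(vocab, p) {
  size <- if (stats::runif(1) < p) sample(2:3, 1L) else 1L
  size <- min(size, length(vocab))
  sort(sample(vocab, size))
}

#' Generate synthetic category profiles with planted structure
#'
#' Draws every component's descriptor set uniformly from the indicator's
#' vocabulary (sizes per `multi_descriptor_prob`), then enforces the planted
#' pairs: for each planted (row, col), `ceiling(planted_match_fraction * K)`
#' components are forced to share a descriptor by copying one token from the
#' row profile into the column profile's set where they do not already
#' intersect. Non-planted pairs share descriptors only at the background
#' rate implied by `vocab_size` (see [expected_match_prob()]).
#'
#' @param cfg An [synth_config()].
#' @param schema The schema from [gen_schema()] (or any schema with matching
#'   K and vocabulary sizes).
#' @return A list with elements `naturalness` and `management`, each a named
#'   list of [fa_profile()].
#' @export
gen_profiles <- function(cfg, schema) {
  fa_assert(inherits(cfg, "fa_synth_config"), "fa_validation_error",
            "cfg must be a synth_config")
  fa_assert(schema$K == cfg$K, "fa_validation_error",
            "schema K (%d) differs from config K (%d)", schema$K, cfg$K)
  ids <- schema_ids(schema)
  with_seed(cfg$seed, {
    draw <- function(axis, code) {
      comps <- lapply(stats::setNames(ids, ids), function(id)
        random_set(schema$vocabulary[[id]], cfg$multi_descriptor_prob))
      fa_profile(axis, code, comps, schema)
    }
    nat <- lapply(stats::setNames(cfg$row_codes, cfg$row_codes),
                  function(code) draw("naturalness", code))
    man <- lapply(stats::setNames(cfg$col_codes, cfg$col_codes),
                  function(code) draw("management", code))
    if (!is.null(cfg$planted_pairs) && nrow(cfg$planted_pairs) > 0L) {
      n_forced <- ceiling(cfg$planted_match_fraction * cfg$K)
      for (i in seq_len(nrow(cfg$planted_pairs))) {
        r <- cfg$planted_pairs$row[i]
        cl <- cfg$planted_pairs$col[i]
        forced <- if (n_forced >= cfg$K) ids else
          ids[sort(sample(cfg$K, n_forced))]
        for (id in forced) {
          a <- nat[[r]]$components[[id]]
          b <- man[[cl]]$components[[id]]
          if (!any(a %in% b)) {
            tok <- if (length(a) == 1L) a else sample(a, 1L)
            man[[cl]]$components[[id]] <- sort(unique(c(b, tok)))
          }
        }
      }
    }
    list(naturalness = nat, management = man)
  })
}

#' Expected per-component match probability under the background model
#'
#' For two descriptor sets drawn independently and uniformly without
#' replacement from a vocabulary of size V, with sizes s1 and s2, the match
#' probability is `1 - choose(V - s1, s2) / choose(V, s2)`. This averages
#' that expression over the generator's size distribution (size 1 with
#' probability `1 - multi_descriptor_prob`, sizes 2 and 3 equiprobable
#' otherwise, capped at V). The expected distance between two unplanted
#' profiles is `1 - expected_match_prob(cfg)` per component.
#'
#' @param cfg An [synth_config()].
#' @return A probability.
#' @export
expected_match_prob <- function(cfg) {
  V <- cfg$vocab_size
  p <- cfg$multi_descriptor_prob
  sizes <- c(1L, min(2L, V), min(3L, V))
  probs <- c(1 - p, p / 2, p / 2)
  em <- 0
  for (i in seq_along(sizes)) {
    for (j in seq_along(sizes)) {
      s1 <- sizes[i]; s2 <- sizes[j]
      pm <- 1 - choose(V - s1, s2) / choose(V, s2)
      em <- em + probs[i] * probs[j] * pm
    }
  }
  em
}

#' Generate synthetic case studies from a typology
#'
#' Draws `n` cases uniformly (with replacement) from the typology's member
#' cells — all assignable by construction — plus `n_off` cases on
#' cross-product cells outside the typology, which are unassignable by
#' construction. Deterministic given `cfg$seed`.
#'
#' @param cfg An [synth_config()] (supplies seed and axis codes).
#' @param typology A non-empty [fa_typology()].
#' @param n Number of on-typology cases (default 38, the scale of the
#'   reference verification).
#' @param n_off Number of off-typology cases.
#' @return A case data frame as from [read_cases()].
#' @export
gen_cases <- function(cfg, typology, n = 38L, n_off = 0L) {
  fa_assert(inherits(typology, "fa_typology"), "fa_validation_error",
            "typology must be an fa_typology")
  cells <- typology_cells(typology)
  all_cells <- expand.grid(naturalness = cfg$row_codes,
                           management = cfg$col_codes,
                           stringsAsFactors = FALSE)
  key <- function(d) paste(d$naturalness, d$management, sep = "\r")
  off_cells <- all_cells[!key(all_cells) %in% key(cells), , drop = FALSE]
  fa_assert(n_off == 0L || nrow(off_cells) > 0L, "fa_validation_error",
            "no off-typology cells exist to draw from")
  with_seed(cfg$seed + 1L, {
    pick_on <- if (n > 0L) sample(nrow(cells), n, replace = TRUE) else integer(0)
    pick_off <- if (n_off > 0L)
      sample(nrow(off_cells), n_off, replace = TRUE) else integer(0)
    df <- rbind(cells[pick_on, c("naturalness", "management"), drop = FALSE],
                off_cells[pick_off, , drop = FALSE])
    if (nrow(df) == 0L)
      return(data.frame(id = character(0), source = character(0),
                        naturalness_code = character(0),
                        management_code = character(0),
                        notes = character(0), stringsAsFactors = FALSE))
    data.frame(id = sprintf("case%03d", seq_len(nrow(df))),
               source = "synthetic",
               naturalness_code = df$naturalness,
               management_code = df$management,
               notes = c(rep("on-typology", length(pick_on)),
                         rep("off-typology", length(pick_off))),
               stringsAsFactors = FALSE)
  })
}
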