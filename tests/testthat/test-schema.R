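test_that("packaged schema loads with 19 indicators across all four groups", {
  sch <- read_schema(fa_example("indicator_schema.csv"))
  expect_s3_class(sch, "fa_schema")
  expect_identical(sch$K, 19L)
  expect_setequal(unique(sch$indicators$group), fa_indicator_groups)
  expect_true(all(lengths(sch$vocabulary) >= 1L))
})

test_that("schema validation rejects malformed inputs", {
  df <- data.frame(id = c("a", "a"), name = c("x", "y"),
                   group = "structural", stringsAsFactors = FALSE)
  vocab <- list(a = "1")
  expect_error(fa_schema(df, vocab), class = "fa_schema_error",
               regexp = "duplicate indicator id.*a")
  df2 <- data.frame(id = "a", name = "x", group = "structural",
                    stringsAsFactors = FALSE)
  expect_error(fa_schema(df2, list(a = character(0))),
               class = "fa_schema_error", regexp = "empty vocabulary")
  expect_error(fa_schema(data.frame(id = "a", name = "x", group = "weird"),
                         list(a = "1")),
               class = "fa_schema_error", regexp = "unknown indicator group")
})

test_that("single-indicator schema round-trips through CSV", {
  sch <- mk_schema(1, vocab = c("x", "y"))
  expect_identical(sch$K, 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_schema(sch, path)
  back <- read_schema(path)
  expect_identical(back$indicators, sch$indicators)
  expect_identical(back$vocabulary, sch$vocabulary)
})

test_that("duplicate indicator id in a schema file is rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,group,vocabulary",
               "a,first,structural,1|2",
               "a,second,functional,3"), path)
  expect_error(read_schema(path), class = "fa_schema_error",
               regexp = "duplicate indicator id")
})

test_that("packaged profile files parse to 11 naturalness and 5 management categories", {
  sch <- read_schema(fa_example("indicator_schema.csv"))
  nat <- read_profiles(fa_example("naturalness_profiles.csv"), sch)
  man <- read_profiles(fa_example("management_profiles.csv"), sch)
  expect_length(nat, 11L)
  expect_length(man, 5L)
  expect_identical(names(nat), c("n7", "n6", "n5", "n4", "n3", "n2", "n1",
                                 "p4", "p3", "p2", "p1"))
  expect_identical(names(man),
                   c("passive", "low", "medium", "high", "intensive"))
  expect_true(all(vapply(nat, function(p) p$K == 19L, logical(1))))
  # every component non-empty and in-vocabulary is enforced at construction
  expect_true(all(vapply(nat, function(p)
    all(lengths(p$components) >= 1L), logical(1))))
})

test_that("profile validation errors cite category and indicator", {
  sch <- mk_schema(3)
  comps <- stats::setNames(list("1", "2", "3"), sch$indicators$id)
  # short profile (K-1 components)
  expect_error(fa_profile("naturalness", "x", comps[1:2], sch),
               class = "fa_validation_error", regexp = "K = 3")
  # empty component
  bad <- comps; bad[["i02"]] <- character(0)
  expect_error(fa_profile("naturalness", "x", bad, sch),
               class = "fa_validation_error",
               regexp = "'x'.*'i02'.*empty descriptor set")
  # unknown descriptor token
  bad2 <- comps; bad2[["i03"]] <- "zz"
  expect_error(fa_profile("naturalness", "x", bad2, sch),
               class = "fa_validation_error", regexp = "'zz'.*'i03'")
})

test_that("profile file row order never changes the loaded profile", {
  sch <- mk_schema(4)
  p <- mk_profile("c1", list("1", c("2", "3"), "4", "5"), sch)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(list(p), path)
  df <- utils::read.csv(path, colClasses = "character")
  shuffled <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[rev(seq_len(nrow(df))), ], shuffled, row.names = FALSE)
  back <- read_profiles(shuffled, sch)[["c1"]]
  expect_identical(back$components, p$components)
})

test_that("mask requires full row coverage and known codes", {
  expect_error(fa_mask(list(r1 = "c1"), c("r1", "r2"), c("c1", "c2")),
               class = "fa_validation_error")
  expect_error(fa_mask(list(r1 = "c9", r2 = "c1"), c("r1", "r2"),
                       c("c1", "c2")),
               class = "fa_validation_error", regexp = "unknown management")
  m <- fa_mask_all(c("r1", "r2"), c("c1", "c2"))
  expect_true(all(m))
  path <- withr::local_tempfile(fileext = ".json")
  write_mask(m, path)
  expect_identical(unclass(read_mask(path))[, ], unclass(m)[, ])
})

test_that("aggregation rules reject repeated or unknown codes", {
  rules <- list(list(merged_codes = c("a", "b"), target_archetype_id = "X"),
                list(merged_codes = "b", target_archetype_id = "Y"))
  expect_error(fa_aggregation(rules), class = "fa_validation_error",
               regexp = "more than one aggregation rule")
  expect_error(
    fa_aggregation(list(list(merged_codes = "zz",
                             target_archetype_id = "X")),
                   naturalness_codes = c("a", "b")),
    class = "fa_validation_error", regexp = "unknown naturalness")
})

test_that("reference typology fixture has nine disjoint archetypes covering all levels", {
  ref <- ref_typology()
  expect_length(ref, 9L)
  expect_identical(names(ref), LETTERS[1:9])
  cells <- do.call(rbind, lapply(ref, `[[`, "cells"))
  expect_identical(anyDuplicated(paste(cells$naturalness, cells$management)),
                   0L)
  expect_setequal(unique(cells$naturalness),
                  c("n7", "n6", "n5", "n4", "n3", "n2", "n1",
                    "p4", "p3", "p2", "p1"))
  # spot-check the multi-cell archetypes
  expect_setequal(ref$A$cells$naturalness, c("n5", "n6", "n7"))
  expect_setequal(ref$F$cells$management, c("passive", "low", "medium"))
  expect_setequal(ref$I$cells$management, c("high", "intensive"))
})

test_that("typology IO is a round-trip identity and rejects bad files", {
  ref <- ref_typology()
  path <- withr::local_tempfile(fileext = ".json")
  write_typology(ref, path)
  back <- read_typology(path)
  expect_true(fa_diff_empty(compare_typologies(ref, back)))

  empty <- withr::local_tempfile(fileext = ".json")
  writeLines('{"archetypes": []}', empty)
  expect_error(read_typology(empty), class = "fa_validation_error")

  overlap <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"archetypes": [',
                    '{"id":"A","label":"","cells":[["n1","low"]]},',
                    '{"id":"B","label":"","cells":[["n1","low"]]}]}'),
             overlap)
  expect_error(read_typology(overlap), class = "fa_validation_error",
               regexp = "more than one archetype")
})
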