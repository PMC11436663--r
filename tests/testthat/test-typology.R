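test_that("build_matrix populates the full cross-product", {
  sch <- read_schema(fa_example("indicator_schema.csv"))
  nat <- read_profiles(fa_example("naturalness_profiles.csv"), sch)
  man <- read_profiles(fa_example("management_profiles.csv"), sch)
  dm <- build_matrix(nat, man, sch)
  expect_identical(dim(dm$counts), c(11L, 5L))
  expect_identical(sum(!is.na(dm$counts)), 55L)
  expect_true(all(dm$values >= 0 & dm$values <= 1))
  expect_identical(dm$values, dm$counts / 19L)
})

test_that("a 1x1 matrix equals the pairwise distance", {
  sch <- mk_schema(3)
  p <- mk_profile("r", list("1", "2", "3"), sch)
  q <- mk_profile("c", list("1", "9", "3"), sch, axis = "management")
  dm <- build_matrix(list(p), list(q), sch)
  expect_identical(unname(dm$values[1, 1]),
                   hamming_distance(p, q, sch)$value)
})

test_that("matrix cell values are invariant to profile list order", {
  withr::local_seed(5)
  sch <- mk_schema(6)
  nat <- lapply(paste0("r", 1:4), function(cd) rand_profile(cd, sch))
  man <- lapply(paste0("c", 1:3), function(cd)
    rand_profile(cd, sch, axis = "management"))
  dm1 <- build_matrix(nat, man, sch)
  dm2 <- build_matrix(rev(nat), rev(man), sch)
  rows <- dm1$rows; cols <- dm1$cols
  expect_identical(dm1$counts[rows, cols], dm2$counts[rows, cols])
})

test_that("duplicate axis codes are rejected", {
  sch <- mk_schema(2)
  p <- mk_profile("same", list("1", "2"), sch)
  q <- mk_profile("c", list("1", "2"), sch, axis = "management")
  expect_error(build_matrix(list(p, p), list(q), sch),
               class = "fa_validation_error", regexp = "duplicate")
})

test_that("matrix IO round-trips exact counts through TSV + sidecar", {
  sch <- read_schema(fa_example("indicator_schema.csv"))
  nat <- read_profiles(fa_example("naturalness_profiles.csv"), sch)
  man <- read_profiles(fa_example("management_profiles.csv"), sch)
  dm <- build_matrix(nat, man, sch)
  path <- file.path(withr::local_tempdir(), "matrix.tsv")
  write_matrix(dm, path)
  back <- read_matrix(path)
  expect_identical(back$counts, dm$counts)
  expect_identical(back$K, dm$K)
  expect_identical(back$rows, dm$rows)
})

test_that("delineation on the packaged transcription reproduces the reference typology", {
  sch <- read_schema(fa_example("indicator_schema.csv"))
  nat <- read_profiles(fa_example("naturalness_profiles.csv"), sch)
  man <- read_profiles(fa_example("management_profiles.csv"), sch)
  dm <- build_matrix(nat, man, sch)
  for (tw in 0:1) {  # the transcription separates cells by >= 2 units
    typ <- delineate(dm, shipped_delineation_config(tier_width = tw))
    expect_true(fa_diff_empty(compare_typologies(ref_typology(), typ)),
                info = sprintf("tier_width = %d", tw))
  }
})

test_that("rows selecting one column fuse under an aggregation rule", {
  # three rows tied at zero on the first column, one standalone row
  sch <- mk_schema(4, vocab = as.character(1:9))
  nat <- list(mk_profile("r1", list("1", "2", "3", "4"), sch),
              mk_profile("r2", list("1", "2", "3", "4"), sch),
              mk_profile("r3", list("1", "2", "3", "4"), sch),
              mk_profile("r4", list("5", "6", "7", "8"), sch))
  man <- list(mk_profile("c1", list("1", "2", "3", "4"), sch,
                         axis = "management"),
              mk_profile("c2", list("5", "6", "7", "8"), sch,
                         axis = "management"))
  dm <- build_matrix(nat, man, sch)
  cfg <- delineation_config(
    fa_mask_all(dm$rows, dm$cols),
    aggregation = list(list(merged_codes = c("r1", "r2", "r3"),
                            target_archetype_id = "A")))
  typ <- delineate(dm, cfg)
  expect_identical(names(typ), c("A", "B"))
  expect_identical(nrow(typ$A$cells), 3L)
  expect_setequal(typ$A$cells$naturalness, c("r1", "r2", "r3"))
  expect_identical(unique(typ$A$cells$management), "c1")
  expect_identical(typ$B$cells$management, "c2")
})

test_that("degenerate tier keeps every allowed column", {
  withr::local_seed(9)
  sch <- mk_schema(5)
  nat <- lapply(paste0("r", 1:3), function(cd) rand_profile(cd, sch))
  man <- lapply(paste0("c", 1:4), function(cd)
    rand_profile(cd, sch, axis = "management"))
  dm <- build_matrix(nat, man, sch)
  cfg <- delineation_config(fa_mask_all(dm$rows, dm$cols),
                            tier_width = sch$K)
  typ <- delineate(dm, cfg)
  for (a in typ) expect_setequal(a$cells$management, dm$cols)
})

test_that("tier widening is monotone and mask-disallowed cells never appear", {
  withr::local_seed(31)
  sch <- mk_schema(6)
  nat <- lapply(paste0("r", 1:5), function(cd) rand_profile(cd, sch))
  man <- lapply(paste0("c", 1:4), function(cd)
    rand_profile(cd, sch, axis = "management"))
  dm <- build_matrix(nat, man, sch)
  allowed <- list(r1 = c("c1", "c2"), r2 = c("c2", "c3", "c4"),
                  r3 = "c1", r4 = c("c1", "c4"), r5 = c("c2", "c3"))
  mask <- fa_mask(allowed, dm$rows, dm$cols)
  prev <- NULL
  for (tw in 0:6) {
    typ <- delineate(dm, delineation_config(mask, tier_width = tw))
    cells <- do.call(rbind, lapply(typ, `[[`, "cells"))
    for (i in seq_len(nrow(cells))) {
      expect_true(mask[cells$naturalness[i], cells$management[i]])
    }
    key <- paste(cells$naturalness, cells$management)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("a row with no admissible cell is a named delineation error", {
  sch <- mk_schema(2)
  nat <- list(mk_profile("r1", list("1", "2"), sch))
  man <- list(mk_profile("c1", list("1", "2"), sch, axis = "management"))
  dm <- build_matrix(nat, man, sch)
  mask <- fa_mask_all("r1", "c1")
  mask["r1", "c1"] <- FALSE
  cfg <- delineation_config(mask)
  expect_error(delineate(dm, cfg), class = "fa_delineation_error",
               regexp = "'r1'")
})

test_that("compare_typologies reports the exact symmetric difference", {
  ref <- ref_typology()
  expect_true(fa_diff_empty(compare_typologies(ref, ref)))
  # drop one cell from archetype F
  mod <- unclass(ref)
  mod$F$cells <- mod$F$cells[mod$F$cells$management != "medium", ]
  mod <- fa_typology(mod)
  d <- compare_typologies(ref, mod)
  expect_false(fa_diff_empty(d))
  expect_identical(d$F$missing,
                   data.frame(naturalness = "p4", management = "medium",
                              stringsAsFactors = FALSE))
  expect_identical(nrow(d$F$extra), 0L)
  for (id in setdiff(LETTERS[1:9], "F")) {
    expect_identical(nrow(d[[id]]$missing) + nrow(d[[id]]$extra), 0L)
  }
})
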