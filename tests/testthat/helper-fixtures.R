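# in-code fixture builders shared across test files

# minimal schema: K indicators, shared vocabulary, groups cycled
mk_schema <- function(K, vocab = as.character(0:9)) {
  ids <- sprintf("i%02d", seq_len(K))
  fa_schema(data.frame(id = ids, name = paste("indicator", ids),
                       group = rep_len(fa_indicator_groups, K),
                       stringsAsFactors = FALSE),
            stats::setNames(rep(list(vocab), K), ids))
}

# profile from a list of descriptor sets (schema order)
mk_profile <- function(code, sets, schema, axis = "naturalness") {
  fa_profile(axis, code, stats::setNames(sets, schema$indicators$id), schema)
}

# profile of singletons from a plain vector, e.g. c(1,2,1,0,3)
mk_singleton_profile <- function(code, values, schema,
                                 axis = "naturalness") {
  mk_profile(code, as.list(as.character(values)), schema, axis = axis)
}

# random profile with multi-descriptor components; caller controls the seed
rand_profile <- function(code, schema, p_multi = 0.5,
                         axis = "naturalness") {
  sets <- lapply(schema$indicators$id, function(id) {
    v <- schema$vocabulary[[id]]
    n <- if (stats::runif(1) < p_multi) sample(2:min(3, length(v)), 1) else 1
    sort(sample(v, n))
  })
  mk_profile(code, sets, schema, axis = axis)
}

# the worked five-component singleton example
worked_example <- function() {
  sch <- mk_schema(5, vocab = as.character(0:3))
  list(schema = sch,
       a = mk_singleton_profile("A", c(1, 2, 1, 0, 3), sch),
       b = mk_singleton_profile("B", c(1, 2, 2, 0, 3), sch,
                                axis = "management"))
}

ref_typology <- function() read_typology(fa_example("typology_reference.json"))

shipped_delineation_config <- function(tier_width = 1) {
  delineation_config(
    read_mask(fa_example("plausibility_mask.json")),
    tier_width = tier_width,
    aggregation = read_aggregation(fa_example("aggregation_rules.json")))
}

shipped_pipeline_inputs <- function() {
  list(schema = fa_example("indicator_schema.csv"),
       naturalness = fa_example("naturalness_profiles.csv"),
       management = fa_example("management_profiles.csv"),
       mask = fa_example("plausibility_mask.json"),
       aggregation = fa_example("aggregation_rules.json"),
       cases = fa_example("case_studies_synthetic.csv"))
}
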