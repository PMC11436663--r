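Package: forestarch
Title: Archetype Typologies of Forest Ecosystems from Naturalness and
    Management-Intensity Profiles
Version: 0.1.0
Authors@R: person("Forest", "Typology Lab", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building rule-based archetype typologies of forest
    ecosystems. Categories of forest naturalness and of forest management
    intensity are encoded as descriptor-set vectors over a shared indicator
    schema; a generalized Hamming distance with set-overlap ("or") matching
    quantifies dissimilarity between every naturalness/management pair;
    archetypes are delineated per naturalness level under an expert
    plausibility mask with an explicit distance-tier rule and aggregation of
    primary-forest levels; literature case studies are assigned to archetypes
    and coverage is reported. Includes seeded synthetic-data generators with
    planted structure for end-to-end testing, plain-text readers/writers for
    all artifacts, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
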