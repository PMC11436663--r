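"id","name","group","vocabulary"
"age_structure","Age structure of the stand","structural","uneven|mosaic|mostly_even|even"
"canopy_layers","Number of canopy layers","structural","multiple|two|single"
"standing_deadwood","Standing deadwood amount","structural","abundant|moderate|scarce|absent"
"lying_deadwood","Lying deadwood amount","structural","abundant|moderate|scarce|absent"
"tree_size_variation","Variation in tree sizes","structural","wide|intermediate|uniform"
"tree_spacing","Spacing pattern of trees","structural","irregular|semi_regular|regular"
"old_trees","Presence of old trees","structural","frequent|occasional|absent"
"regeneration","Regeneration type","functional","natural|mixed|planted|coppice"
"disturbance_regime","Disturbance regime","functional","natural|emulated|suppressed"
"development_phases","Stand development phases present","functional","all_phases|truncated|single_phase"
"canopy_gaps","Canopy gap origin","functional","natural_gaps|harvest_gaps|none"
"continuity","Forest continuity","functional","long|interrupted|recent"
"species_origin","Origin of canopy tree species","compositional","native|mostly_native|exotic"
"canopy_species_count","Canopy tree species count","compositional","many|few|one"
"provenance","Provenance of regeneration material","compositional","wild|nursery|breeding"
"understorey_diversity","Understorey and epiphyte diversity","compositional","rich|moderate|poor"
"management_objective","Primary management objective","human_impact","none|conservation|multifunctional|timber|biomass"
"harvest_system","Harvesting system","human_impact","none|selective|shelterwood|clearcut|whole_tree"
"time_since_intervention","Time since last silvicultural intervention","human_impact","never|over_80|under_80|recent|continuous"
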