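"axis","code","indicator_id","descriptors","scale"
"management","passive","age_structure","uneven|mosaic","stand"
"management","passive","canopy_layers","multiple|two","stand"
"management","passive","standing_deadwood","abundant|moderate","stand"
"management","passive","lying_deadwood","abundant|moderate","stand"
"management","passive","tree_size_variation","wide|intermediate","stand"
"management","passive","tree_spacing","irregular|semi_regular","stand"
"management","passive","old_trees","frequent|occasional","stand"
"management","passive","regeneration","natural","stand"
"management","passive","disturbance_regime","natural|suppressed","stand"
"management","passive","development_phases","all_phases|truncated","stand"
"management","passive","canopy_gaps","natural_gaps","stand"
"management","passive","continuity","long|interrupted","stand"
"management","passive","species_origin","native|mostly_native|exotic","stand"
"management","passive","canopy_species_count","many|few","stand"
"management","passive","provenance","wild","stand"
"management","passive","understorey_diversity","rich|moderate","stand"
"management","passive","management_objective","none|conservation","stand"
"management","passive","harvest_system","none","stand"
"management","passive","time_since_intervention","never|over_80|under_80","stand"
"management","low","age_structure","uneven|mosaic","stand"
"management","low","canopy_layers","multiple|two","stand"
"management","low","standing_deadwood","moderate|abundant","stand"
"management","low","lying_deadwood","moderate|abundant","stand"
"management","low","tree_size_variation","wide|intermediate","stand"
"management","low","tree_spacing","irregular|semi_regular","stand"
"management","low","old_trees","frequent|occasional","stand"
"management","low","regeneration","natural|coppice","stand"
"management","low","disturbance_regime","emulated","stand"
"management","low","development_phases","all_phases|truncated","stand"
"management","low","canopy_gaps","natural_gaps|harvest_gaps","stand"
"management","low","continuity","long|interrupted","stand"
"management","low","species_origin","native|mostly_native","stand"
"management","low","canopy_species_count","many|few","stand"
"management","low","provenance","wild","stand"
"management","low","understorey_diversity","rich|moderate","stand"
"management","low","management_objective","conservation|multifunctional","stand"
"management","low","harvest_system","selective","stand"
"management","low","time_since_intervention","recent|under_80","stand"
"management","medium","age_structure","mosaic|mostly_even","stand"
"management","medium","canopy_layers","two","stand"
"management","medium","standing_deadwood","moderate|scarce","stand"
"management","medium","lying_deadwood","moderate|scarce","stand"
"management","medium","tree_size_variation","intermediate","stand"
"management","medium","tree_spacing","semi_regular","stand"
"management","medium","old_trees","occasional","stand"
"management","medium","regeneration","natural|mixed|planted","stand"
"management","medium","disturbance_regime","emulated|suppressed","stand"
"management","medium","development_phases","truncated","stand"
"management","medium","canopy_gaps","harvest_gaps","stand"
"management","medium","continuity","interrupted|recent","stand"
"management","medium","species_origin","native|mostly_native","stand"
"management","medium","canopy_species_count","few|many","stand"
"management","medium","provenance","wild|nursery","stand"
"management","medium","understorey_diversity","moderate","stand"
"management","medium","management_objective","multifunctional","stand"
"management","medium","harvest_system","selective|shelterwood","stand"
"management","medium","time_since_intervention","recent|continuous","stand"
"management","high","age_structure","even","stand"
"management","high","canopy_layers","single","stand"
"management","high","standing_deadwood","scarce|absent","stand"
"management","high","lying_deadwood","scarce|absent","stand"
"management","high","tree_size_variation","uniform","stand"
"management","high","tree_spacing","regular|semi_regular","stand"
"management","high","old_trees","absent","stand"
"management","high","regeneration","planted|natural|mixed","stand"
"management","high","disturbance_regime","suppressed","stand"
"management","high","development_phases","single_phase","stand"
"management","high","canopy_gaps","harvest_gaps|none","stand"
"management","high","continuity","recent","stand"
"management","high","species_origin","native|mostly_native|exotic","stand"
"management","high","canopy_species_count","one|few","stand"
"management","high","provenance","nursery|breeding|wild","stand"
"management","high","understorey_diversity","poor","stand"
"management","high","management_objective","timber","stand"
"management","high","harvest_system","clearcut|shelterwood","stand"
"management","high","time_since_intervention","continuous","stand"
"management","intensive","age_structure","even","stand"
"management","intensive","canopy_layers","single","stand"
"management","intensive","standing_deadwood","absent|scarce","stand"
"management","intensive","lying_deadwood","absent|scarce","stand"
"management","intensive","tree_size_variation","uniform","stand"
"management","intensive","tree_spacing","regular","stand"
"management","intensive","old_trees","absent","stand"
"management","intensive","regeneration","planted|coppice|natural","stand"
"management","intensive","disturbance_regime","suppressed","stand"
"management","intensive","development_phases","single_phase","stand"
"management","intensive","canopy_gaps","none|harvest_gaps","stand"
"management","intensive","continuity","recent","stand"
"management","intensive","species_origin","exotic|native|mostly_native","stand"
"management","intensive","canopy_species_count","one","stand"
"management","intensive","provenance","breeding|nursery|wild","stand"
"management","intensive","understorey_diversity","poor","stand"
"management","intensive","management_objective","biomass|timber","stand"
"management","intensive","harvest_system","whole_tree|clearcut","stand"
"management","intensive","time_since_intervention","continuous","stand"
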