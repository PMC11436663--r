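"id","source","naturalness_code","management_code","notes"
"S01","synthetic stand-in 1","n7","passive","near-virgin reserve, no recorded intervention"
"S02","synthetic stand-in 2","n7","passive","remnant primary stand in strict reserve"
"S03","synthetic stand-in 3","n6","passive","old-growth stand, large deadwood, multiple layers"
"S04","synthetic stand-in 4","n6","passive","old trees, late-seral structure, conservation area"
"S05","synthetic stand-in 5","n5","passive","untouched for over 80 years, blurred past impacts"
"S06","synthetic stand-in 6","n5","passive","long-unmanaged stand, natural regeneration"
"S07","synthetic stand-in 7","n4","passive","operations discontinued 40 years ago"
"S08","synthetic stand-in 8","n4","passive","abandoned managed stand, visible old stumps"
"S09","synthetic stand-in 9","n4","passive","recently set aside, former selective logging"
"S10","synthetic stand-in 10","n3","low","coppice with standards, rich ground flora"
"S11","synthetic stand-in 11","n3","low","pasture forest, old trees retained"
"S12","synthetic stand-in 12","n3","low","non-industrial selective logging, protective role"
"S13","synthetic stand-in 13","n3","low","recreational stand, low-intensity interventions"
"S14","synthetic stand-in 14","n2","low","exploited native forest, selective harvest"
"S15","synthetic stand-in 15","n2","low","self-sown native trees, emulated disturbances"
"S16","synthetic stand-in 16","n2","low","modified structure, natural regeneration"
"S17","synthetic stand-in 17","n2","medium","combined objective stand, mixed species"
"S18","synthetic stand-in 18","n2","medium","timber plus soil protection objectives"
"S19","synthetic stand-in 19","n2","medium","shelterwood system, native mixture"
"S20","synthetic stand-in 20","n1","high","self-sown native trees, even-aged, clear-cut system"
"S21","synthetic stand-in 21","p4","passive","planted native stand left unmanaged, heavy ingrowth"
"S22","synthetic stand-in 22","p4","passive","abandoned plantation, uneven-aged now"
"S23","synthetic stand-in 23","p4","passive","sown stand without later operations"
"S24","synthetic stand-in 24","p4","low","planted native forest under close-to-nature regime"
"S25","synthetic stand-in 25","p4","low","ageing planted stand, selective harvest only"
"S26","synthetic stand-in 26","p4","medium","planted native mixture, combined objectives"
"S27","synthetic stand-in 27","p4","medium","planted stand with significant self-sown share"
"S28","synthetic stand-in 28","p3","high","native conifer plantation, even-aged, thinned"
"S29","synthetic stand-in 29","p3","high","monospecific native plantation, clear-cut"
"S30","synthetic stand-in 30","p3","intensive","short-rotation native plantation"
"S31","synthetic stand-in 31","p3","intensive","biomass-oriented native plantation"
"S32","synthetic stand-in 32","p2","high","exotic plantation, even-aged, regular spacing"
"S33","synthetic stand-in 33","p2","high","non-native plantation from breeding material"
"S34","synthetic stand-in 34","p2","intensive","short-rotation exotic plantation, residues removed"
"S35","synthetic stand-in 35","p2","intensive","fast-growing exotic species, whole-tree harvest"
"S36","synthetic stand-in 36","p1","high","self-sown exotic stand managed for timber"
"S37","synthetic stand-in 37","p1","high","invasive-origin stand under even-aged forestry"
"S38","synthetic stand-in 38","p1","intensive","self-sown exotics in short-rotation use"
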