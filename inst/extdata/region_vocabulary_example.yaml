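# Example region vocabulary: fine region label -> coarse system label.
thalamus: thalamus
LGN: thalamus
MGE: germinal zones
LGE: germinal zones
CGE: germinal zones
VZ: germinal zones
iSVZ: germinal zones
oSVZ: germinal zones
cortical plate: cortex
subplate: cortex
intermediate zone: cortex
putamen: basal ganglia
caudate nucleus: basal ganglia
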