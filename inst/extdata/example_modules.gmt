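il1_inflammasome_partial	partial example list (incomplete; supply full curated GMT)	Casp1	Nlrp3	Il1r1	Il1b
il17_targets_partial	partial example list (incomplete; supply full curated GMT)	Cxcl1	Cxcl2	Lcn2	S100a8	S100a9
th17_axis_partial	partial example list (incomplete; supply full curated GMT)	Ccl20	Stat3	Batf	Tnfrsf9	Tnfsf13b
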