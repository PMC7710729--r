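variant	population	hom_ancestral	het	hom_derived
rs17112895	Gumuz	0.04	0.5	0.46
rs7909153	Gumuz	0.04	0.5	0.46
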