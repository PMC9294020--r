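# Reference case study 9: porous stent (1e-10 m^2), 42 side holes,
# completely occluded mid-ureter.
case_id: 9
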