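# A porous stented ureter described explicitly (lengths in mm).
geometry:
  length_mm: 240
  min_clearance_mm: 0.1
permeability_m2: 1.0e-10
side_holes: true
occlusion:
  present: false
pressures_pa:
  inlet: 97.8
  outlet: 0
fluid:
  density: 997.044
  viscosity: 0.001
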