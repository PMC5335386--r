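# Quick version of the headline in-silico comparison: control vs
# PAR1-activated astrocytic coverage, plus a half-transporter-density
# control, 30 seeds each.
name: fig4_quick
seeds: 30
simulation:
  nIterations: 5000
  nMolecules: 2000
  recordStride: 5
kinetics:
  applyQ10: true
conditions:
  - name: control
    scene: control
  - name: tfllr
    scene: tfllr
  - name: control_half_density
    scene: control
    overrides:
      transporterDensity: 5400
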