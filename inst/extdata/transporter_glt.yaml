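# Simplified astrocytic glutamate transporter cycle (rates at the
# recording temperature; apply Q10 scaling for physiological temperature).
states:
- T
- TG
- Tin
transitions:
- from: T
  to: TG
  rate: 6000000.0
  ligand: Glu
  effect: consume
- from: TG
  to: T
  rate: 601.0
  effect: release
- from: TG
  to: Tin
  rate: 2000.0
  effect: sequester
- from: Tin
  to: T
  rate: 50.0
  effect: none
conducting: []
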