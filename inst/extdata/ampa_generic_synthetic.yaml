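# Generic, order-of-magnitude AMPA-like scheme with competitive antagonist
# binding (synthetic template; edit rates to taste). Ligands: Glu, Ant.
states:
- C
- CG
- O
- D
- CB
transitions:
- from: C
  to: CG
  rate: 1.0e+07
  ligand: Glu
  effect: consume
- from: CG
  to: C
  rate: 5000.0
  effect: release
- from: CG
  to: O
  rate: 20000.0
  effect: none
- from: O
  to: CG
  rate: 8000.0
  effect: none
- from: CG
  to: D
  rate: 1000.0
  effect: none
- from: D
  to: CG
  rate: 8.0
  effect: none
- from: C
  to: CB
  rate: 1.0e+07
  ligand: Ant
  effect: consume
- from: CB
  to: C
  rate: 1200.0
  effect: release
conducting:
- O
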