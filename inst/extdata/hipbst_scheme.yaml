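symmetry: C2
bodies:
- label: HipB-N
  chain: A
  first: 1
  last: 31
- label: HipB-mid
  chain: A
  first: 32
  last: 43
- label: HipB-C
  chain: A
  first: 44
  last: 107
- label: HipS
  chain: B
  first: 1
  last: 110
- label: HipT-N
  chain: C
  first: 2
  last: 59
- label: HipT-core
  chain: C
  first: 60
  last: 169
- label: HipT-C
  chain: C
  first: 170
  last: 331
restraints:
- chain_a: A
  resno_a: 107
  resid_a: GLU
  chain_b: D
  resno_b: 101
  resid_b: VAL
  weight: 1.0
  target: .na.real
- chain_a: B
  resno_a: 55
  resid_a: PRO
  chain_b: C
  resno_b: 154
  resid_b: GLY
  weight: 1.0
  target: .na.real
- chain_a: B
  resno_a: 65
  resid_a: TRP
  chain_b: C
  resno_b: 60
  resid_b: GLY
  weight: 1.0
  target: .na.real
- chain_a: D
  resno_a: 100
  resid_a: GLY
  chain_b: F
  resno_b: 188
  resid_b: ASP
  weight: 1.0
  target: .na.real
- chain_a: D
  resno_a: 6
  resid_a: LEU
  chain_b: F
  resno_b: 291
  resid_b: ARG
  weight: 1.0
  target: .na.real
- chain_a: C
  resno_a: 147
  resid_a: VAL
  chain_b: B
  resno_b: 94
  resid_b: GLY
  weight: 1.0
  target: .na.real
- chain_a: A
  resno_a: 31
  resid_a: .na.character
  chain_b: A
  resno_b: 32
  resid_b: .na.character
  weight: 1.0
  target: .na.real
- chain_a: A
  resno_a: 43
  resid_a: .na.character
  chain_b: A
  resno_b: 44
  resid_b: .na.character
  weight: 1.0
  target: .na.real
- chain_a: C
  resno_a: 59
  resid_a: .na.character
  chain_b: C
  resno_b: 60
  resid_b: .na.character
  weight: 1.0
  target: .na.real
- chain_a: C
  resno_a: 169
  resid_a: .na.character
  chain_b: C
  resno_b: 170
  resid_b: .na.character
  weight: 1.0
  target: .na.real
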