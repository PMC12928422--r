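NAP:
  name: naphthalene
  rings: 2
  tef: 0.001
  lod: 0.055
  loq: 0.165
ACY:
  name: acenaphthylene
  rings: 3
  tef: 0.001
  lod: 0.055
  loq: 0.165
PBN2:
  name: 2-bromonaphthalene
  rings: 2
  tef: 0.001
  lod: 0.063
  loq: 0.189
ACE:
  name: acenaphthene
  rings: 3
  tef: 0.001
  lod: 0.055
  loq: 0.165
FLR:
  name: fluorene
  rings: 3
  tef: 0.001
  lod: 0.063
  loq: 0.189
PHE:
  name: phenanthrene
  rings: 3
  tef: 0.001
  lod: 0.072
  loq: 0.216
ANT:
  name: anthracene
  rings: 3
  tef: 0.01
  lod: 0.045
  loq: 0.135
FLT:
  name: fluoranthene
  rings: 4
  tef: 0.001
  lod: 0.045
  loq: 0.135
PYR:
  name: pyrene
  rings: 4
  tef: 0.001
  lod: 0.072
  loq: 0.216
BaA:
  name: benzo[a]anthracene
  rings: 4
  tef: 0.1
  lod: 0.083
  loq: 0.249
CHR:
  name: chrysene
  rings: 4
  tef: 0.01
  lod: 0.055
  loq: 0.165
BbF:
  name: benzo[b]fluoranthene
  rings: 5
  tef: 0.1
  lod: 0.072
  loq: 0.216
BaP:
  name: benzo[a]pyrene
  rings: 5
  tef: 1.0
  lod: 0.063
  loq: 0.189
IP:
  name: indeno[1,2,3-cd]pyrene
  rings: 6
  tef: 0.1
  lod: 0.045
  loq: 0.135
DhA:
  name: dibenz[a,h]anthracene
  rings: 5
  tef: 1.0
  lod: 0.093
  loq: 0.279
BghiP:
  name: benzo[g,h,i]perylene
  rings: 6
  tef: 0.01
  lod: 0.063
  loq: 0.189
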