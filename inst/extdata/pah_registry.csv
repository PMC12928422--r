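"id","name","rings","tef","lod","loq"
"NAP","naphthalene",2,0.001,0.055,0.165
"ACY","acenaphthylene",3,0.001,0.055,0.165
"PBN2","2-bromonaphthalene",2,0.001,0.063,0.189
"ACE","acenaphthene",3,0.001,0.055,0.165
"FLR","fluorene",3,0.001,0.063,0.189
"PHE","phenanthrene",3,0.001,0.072,0.216
"ANT","anthracene",3,0.01,0.045,0.135
"FLT","fluoranthene",4,0.001,0.045,0.135
"PYR","pyrene",4,0.001,0.072,0.216
"BaA","benzo[a]anthracene",4,0.1,0.083,0.249
"CHR","chrysene",4,0.01,0.055,0.165
"BbF","benzo[b]fluoranthene",5,0.1,0.072,0.216
"BaP","benzo[a]pyrene",5,1,0.063,0.189
"IP","indeno[1,2,3-cd]pyrene",6,0.1,0.045,0.135
"DhA","dibenz[a,h]anthracene",5,1,0.093,0.279
"BghiP","benzo[g,h,i]perylene",6,0.01,0.063,0.189
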