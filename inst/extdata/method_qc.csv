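"id","linear_low","linear_high","r_squared","recovery_pct","rsd_pct"
"NAP",0.1,1000,0.984,98.2,8.9
"ACY",0.1,1000,0.991,95.2,7.7
"PBN2",0.1,1000,0.996,96.3,6.8
"ACE",0.1,1000,0.983,98.4,10.56
"FLR",0.1,1000,0.983,99.21,11.52
"PHE",0.1,1000,0.993,94.52,4.7
"ANT",0.1,1000,0.995,105.55,9.8
"FLT",0.1,1000,0.984,91.61,6.9
"PYR",0.1,1000,0.996,102.56,11.67
"BaA",0.1,1000,0.993,96.7,7.9
"CHR",0.1,1000,0.989,105.6,10.67
"BbF",0.1,1000,0.993,96.6,4.7
"BaP",0.1,1000,0.991,103.6,10.58
"IP",0.1,1000,0.997,91.6,6.9
"DhA",0.1,1000,0.987,93.6,8.6
"BghiP",0.1,1000,0.993,102.6,9.87
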