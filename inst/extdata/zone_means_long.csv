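sample_id,zone,method,bread_type,replicate,congener,value,censored
zone1,1,mixed,mixed,1,NAP,28.4,FALSE
zone1,1,mixed,mixed,1,ACY,0.43,FALSE
zone1,1,mixed,mixed,1,PBN2,4.44,FALSE
zone1,1,mixed,mixed,1,ACE,3.06,FALSE
zone1,1,mixed,mixed,1,FLR,1.69,FALSE
zone1,1,mixed,mixed,1,PHE,1.62,FALSE
zone1,1,mixed,mixed,1,ANT,1.52,FALSE
zone1,1,mixed,mixed,1,FLT,0.94,FALSE
zone1,1,mixed,mixed,1,PYR,1.24,FALSE
zone1,1,mixed,mixed,1,BaA,0.34,FALSE
zone1,1,mixed,mixed,1,CHR,0.65,FALSE
zone1,1,mixed,mixed,1,BbF,0.14,FALSE
zone1,1,mixed,mixed,1,BaP,0.04,FALSE
zone1,1,mixed,mixed,1,IP,ND,TRUE
zone1,1,mixed,mixed,1,DhA,ND,TRUE
zone1,1,mixed,mixed,1,BghiP,ND,TRUE
zone2,2,mixed,mixed,1,NAP,28.17,FALSE
zone2,2,mixed,mixed,1,ACY,0.46,FALSE
zone2,2,mixed,mixed,1,PBN2,6.37,FALSE
zone2,2,mixed,mixed,1,ACE,4.66,FALSE
zone2,2,mixed,mixed,1,FLR,3.2,FALSE
zone2,2,mixed,mixed,1,PHE,2.27,FALSE
zone2,2,mixed,mixed,1,ANT,2.51,FALSE
zone2,2,mixed,mixed,1,FLT,1.25,FALSE
zone2,2,mixed,mixed,1,PYR,1.15,FALSE
zone2,2,mixed,mixed,1,BaA,0.36,FALSE
zone2,2,mixed,mixed,1,CHR,0.59,FALSE
zone2,2,mixed,mixed,1,BbF,0.14,FALSE
zone2,2,mixed,mixed,1,BaP,0.04,FALSE
zone2,2,mixed,mixed,1,IP,ND,TRUE
zone2,2,mixed,mixed,1,DhA,ND,TRUE
zone2,2,mixed,mixed,1,BghiP,ND,TRUE
zone3,3,mixed,mixed,1,NAP,30.55,FALSE
zone3,3,mixed,mixed,1,ACY,0.49,FALSE
zone3,3,mixed,mixed,1,PBN2,6.51,FALSE
zone3,3,mixed,mixed,1,ACE,3.95,FALSE
zone3,3,mixed,mixed,1,FLR,2.08,FALSE
zone3,3,mixed,mixed,1,PHE,1.59,FALSE
zone3,3,mixed,mixed,1,ANT,1.62,FALSE
zone3,3,mixed,mixed,1,FLT, 1,FALSE
zone3,3,mixed,mixed,1,PYR,1.07,FALSE
zone3,3,mixed,mixed,1,BaA,0.35,FALSE
zone3,3,mixed,mixed,1,CHR,0.39,FALSE
zone3,3,mixed,mixed,1,BbF,0.08,FALSE
zone3,3,mixed,mixed,1,BaP,0.03,FALSE
zone3,3,mixed,mixed,1,IP,ND,TRUE
zone3,3,mixed,mixed,1,DhA,ND,TRUE
zone3,3,mixed,mixed,1,BghiP,ND,TRUE
zone4,4,mixed,mixed,1,NAP,30.43,FALSE
zone4,4,mixed,mixed,1,ACY,0.79,FALSE
zone4,4,mixed,mixed,1,PBN2, 5,FALSE
zone4,4,mixed,mixed,1,ACE,3.05,FALSE
zone4,4,mixed,mixed,1,FLR,2.34,FALSE
zone4,4,mixed,mixed,1,PHE,2.28,FALSE
zone4,4,mixed,mixed,1,ANT,2.08,FALSE
zone4,4,mixed,mixed,1,FLT,1.04,FALSE
zone4,4,mixed,mixed,1,PYR, 1,FALSE
zone4,4,mixed,mixed,1,BaA,0.3,FALSE
zone4,4,mixed,mixed,1,CHR,0.65,FALSE
zone4,4,mixed,mixed,1,BbF,0.15,FALSE
zone4,4,mixed,mixed,1,BaP,0.03,FALSE
zone4,4,mixed,mixed,1,IP,ND,TRUE
zone4,4,mixed,mixed,1,DhA,ND,TRUE
zone4,4,mixed,mixed,1,BghiP,ND,TRUE
zone5,5,mixed,mixed,1,NAP,36.02,FALSE
zone5,5,mixed,mixed,1,ACY,0.43,FALSE
zone5,5,mixed,mixed,1,PBN2,5.43,FALSE
zone5,5,mixed,mixed,1,ACE,2.82,FALSE
zone5,5,mixed,mixed,1,FLR,2.07,FALSE
zone5,5,mixed,mixed,1,PHE,1.96,FALSE
zone5,5,mixed,mixed,1,ANT,1.37,FALSE
zone5,5,mixed,mixed,1,FLT,0.56,FALSE
zone5,5,mixed,mixed,1,PYR,0.57,FALSE
zone5,5,mixed,mixed,1,BaA,0.19,FALSE
zone5,5,mixed,mixed,1,CHR,0.29,FALSE
zone5,5,mixed,mixed,1,BbF,0.06,FALSE
zone5,5,mixed,mixed,1,BaP,0.05,FALSE
zone5,5,mixed,mixed,1,IP,ND,TRUE
zone5,5,mixed,mixed,1,DhA,ND,TRUE
zone5,5,mixed,mixed,1,BghiP,ND,TRUE
zone6,6,mixed,mixed,1,NAP,31.28,FALSE
zone6,6,mixed,mixed,1,ACY,0.77,FALSE
zone6,6,mixed,mixed,1,PBN2,3.75,FALSE
zone6,6,mixed,mixed,1,ACE,1.69,FALSE
zone6,6,mixed,mixed,1,FLR,1.39,FALSE
zone6,6,mixed,mixed,1,PHE,1.18,FALSE
zone6,6,mixed,mixed,1,ANT,1.3,FALSE
zone6,6,mixed,mixed,1,FLT,0.85,FALSE
zone6,6,mixed,mixed,1,PYR,0.97,FALSE
zone6,6,mixed,mixed,1,BaA,0.31,FALSE
zone6,6,mixed,mixed,1,CHR,0.35,FALSE
zone6,6,mixed,mixed,1,BbF,0.09,FALSE
zone6,6,mixed,mixed,1,BaP,0.05,FALSE
zone6,6,mixed,mixed,1,IP,ND,TRUE
zone6,6,mixed,mixed,1,DhA,ND,TRUE
zone6,6,mixed,mixed,1,BghiP,ND,TRUE
zone7,7,mixed,mixed,1,NAP,45.44,FALSE
zone7,7,mixed,mixed,1,ACY,0.68,FALSE
zone7,7,mixed,mixed,1,PBN2,6.47,FALSE
zone7,7,mixed,mixed,1,ACE,3.96,FALSE
zone7,7,mixed,mixed,1,FLR, 3,FALSE
zone7,7,mixed,mixed,1,PHE,2.42,FALSE
zone7,7,mixed,mixed,1,ANT,1.97,FALSE
zone7,7,mixed,mixed,1,FLT,1.73,FALSE
zone7,7,mixed,mixed,1,PYR,1.94,FALSE
zone7,7,mixed,mixed,1,BaA,0.64,FALSE
zone7,7,mixed,mixed,1,CHR,0.68,FALSE
zone7,7,mixed,mixed,1,BbF,0.19,FALSE
zone7,7,mixed,mixed,1,BaP,0.12,FALSE
zone7,7,mixed,mixed,1,IP,ND,TRUE
zone7,7,mixed,mixed,1,DhA,ND,TRUE
zone7,7,mixed,mixed,1,BghiP,ND,TRUE
zone8,8,mixed,mixed,1,NAP,41.51,FALSE
zone8,8,mixed,mixed,1,ACY,0.74,FALSE
zone8,8,mixed,mixed,1,PBN2,6.8,FALSE
zone8,8,mixed,mixed,1,ACE,4.3,FALSE
zone8,8,mixed,mixed,1,FLR,3.34,FALSE
zone8,8,mixed,mixed,1,PHE,2.27,FALSE
zone8,8,mixed,mixed,1,ANT,2.17,FALSE
zone8,8,mixed,mixed,1,FLT,0.91,FALSE
zone8,8,mixed,mixed,1,PYR,0.99,FALSE
zone8,8,mixed,mixed,1,BaA,0.21,FALSE
zone8,8,mixed,mixed,1,CHR,0.83,FALSE
zone8,8,mixed,mixed,1,BbF,0.19,FALSE
zone8,8,mixed,mixed,1,BaP,0.12,FALSE
zone8,8,mixed,mixed,1,IP,ND,TRUE
zone8,8,mixed,mixed,1,DhA,ND,TRUE
zone8,8,mixed,mixed,1,BghiP,ND,TRUE
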