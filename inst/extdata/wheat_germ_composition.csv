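label,codes,g_per_100g
Asp+Asn,DN,8.40
Glu+Gln,EQ,15.28
Ser,S,4.40
His,H,3.15
Gly,G,6.19
Thr,T,3.94
Arg,R,9.79
Ala,A,6.41
Tyr,Y,2.97
Cys,C,0.39
Val,V,7.20
Met,M,1.70
Phe,F,5.22
Ile,I,4.94
Leu,L,8.07
Lys,K,6.33
Pro,P,5.63
Trp,W,0.69
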