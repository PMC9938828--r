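metal,season,n,mean,sd,min,max
Pb,winter,45,0.36,0.08,0.22,0.60
Pb,summer,45,0.50,0.62,0.11,3.80
Hg,winter,45,0.32,0.12,0.17,0.60
Hg,summer,45,0.20,0.11,0.10,0.60
Mn,winter,45,2.28,3.91,0.28,16.23
Mn,summer,45,0.55,0.57,0.19,3.68
Fe,winter,45,8.72,6.35,3.69,32.53
Fe,summer,45,10.36,3.04,6.86,26.64
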