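phenotype,n,mortality_pct,tamof_pct,mas_pct,ipmof_pct,smof_pct,npmof_pct
PedSep-A,136,2.2,0.0,0.0,8.8,0.0,20.6
PedSep-B,102,11.7,5.9,2.9,28.4,0.0,24.5
PedSep-C,110,10.0,2.7,1.8,20.0,0.9,29.1
PedSep-D,56,33.9,50.0,33.9,39.3,10.7,57.1
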