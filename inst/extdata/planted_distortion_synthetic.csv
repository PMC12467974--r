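"channel","c1","r","g","b","r2","g2","b2","rg","rb","gb"
"R",0.03,0.62,0.22,0.05,0.12,0,0,0,0,0
"G",0.05,0.12,0.7,0.06,0,0.1,0,0,0,0
"B",0.07,0.08,0.14,0.62,0,0,0.15,0,0,0
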