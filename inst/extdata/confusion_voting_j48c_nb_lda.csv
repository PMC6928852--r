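"","N","V","S","F","Q"
"N",38329,66,942,2678,0
"V",553,2532,20,1,0
"S",1405,2,416,14,0
"F",20,4,1,235,0
"Q",0,0,0,0,6
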