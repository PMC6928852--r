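"","N","V","S","F","Q"
"N",39542,53,489,1931,0
"V",395,2708,3,0,0
"S",1473,1,353,10,0
"F",22,5,1,232,0
"Q",0,0,0,0,6
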