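"","N","V","S"
"N",40918,361,736
"V",205,2897,4
"S",1469,3,365
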