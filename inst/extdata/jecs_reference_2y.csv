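sex,outcome,bp_percentile,h05,h10,h25,h50,h75,h90,h95
boy,SBP,50,90,90,91,91,92,92,92
boy,SBP,90,101,101,102,102,103,103,104
boy,SBP,95,105,105,105,106,106,107,107
boy,SBP,99,111,111,112,112,113,113,114
boy,DBP,50,51,51,51,52,52,53,53
boy,DBP,90,61,61,62,62,63,63,63
boy,DBP,95,64,64,65,65,66,66,66
boy,DBP,99,70,70,70,71,71,72,72
girl,SBP,50,89,89,90,90,91,91,92
girl,SBP,90,99,99,100,101,101,102,102
girl,SBP,95,102,102,103,103,104,105,105
girl,SBP,99,107,108,108,109,110,110,111
girl,DBP,50,51,51,51,52,52,53,53
girl,DBP,90,61,61,62,62,63,63,64
girl,DBP,95,64,64,65,65,66,66,67
girl,DBP,99,69,70,70,71,72,72,73
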