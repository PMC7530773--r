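"label","kind"
"V1",2
"V2",1
"V4",1
"DP",1
"MT",1
"8m",1
"5",1
"8l",1
"TEO",1
"2",1
"F1",1
"STPc",1
"7A",1
"46d",1
"10",1
"9/46v",1
"9/46d",1
"F5",1
"TEpd",1
"PBr",1
"7m",1
"LIP",1
"F2",1
"7B",1
"ProM",1
"STPi",1
"F7",1
"8B",1
"24c",1
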