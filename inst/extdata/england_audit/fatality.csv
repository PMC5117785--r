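"age_band","stage","rho"
"25.5-34","1A",0.014
"25.5-34","1B",0.088
"25.5-34","2",0.551
"25.5-34","3plus",0.8
"35-49","1A",0.014
"35-49","1B",0.086
"35-49","2",0.542
"35-49","3plus",0.792
"50-64","1A",0.025
"50-64","1B",0.109
"50-64","2",0.512
"50-64","3plus",0.86
"65-69","1A",0.021
"65-69","1B",0.091
"65-69","2",0.449
"65-69","3plus",0.805
"70-79","1A",0.015
"70-79","1B",0.148
"70-79","2",0.688
"70-79","3plus",0.951
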