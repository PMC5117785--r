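"diag_band","death_band","rr_no_screening","rr_no_screening_lo","rr_no_screening_hi","rr_all_regular","rr_all_regular_lo","rr_all_regular_hi","est_no_screening","est_all_regular"
"25-34","25-39",1.96,1.66,2.31,0.68,0.61,0.76,202,70
"35-49","40-54",4.13,3.59,4.75,0.42,0.38,0.47,721,73
"50-64","55-69",5.3,4.36,6.44,0.35,0.33,0.37,1054,70
"65-79","70-84",2.51,2.18,2.9,0.61,0.58,0.65,542,132
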