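"age_band","stage","category","or","lo","hi","se_log"
"25.5-34","1A","not_screened",1,1,1,0
"25.5-34","1A","regular",0.76,0.65,0.88,0.0772844672076112
"25.5-34","1A","irregular",0.95,0.8,1.12,0.0858363315028396
"25.5-34","1B","not_screened",1,1,1,0
"25.5-34","1B","regular",0.59,0.48,0.71,0.0998688928014392
"25.5-34","1B","irregular",0.72,0.58,0.88,0.106352414437253
"25.5-34","2","not_screened",1,1,1,0
"25.5-34","2","regular",0.28,0.17,0.43,0.23673566936872
"25.5-34","2","irregular",0.39,0.25,0.6,0.223337965457398
"25.5-34","3plus","not_screened",1,1,1,0
"25.5-34","3plus","regular",0.16,0.06,0.37,0.464079559054518
"25.5-34","3plus","irregular",0.27,0.13,0.56,0.37255846148018
"35-64","1A","not_screened",1,1,1,0
"35-64","1A","regular",0.33,0.27,0.38,0.0871825442757447
"35-64","1A","irregular",0.53,0.43,0.64,0.101451600846491
"35-64","1A","very_irregular",0.87,0.72,1.06,0.0986683883343847
"35-64","1B","not_screened",1,1,1,0
"35-64","1B","regular",0.25,0.21,0.28,0.073389632340436
"35-64","1B","irregular",0.38,0.31,0.46,0.10067893979607
"35-64","1B","very_irregular",0.62,0.51,0.74,0.0949607909675947
"35-64","2","not_screened",1,1,1,0
"35-64","2","regular",0.1,0.07,0.12,0.137501633954558
"35-64","2","irregular",0.17,0.12,0.22,0.154629321852707
"35-64","2","very_irregular",0.37,0.28,0.48,0.137501633954558
"35-64","3plus","not_screened",1,1,1,0
"35-64","3plus","regular",0.05,0.03,0.06,0.176826509575534
"35-64","3plus","irregular",0.1,0.06,0.14,0.216151385196509
"35-64","3plus","very_irregular",0.2,0.14,0.27,0.16754887884922
"65-79","1A","not_screened",1,1,1,0
"65-79","1A","regular",0.31,0.14,0.67,0.399404096739848
"65-79","1A","irregular",0.3,0.08,1.04,0.65433583925356
"65-79","1A","very_irregular",0.29,0.1,0.84,0.542926227889004
"65-79","1B","not_screened",1,1,1,0
"65-79","1B","regular",0.39,0.28,0.54,0.16754887884922
"65-79","1B","irregular",0.53,0.31,0.91,0.274717369943003
"65-79","1B","very_irregular",0.59,0.37,0.96,0.243226479247616
"65-79","2","not_screened",1,1,1,0
"65-79","2","regular",0.32,0.24,0.44,0.154629321852707
"65-79","2","irregular",0.29,0.18,0.48,0.250216141915969
"65-79","2","very_irregular",0.62,0.39,1.01,0.242749070446546
"65-79","3plus","not_screened",1,1,1,0
"65-79","3plus","regular",0.19,0.14,0.26,0.15792106724642
"65-79","3plus","irregular",0.23,0.14,0.37,0.247928173858009
"65-79","3plus","very_irregular",0.61,0.4,0.94,0.21796709911396
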