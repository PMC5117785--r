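"age_band","stage","category","count"
"25.5-34","1A","not_screened",560.7
"25.5-34","1A","regular",635.46
"25.5-34","1A","irregular",583.84
"25.5-34","1B","not_screened",395.963963963964
"25.5-34","1B","regular",312.24024024024
"25.5-34","1B","irregular",275.795795795796
"25.5-34","2","not_screened",117.058
"25.5-34","2","regular",60.99
"25.5-34","2","irregular",35.952
"25.5-34","3plus","not_screened",49.03003003003
"25.5-34","3plus","regular",28.042042042042
"25.5-34","3plus","irregular",9.92792792792793
"35-64","1A","not_screened",370.382617382617
"35-64","1A","regular",740.765234765235
"35-64","1A","irregular",326.243756243756
"35-64","1A","very_irregular",483.608391608392
"35-64","1B","not_screened",527.043043043043
"35-64","1B","regular",886.593593593594
"35-64","1B","irregular",343.917917917918
"35-64","1B","very_irregular",473.445445445445
"35-64","2","not_screened",407.423576423576
"35-64","2","regular",216.240759240759
"35-64","2","irregular",112.296703296703
"35-64","2","very_irregular",193.038961038961
"35-64","3plus","not_screened",430.848
"35-64","3plus","regular",115.192
"35-64","3plus","irregular",74.052
"35-64","3plus","very_irregular",127.908
"65-79","1A","not_screened",24
"65-79","1A","regular",30.989010989011
"65-79","1A","irregular",4.02197802197802
"65-79","1A","very_irregular",6.98901098901099
"65-79","1B","not_screened",108.018
"65-79","1B","regular",135.864
"65-79","1B","irregular",26.01
"65-79","1B","very_irregular",36.108
"65-79","2","not_screened",139.908
"65-79","2","regular",143.824
"65-79","2","irregular",28.124
"65-79","2","very_irregular",44.144
"65-79","3plus","not_screened",198.968
"65-79","3plus","regular",132.924
"65-79","3plus","irregular",30.932
"65-79","3plus","very_irregular",55.176
"25.5-34","unknown",NA,482.035358565737
"35-64","unknown",NA,916.732171314741
"65-79","unknown",NA,180.232470119522
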