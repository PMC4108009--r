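category,stratum,national_total,cost_per_infant
delivery,all,16722919,612
delivery,early,1057377,578
delivery,moderate,2920146,623
delivery,late,12745395,613
neonatal,all,374121486,13700
neonatal,early,97833950,53520
neonatal,moderate,198164090,42298
neonatal,late,78123447,3757
discharge_to_age2,all,94081058,3445
discharge_to_age2,early,16963439,9280
discharge_to_age2,moderate,30793148,6573
discharge_to_age2,late,46324421,2228
medical_2_4,all,32694477,1197
medical_2_4,early,2511003,1374
medical_2_4,moderate,9070596,1936
medical_2_4,late,21112878,1015
indirect_2_4,all,23662266,866
indirect_2_4,early,1599934,875
indirect_2_4,moderate,5322006,1136
indirect_2_4,late,16740327,805
medical_5_10,all,23901819,875
medical_5_10,early,1934994,1059
medical_5_10,moderate,5044290,1077
medical_5_10,late,16922535,814
indirect_5_10,all,21899601,802
indirect_5_10,early,1429570,782
indirect_5_10,moderate,4272425,912
indirect_5_10,late,16197606,779
total,all,587083627,21498
total,early,123330267,67467
total,moderate,255586702,54554
total,late,208166658,10010
total_psa_p2.5,all,507206197,18754
total_psa_p2.5,early,96510494,52796
total_psa_p2.5,moderate,216918336,46301
total_psa_p2.5,late,179848879,8649
total_psa_p97.5,all,732354145,26818
total_psa_p97.5,early,152099814,83206
total_psa_p97.5,moderate,311185320,66422
total_psa_p97.5,late,276500332,13296
total_with_sensitivity_layers,all,2430359101,88988
total_with_sensitivity_layers,early,216584016,118481
total_with_sensitivity_layers,moderate,576661757,123087
total_with_sensitivity_layers,late,1637113329,78726
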