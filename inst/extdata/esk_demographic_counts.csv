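block,category,count
sex,female,3652
sex,male,2037
sex,unknown,1198
age_group,<18,55
age_group,18-64,3395
age_group,>=65,532
age_group,unknown,2905
reporter_type,healthcare_professional,5428
reporter_type,consumer,1456
reporter_type,unknown,3
country,US,5494
country,FR,244
country,BR,135
country,DE,97
country,ES,94
country,Other,823
year,2019,677
year,2020,1082
year,2021,1311
year,2022,1540
year,2023,2277
seriousness,serious,4161
seriousness,non_serious,2726
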