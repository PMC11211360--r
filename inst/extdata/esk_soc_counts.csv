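soc,count,signal_pts
"Psychiatric disorders",4849,105
"Nervous system disorders",2435,71
"General disorders and administration site conditions",2075,58
"Injury, poisoning, and procedural complications",1136,47
"Gastrointestinal disorders",1041,23
"Investigations",500,24
"Vascular disorders",415,11
"Surgical and medical procedures",376,19
"Product issues",282,12
"Respiratory, thoracic, and mediastinal disorders",273,26
"Infections and infestations",229,18
"Renal and urinary disorders",159,17
"Eye disorders",148,14
"Cardiac disorders",138,10
"Musculoskeletal and connective tissue disorders",129,16
"Skin and subcutaneous tissue disorders",125,10
"Ear and labyrinth disorders",81,5
"Metabolism and nutrition disorders",72,10
"Immune system disorders",37,5
"Benign, malignant, and unspecified neoplasms (including cysts and polyps)",35,4
"Social circumstances",24,4
"Hepatobiliary disorders",24,5
"Pregnancy, puerperium, and perinatal conditions",14,2
"Endocrine disorders",5,1
"Reproductive system and breast disorders",4,1
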