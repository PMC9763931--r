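variable,group,age_weeks,mean,se
mass_g,LZR,7,149.7,1.5
mass_g,LZR,10,243.0,2.1
mass_g,LZR,13,307.2,2.0
mass_g,LZR,17,357.5,1.5
mass_g,LZR,20,374.3,2.6
mass_g,OZR,7,233.9,1.8
mass_g,OZR,10,409.4,2.6
mass_g,OZR,13,512.3,3.2
mass_g,OZR,17,682.3,2.5
mass_g,OZR,20,741.8,11.0
mass_g,OZR_EXERCISE,7,187.3,27.2
mass_g,OZR_EXERCISE,10,291.3,29.7
mass_g,OZR_EXERCISE,13,359.3,41.1
mass_g,OZR_EXERCISE,17,441.0,53.3
mass_g,OZR_CAPTOPRIL,7,239.0,2.7
mass_g,OZR_CAPTOPRIL,10,409.0,4.5
mass_g,OZR_CAPTOPRIL,13,515.3,4.6
mass_g,OZR_CAPTOPRIL,17,624.3,8.6
insulin_ng_ml,LZR,7,1.0,0.1
insulin_ng_ml,LZR,10,1.2,0.1
insulin_ng_ml,LZR,13,1.3,0.1
insulin_ng_ml,LZR,17,1.1,0.1
insulin_ng_ml,LZR,20,1.5,0.1
insulin_ng_ml,OZR,7,3.5,0.1
insulin_ng_ml,OZR,10,5.0,0.1
insulin_ng_ml,OZR,13,7.6,0.2
insulin_ng_ml,OZR,17,7.8,0.1
insulin_ng_ml,OZR,20,10.8,0.6
insulin_ng_ml,OZR_EXERCISE,7,1.7,0.4
insulin_ng_ml,OZR_EXERCISE,10,2.4,0.8
insulin_ng_ml,OZR_EXERCISE,13,3.6,1.5
insulin_ng_ml,OZR_EXERCISE,17,4.3,1.9
insulin_ng_ml,OZR_CAPTOPRIL,7,3.5,0.2
insulin_ng_ml,OZR_CAPTOPRIL,10,3.7,0.3
insulin_ng_ml,OZR_CAPTOPRIL,13,5.4,0.3
insulin_ng_ml,OZR_CAPTOPRIL,17,6.7,0.2
glucose_mg_dl,LZR,7,93.7,1.1
glucose_mg_dl,LZR,10,98.4,1.1
glucose_mg_dl,LZR,13,100.9,1.1
glucose_mg_dl,LZR,17,100.2,1.4
glucose_mg_dl,LZR,20,104.7,2.0
glucose_mg_dl,OZR,7,99.7,1.4
glucose_mg_dl,OZR,10,118.6,3.4
glucose_mg_dl,OZR,13,138.6,2.7
glucose_mg_dl,OZR,17,179.1,1.2
glucose_mg_dl,OZR,20,182.6,2.7
glucose_mg_dl,OZR_EXERCISE,7,93.5,5.4
glucose_mg_dl,OZR_EXERCISE,10,94.0,5.0
glucose_mg_dl,OZR_EXERCISE,13,105.0,6.6
glucose_mg_dl,OZR_EXERCISE,17,119.0,12.1
glucose_mg_dl,OZR_CAPTOPRIL,7,99.0,3.5
glucose_mg_dl,OZR_CAPTOPRIL,10,100.0,2.5
glucose_mg_dl,OZR_CAPTOPRIL,13,123.5,2.5
glucose_mg_dl,OZR_CAPTOPRIL,17,137.5,5.3
ntyr_ng_dl,LZR,7,9.2,0.3
ntyr_ng_dl,LZR,10,10.4,0.3
ntyr_ng_dl,LZR,13,12.8,0.3
ntyr_ng_dl,LZR,17,16.5,0.6
ntyr_ng_dl,LZR,20,18.2,1.0
ntyr_ng_dl,OZR,7,15.0,0.4
ntyr_ng_dl,OZR,10,24.8,0.4
ntyr_ng_dl,OZR,13,45.4,1.1
ntyr_ng_dl,OZR,17,51.7,0.9
ntyr_ng_dl,OZR,20,59.6,1.0
ntyr_ng_dl,OZR_EXERCISE,7,10.3,0.7
ntyr_ng_dl,OZR_EXERCISE,10,11.8,1.3
ntyr_ng_dl,OZR_EXERCISE,13,19.0,4.7
ntyr_ng_dl,OZR_EXERCISE,17,20.5,6.3
ntyr_ng_dl,OZR_CAPTOPRIL,7,13.0,0.6
ntyr_ng_dl,OZR_CAPTOPRIL,10,16.0,0.7
ntyr_ng_dl,OZR_CAPTOPRIL,13,24.5,0.3
ntyr_ng_dl,OZR_CAPTOPRIL,17,34.0,0.9
tnfa_pg_ml,LZR,7,1.7,0.1
tnfa_pg_ml,LZR,10,2.0,0.1
tnfa_pg_ml,LZR,13,2.4,0.2
tnfa_pg_ml,LZR,17,2.2,0.1
tnfa_pg_ml,LZR,20,2.6,0.2
tnfa_pg_ml,OZR,7,4.5,0.2
tnfa_pg_ml,OZR,10,8.6,0.3
tnfa_pg_ml,OZR,13,10.9,0.2
tnfa_pg_ml,OZR,17,8.1,0.3
tnfa_pg_ml,OZR,20,13.3,0.4
tnfa_pg_ml,OZR_EXERCISE,7,1.8,0.3
tnfa_pg_ml,OZR_EXERCISE,10,2.8,0.8
tnfa_pg_ml,OZR_EXERCISE,13,3.3,1.0
tnfa_pg_ml,OZR_EXERCISE,17,3.5,1.2
tnfa_pg_ml,OZR_CAPTOPRIL,7,3.5,0.3
tnfa_pg_ml,OZR_CAPTOPRIL,10,6.5,0.7
tnfa_pg_ml,OZR_CAPTOPRIL,13,7.0,0.9
tnfa_pg_ml,OZR_CAPTOPRIL,17,9.5,0.7
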