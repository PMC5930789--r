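block,level,m1,m0
n,patients,1285,1081
age_group,<50,10.9,6.8
age_group,50-54,6.9,5.9
age_group,55-59,8.9,8.6
age_group,60-64,10.4,10.5
age_group,65-69,13.3,11.8
age_group,70+,49.6,56.2
sex,F,35,35.5
charlson_category,no_prev_hosp,56.9,47.8
charlson_category,0,28.6,30.6
charlson_category,1,12.5,4.7
charlson_category,2+,6.9,11
tumour_location,distal,32.9,43.8
tumour_location,entire,9.8,5.1
tumour_location,GEJ,27.3,23.5
tumour_location,middle,15.6,17.1
tumour_location,proximal,9.8,6.9
tumour_location,unknown,4.7,3.6
deaths,one_year,71.9,32.5
deaths,five_years,94.6,64.7
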