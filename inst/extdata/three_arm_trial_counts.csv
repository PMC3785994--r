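factor,level,arm_1,arm_2,arm_3,total_printed,max_diff_printed
age,18-44,21,19,20,60,2
age,45-64,52,46,48,146,6
age,65-79,8,13,12,33,5
age,80-100,0,1,1,2,1
glucose,0-99,39,34,37,110,5
glucose,100-109,31,30,31,92,1
glucose,110-119,7,11,13,31,6
glucose,120-125,4,4,0,8,4
bmi,25-29.9,38,37,38,113,1
bmi,30-34.9,25,27,24,76,3
bmi,35-39.9,12,9,11,32,3
bmi,>=40,6,6,8,20,2
gender,Male,44,41,44,129,3
gender,Female,37,38,37,112,1
phr_access,No,15,15,18,48,3
phr_access,Yes,66,64,63,193,3
race,Hispanic,2,4,4,10,2
race,Asian/Pacific Islander,14,13,14,41,1
race,Non-Hispanic white,64,61,63,188,3
race,Other,1,1,0,2,1
waist,<37,9,10,11,30,2
waist,37-<40,23,19,21,63,4
waist,40-<42,15,16,14,45,2
waist,>=42,34,34,35,103,1
Total,,81,79,81,241,2
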