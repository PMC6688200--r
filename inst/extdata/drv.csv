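nutrient,unit,value_men,value_women,role,source
protein,g,112.5,90,encourage,NNR 2012 (18 energy percent of 2500/2000 kcal)
fiber,g,35,25,encourage,NNR 2012
vitamin_a,ug,750,650,encourage,EFSA
vitamin_c,mg,110,95,encourage,EFSA
vitamin_e,mg,13,11,encourage,EFSA
calcium,mg,1200,1200,encourage,HCNL
iron,mg,11,11,encourage,EFSA
magnesium,mg,350,300,encourage,EFSA
potassium,mg,3500,3500,encourage,EFSA
vitamin_d,ug,20,20,encourage,HCNL/NNR
folate,ug,330,330,encourage,EFSA
vitamin_b12,ug,2.8,2.8,encourage,HCNL
zinc,mg,11.7,9.3,encourage,EFSA (mixed diet with 600 mg phytate)
selenium,ug,70,70,encourage,EFSA
iodine,ug,150,150,encourage,EFSA
copper,mg,1.6,1.3,encourage,EFSA
vitamin_b2,mg,1.6,1.6,encourage,EFSA
pufa,g,22.2,17.8,encourage,NNR 2012 (8 energy percent of 2500/2000 kcal)
vitamin_b1,mg,1.0,0.8,encourage,EFSA (0.4 mg per 1000 kcal)
vitamin_b6,mg,1.7,1.6,encourage,EFSA
saturated_fat,g,20,20,limit,EFSA labeling reference
sugar,g,90,90,limit,EFSA labeling reference
sodium,mg,2400,2400,limit,EFSA labeling reference (6 g salt / 2.5)
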