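"group","nutrient_id","goal_type","value","unit","note"
"females_19_30","energy","goal",2000,"kcal",""
"females_19_30","protein","RDA",46,"g",""
"females_19_30","carbohydrate","RDA",130,"g",""
"females_19_30","fiber","AI",28,"g",""
"females_19_30","linoleic_acid","AI",12,"g",""
"females_19_30","linolenic_acid","AI",1.1,"g",""
"females_19_30","calcium","RDA",1000,"mg",""
"females_19_30","iron","RDA",18,"mg",""
"females_19_30","magnesium","RDA",310,"mg",""
"females_19_30","phosphorus","RDA",700,"mg",""
"females_19_30","potassium","AI",4700,"mg","2005 DRI AI consistent with printed grid, not the 2019 revision"
"females_19_30","sodium","UL",2300,"mg","UL framing; numerically equal to the 2019 CDRR"
"females_19_30","zinc","RDA",8,"mg",""
"females_19_30","copper","RDA",0.9,"mg",""
"females_19_30","selenium","RDA",55,"mg",""
"females_19_30","vitamin_a","RDA",700,"ug_RAE",""
"females_19_30","vitamin_e","RDA",15,"mg_AT",""
"females_19_30","vitamin_d","RDA",600,"IU",""
"females_19_30","vitamin_c","RDA",75,"mg",""
"females_19_30","thiamin","RDA",1.1,"mg",""
"females_19_30","riboflavin","RDA",1.1,"mg",""
"females_19_30","niacin","RDA",14,"mg",""
"females_19_30","vitamin_b6","RDA",1.3,"mg",""
"females_19_30","vitamin_b12","RDA",2.4,"mg",""
"females_19_30","choline","AI",425,"mg","AI; printed grid labels the row % RDA"
"females_19_30","vitamin_k","AI",90,"mg","AI; printed grid labels the row % RDA"
"males_51plus","energy","goal",2000,"kcal",""
"males_51plus","protein","RDA",56,"g",""
"males_51plus","carbohydrate","RDA",130,"g",""
"males_51plus","fiber","AI",28,"g",""
"males_51plus","linoleic_acid","AI",14,"g",""
"males_51plus","linolenic_acid","AI",1.6,"g",""
"males_51plus","calcium","RDA",1200,"mg",""
"males_51plus","iron","RDA",8,"mg",""
"males_51plus","magnesium","RDA",420,"mg",""
"males_51plus","phosphorus","RDA",700,"mg",""
"males_51plus","potassium","AI",4700,"mg","2005 DRI AI consistent with printed grid, not the 2019 revision"
"males_51plus","sodium","UL",2300,"mg","UL framing; numerically equal to the 2019 CDRR"
"males_51plus","zinc","RDA",11,"mg",""
"males_51plus","copper","RDA",0.9,"mg",""
"males_51plus","selenium","RDA",55,"mg",""
"males_51plus","vitamin_a","RDA",900,"ug_RAE",""
"males_51plus","vitamin_e","RDA",15,"mg_AT",""
"males_51plus","vitamin_d","RDA",600,"IU",""
"males_51plus","vitamin_c","RDA",90,"mg",""
"males_51plus","thiamin","RDA",1.2,"mg",""
"males_51plus","riboflavin","RDA",1.3,"mg",""
"males_51plus","niacin","RDA",16,"mg",""
"males_51plus","vitamin_b6","RDA",1.7,"mg",""
"males_51plus","vitamin_b12","RDA",2.4,"mg",""
"males_51plus","choline","AI",550,"mg","AI; printed grid labels the row % RDA"
"males_51plus","vitamin_k","AI",120,"mg","AI; printed grid labels the row % RDA"
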