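"nutrient_id","label","unit","display_precision","category","in_composite_table","reconstructible","unit_note"
"energy","Calories","kcal",0,"macronutrient",TRUE,TRUE,""
"protein","Protein","g",0,"macronutrient",TRUE,TRUE,""
"carbohydrate","Carbohydrate","g",0,"macronutrient",TRUE,TRUE,""
"fiber","Fiber, total dietary","g",0,"macronutrient",FALSE,TRUE,"absent from dairy composite table; dairy contributes none"
"total_fat","Total lipid (fat)","g",0,"macronutrient",TRUE,TRUE,""
"saturated_fat","Saturated fats","g",1,"macronutrient",TRUE,TRUE,""
"monounsaturated_fat","Monounsaturated fats","g",1,"macronutrient",FALSE,FALSE,""
"polyunsaturated_fat","Polyunsaturated fats","g",1,"macronutrient",FALSE,FALSE,""
"linoleic_acid","Linoleic acid (18:2)","g",1,"macronutrient",FALSE,FALSE,""
"linolenic_acid","Linolenic acid (18:3)","g",1,"macronutrient",FALSE,FALSE,""
"epa","EPA (20:5 n-3)","g",2,"macronutrient",FALSE,FALSE,""
"dha","DHA (22:6 n-3)","g",2,"macronutrient",FALSE,FALSE,""
"stearic_acid","Stearic acid (18:0)","g",2,"macronutrient",FALSE,FALSE,""
"cholesterol","Cholesterol","mg",0,"macronutrient",TRUE,TRUE,""
"calcium","Calcium","mg",0,"mineral",TRUE,TRUE,""
"iron","Iron","mg",0,"mineral",FALSE,FALSE,""
"magnesium","Magnesium","mg",0,"mineral",TRUE,TRUE,""
"phosphorus","Phosphorus","mg",0,"mineral",TRUE,TRUE,""
"potassium","Potassium","mg",0,"mineral",TRUE,TRUE,""
"sodium","Sodium","mg",0,"mineral",TRUE,TRUE,""
"zinc","Zinc","mg",0,"mineral",TRUE,TRUE,""
"copper","Copper","mg",1,"mineral",FALSE,FALSE,""
"selenium","Selenium","mg",0,"mineral",TRUE,TRUE,"printed unit as-is; conventionally ug"
"vitamin_a","Vitamin A","ug_RAE",0,"vitamin",TRUE,TRUE,"printed header mg_RAE; stored as ug RAE"
"vitamin_e","Vitamin E","mg_AT",1,"vitamin",TRUE,TRUE,""
"vitamin_d","Vitamin D","IU",0,"vitamin",TRUE,TRUE,""
"vitamin_c","Vitamin C","mg",0,"vitamin",TRUE,TRUE,""
"thiamin","Thiamin","mg",1,"vitamin",TRUE,TRUE,""
"riboflavin","Riboflavin","mg",1,"vitamin",TRUE,TRUE,""
"niacin","Niacin","mg",0,"vitamin",TRUE,TRUE,""
"vitamin_b6","Vitamin B-6","mg",1,"vitamin",TRUE,TRUE,""
"vitamin_b12","Vitamin B-12","mg",1,"vitamin",TRUE,TRUE,"printed unit as-is; conventionally ug"
"choline","Choline","mg",0,"vitamin",TRUE,TRUE,""
"vitamin_k","Vitamin K","mg",0,"vitamin",TRUE,TRUE,"printed unit as-is; conventionally ug"
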