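"model","nutrient_id","total","pct_change","pct_change_flag"
"model1","energy",2006,NA,""
"model1","protein",95,NA,""
"model1","carbohydrate",259,NA,""
"model1","fiber",30,NA,""
"model1","total_fat",70,NA,""
"model1","saturated_fat",17.3,NA,""
"model1","monounsaturated_fat",25.5,NA,""
"model1","polyunsaturated_fat",22.3,NA,""
"model1","linoleic_acid",19.5,NA,""
"model1","linolenic_acid",2.3,NA,""
"model1","epa",0.07,NA,""
"model1","dha",0.15,NA,""
"model1","stearic_acid",4.39,NA,""
"model1","cholesterol",222,NA,""
"model1","calcium",1491,NA,""
"model1","iron",17,NA,""
"model1","magnesium",426,NA,""
"model1","phosphorus",1667,NA,""
"model1","potassium",3571,NA,""
"model1","sodium",2378,NA,""
"model1","zinc",16,NA,""
"model1","copper",1.9,NA,""
"model1","selenium",113,NA,""
"model1","vitamin_a",858,NA,""
"model1","vitamin_e",10.3,NA,""
"model1","vitamin_d",280,NA,""
"model1","vitamin_c",117,NA,""
"model1","thiamin",2,NA,""
"model1","riboflavin",2.4,NA,""
"model1","niacin",28,NA,""
"model1","vitamin_b6",2.7,NA,""
"model1","vitamin_b12",7.7,NA,""
"model1","choline",366,NA,""
"model1","vitamin_k",139,NA,""
"model2","energy",2055,2.4,""
"model2","protein",94,-1.1,""
"model2","carbohydrate",258,-0.1,""
"model2","fiber",30,0,""
"model2","total_fat",76,8.6,""
"model2","saturated_fat",21.1,21.9,""
"model2","monounsaturated_fat",27.3,6.8,""
"model2","polyunsaturated_fat",22.5,0.9,""
"model2","linoleic_acid",19.6,0.7,""
"model2","linolenic_acid",2.3,2.1,""
"model2","epa",0.07,0,""
"model2","dha",0.15,0,""
"model2","stearic_acid",5.09,16,""
"model2","cholesterol",236,6.5,""
"model2","calcium",1419,-4.8,""
"model2","iron",17,0.2,""
"model2","magnesium",404,-5.1,""
"model2","phosphorus",1789,7.3,""
"model2","potassium",3534,-1,""
"model2","sodium",2353,-1.1,""
"model2","zinc",15,-2.5,""
"model2","copper",1.7,-7.7,""
"model2","selenium",112,-1.1,""
"model2","vitamin_a",903,5.2,""
"model2","vitamin_e",10.4,0.3,""
"model2","vitamin_d",334,19.3,""
"model2","vitamin_c",117,0.2,""
"model2","thiamin",1.9,-4.9,""
"model2","riboflavin",2.3,-0.7,""
"model2","niacin",27,-5,""
"model2","vitamin_b6",2.6,-4.7,""
"model2","vitamin_b12",7.5,-2.1,""
"model2","choline",366,0.1,""
"model2","vitamin_k",140,0.6,""
"model3","energy",2084,3.9,""
"model3","protein",93,-1.9,""
"model3","carbohydrate",258,-0.4,""
"model3","fiber",30,0,""
"model3","total_fat",80,14.3,""
"model3","saturated_fat",22.9,32.7,""
"model3","monounsaturated_fat",28,9.7,""
"model3","polyunsaturated_fat",22.8,2.2,""
"model3","linoleic_acid",19.8,1.8,""
"model3","linolenic_acid",2.4,4.9,""
"model3","epa",0.07,3,""
"model3","dha",0.15,0.4,""
"model3","stearic_acid",5.41,23.3,""
"model3","cholesterol",246,10.8,""
"model3","calcium",1624,9,""
"model3","iron",17,1.4,""
"model3","magnesium",403,-5.4,""
"model3","phosphorus",1758,5.5,""
"model3","potassium",3507,-1.8,""
"model3","sodium",2366,-0.5,""
"model3","zinc",15,-3.8,""
"model3","copper",1.8,-6.6,""
"model3","selenium",114,0.8,""
"model3","vitamin_a",899,4.8,""
"model3","vitamin_e",10.5,2.2,""
"model3","vitamin_d",351,25.4,""
"model3","vitamin_c",117,0,""
"model3","thiamin",1.9,-4.9,""
"model3","riboflavin",2.3,-2.3,""
"model3","niacin",27,-5,""
"model3","vitamin_b6",2.6,-4.4,""
"model3","vitamin_b12",7.5,-2.2,""
"model3","choline",364,-0.6,""
"model3","vitamin_k",140,0.8,""
"model4","energy",2074,3.4,""
"model4","protein",92,-2.6,""
"model4","carbohydrate",261,0.9,""
"model4","fiber",30,0,""
"model4","total_fat",77,11,""
"model4","saturated_fat",21.7,25.5,""
"model4","monounsaturated_fat",27.5,7.5,""
"model4","polyunsaturated_fat",22.8,2.2,""
"model4","linoleic_acid",19.8,1.5,""
"model4","linolenic_acid",2.5,7.9,""
"model4","epa",0.07,0,""
"model4","dha",0.15,0,""
"model4","stearic_acid",5.25,19.7,""
"model4","cholesterol",237,6.6,""
"model4","calcium",1395,-6.4,""
"model4","iron",17,0.2,""
"model4","magnesium",405,-4.8,""
"model4","phosphorus",1653,-0.8,""
"model4","potassium",3578,0.2,""
"model4","sodium",2082,-12.4,""
"model4","zinc",15,-4.9,""
"model4","copper",1.8,-5.4,""
"model4","selenium",115,1,""
"model4","vitamin_a",885,30,"suspected_typo"
"model4","vitamin_e",10.4,0.8,""
"model4","vitamin_d",344,22.6,""
"model4","vitamin_c",117,-0.1,""
"model4","thiamin",1.9,-2.7,""
"model4","riboflavin",2.4,1.2,""
"model4","niacin",27,-4.8,""
"model4","vitamin_b6",2.6,-4,""
"model4","vitamin_b12",7.6,-0.6,""
"model4","choline",370,1.3,""
"model4","vitamin_k",140,0.5,""
"model5","energy",2048,2.1,""
"model5","protein",93,-2.2,""
"model5","carbohydrate",261,0.9,""
"model5","fiber",30,0,""
"model5","total_fat",74,6.7,""
"model5","saturated_fat",20.2,17,""
"model5","monounsaturated_fat",26.9,5.1,""
"model5","polyunsaturated_fat",22.5,0.8,""
"model5","linoleic_acid",19.6,0.8,""
"model5","linolenic_acid",2.3,0.8,""
"model5","epa",0.07,0,""
"model5","dha",0.15,0,""
"model5","stearic_acid",4.96,13,""
"model5","cholesterol",232,4.5,""
"model5","calcium",1411,-5.3,""
"model5","iron",17,0,""
"model5","magnesium",408,-4.3,""
"model5","phosphorus",1673,0.3,""
"model5","potassium",3598,0.8,""
"model5","sodium",2092,-12,""
"model5","zinc",15,-3.2,""
"model5","copper",1.7,-7.8,""
"model5","selenium",112,1.5,""
"model5","vitamin_a",905,5.5,""
"model5","vitamin_e",10.3,-0.1,""
"model5","vitamin_d",334,19.2,""
"model5","vitamin_c",117,0.3,""
"model5","thiamin",1.9,-3.6,""
"model5","riboflavin",2.4,2.9,""
"model5","niacin",27,-4.8,""
"model5","vitamin_b6",2.6,-3.9,""
"model5","vitamin_b12",7.8,2,""
"model5","choline",375,2.7,""
"model5","vitamin_k",140,0.3,""
"model6","energy",2097,4.5,""
"model6","protein",94,-1.2,""
"model6","carbohydrate",254,-1.7,""
"model6","fiber",30,0,""
"model6","total_fat",82,18.1,""
"model6","saturated_fat",24.3,40.7,""
"model6","monounsaturated_fat",28.6,12.1,""
"model6","polyunsaturated_fat",22.8,2.4,""
"model6","linoleic_acid",19.9,2.2,""
"model6","linolenic_acid",2.3,2.2,""
"model6","epa",0.07,6.3,""
"model6","dha",0.15,0.7,""
"model6","stearic_acid",5.6,27.7,""
"model6","cholesterol",255,15.2,""
"model6","calcium",1880,26.1,""
"model6","iron",17,2.8,""
"model6","magnesium",400,-6.1,""
"model6","phosphorus",1874,12.4,""
"model6","potassium",3424,-4.1,""
"model6","sodium",2683,12.8,""
"model6","zinc",15,-2.8,""
"model6","copper",1.7,-7.8,""
"model6","selenium",115,1,""
"model6","vitamin_a",922,7.4,""
"model6","vitamin_e",10.7,3.7,""
"model6","vitamin_d",362,29.1,""
"model6","vitamin_c",117,-0.1,""
"model6","thiamin",1.8,-7.2,""
"model6","riboflavin",2.2,-6,""
"model6","niacin",27,-5.2,""
"model6","vitamin_b6",2.6,-4.7,""
"model6","vitamin_b12",7.4,-3.7,""
"model6","choline",356,-2.7,""
"model6","vitamin_k",141,1.2,""
"model7","energy",2060,27,"suspected_typo"
"model7","protein",95,-0.3,""
"model7","carbohydrate",255,-1.3,""
"model7","fiber",30,0,""
"model7","total_fat",77,11,""
"model7","saturated_fat",22.1,27.7,""
"model7","monounsaturated_fat",27.8,8.8,""
"model7","polyunsaturated_fat",22.5,1,""
"model7","linoleic_acid",19.6,0.8,""
"model7","linolenic_acid",2.4,3.6,""
"model7","epa",0.07,0,""
"model7","dha",0.15,0,""
"model7","stearic_acid",5.26,19.9,""
"model7","cholesterol",242,9,""
"model7","calcium",1414,-5.1,""
"model7","iron",17,0.4,""
"model7","magnesium",399,-6.2,""
"model7","phosphorus",1908,14.4,""
"model7","potassium",3443,-3.6,""
"model7","sodium",2640,11,""
"model7","zinc",15,-2.3,""
"model7","copper",1.7,-7.7,""
"model7","selenium",113,-0.8,""
"model7","vitamin_a",911,6.2,""
"model7","vitamin_e",10.4,0.7,""
"model7","vitamin_d",335,19.7,""
"model7","vitamin_c",117,-0.1,""
"model7","thiamin",1.9,-6.3,""
"model7","riboflavin",2.2,-4.8,""
"model7","niacin",27,-5.2,""
"model7","vitamin_b6",2.6,-5.6,""
"model7","vitamin_b12",7.2,-6.7,""
"model7","choline",356,-2.6,""
"model7","vitamin_k",141,1,""
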