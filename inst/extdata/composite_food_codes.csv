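"composite","group","fat_tier","food_code","note"
"A","milk","fat_free","11113000",""
"A","cheese","fat_free","14410130",""
"A","yogurt","fat_free","11411300",""
"B","milk","reduced_fat","11112110",""
"B","cheese","reduced_fat","14410120",""
"B","yogurt","low_fat","11411200",""
"C","milk","whole","11111000",""
"C","cheese","whole","14410110",""
"C","yogurt","whole","11411000","source prints 7-digit 1141100; stored as likely 8-digit code"
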