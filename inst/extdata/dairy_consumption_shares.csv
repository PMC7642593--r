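"era","component","share_pct","used_in_modeling"
"2013-2016","milk",47.76,TRUE
"2013-2016","cheese",47.3,TRUE
"2013-2016","yogurt",4.93,TRUE
"2009-2010","milk",51,FALSE
"2009-2010","cheese",44.8,FALSE
"2009-2010","yogurt",2.6,FALSE
"2009-2010","soymilk",1.5,FALSE
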