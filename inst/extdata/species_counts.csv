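species,treatment,count,migratory_tree_bat
big brown bat,control,27,FALSE
big brown bat,WOC,8,FALSE
big brown bat,TIMR,7,FALSE
eastern red bat,control,37,TRUE
eastern red bat,WOC,19,TRUE
eastern red bat,TIMR,6,TRUE
hoary bat,control,48,TRUE
hoary bat,WOC,18,TRUE
hoary bat,TIMR,11,TRUE
little brown bat,control,29,FALSE
little brown bat,WOC,15,FALSE
little brown bat,TIMR,3,FALSE
silver-haired bat,control,45,TRUE
silver-haired bat,WOC,17,TRUE
silver-haired bat,TIMR,4,TRUE
tri-colored bat,control,1,FALSE
tri-colored bat,WOC,1,FALSE
tri-colored bat,TIMR,0,FALSE
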