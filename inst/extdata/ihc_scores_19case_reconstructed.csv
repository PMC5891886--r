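"case_id","epithelium_score","stroma_score"
"case_01",3,0
"case_02",3,1
"case_03",3,1
"case_04",3,1
"case_05",3,1
"case_06",3,1
"case_07",3,1
"case_08",2,0
"case_09",2,0
"case_10",2,0
"case_11",3,2
"case_12",2,2
"case_13",2,1
"case_14",2,1
"case_15",2,1
"case_16",2,1
"case_17",2,1
"case_18",1,1
"case_19",1,0
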