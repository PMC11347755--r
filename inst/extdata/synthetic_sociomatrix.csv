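"","F01","F02","F03","F04","F05","F06"
"F01",0,12,10,11,12,9
"F02",1,0,11,17,11,10
"F03",0,1,0,11,16,8
"F04",0,0,0,0,12,12
"F05",0,0,1,4,0,7
"F06",0,0,1,2,2,0
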