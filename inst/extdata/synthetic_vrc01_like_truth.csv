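"id","l11","l12","l21","l22","l23","N","Delta"
"bcr_1",53,4,39,0,2,6,-4
"bcr_2",50,7,39,0,2,9,-7
"bcr_3",56,1,40,0,1,2,-1
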