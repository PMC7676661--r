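site,mt_A,mt_C,mt_M,hi_african,hi_hybrid,hi_european,hi_na,n
MUS01,0,1,0,0,1,0,0,1
MUS02,19,0,0,12,7,0,0,19
MUS03,0,1,0,0,1,0,0,1
MUS04,9,0,0,4,4,0,1,9
MUS05,1,2,0,1,2,0,0,3
MUS06,9,0,0,5,3,0,1,9
MUS07,12,1,0,3,9,0,1,13
MUS08,14,1,2,5,12,0,0,17
MUS09,6,16,2,3,17,2,2,24
MUS12,19,1,0,9,10,0,1,20
MUS13,0,3,0,0,3,0,0,3
MUS14,1,0,0,1,0,0,0,1
MUS15,4,4,0,3,5,0,0,8
MUS16,13,0,0,8,4,0,1,13
MUS17,13,1,0,3,10,0,1,14
MUS18,21,1,0,11,11,0,0,22
MUS19,4,9,0,2,10,1,0,13
MUS20,0,70,0,0,48,17,5,70
MUS21,1,18,0,0,11,6,2,19
MUS22,1,0,0,1,0,0,0,1
MUS23,1,0,0,1,0,0,0,1
MUS24,2,0,0,1,1,0,0,2
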