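reference,DR0,DR1,DR2,DR3,PRP,Other,Disqualification
No DR,5377,290,782,223,23,74,2497
Mild NPDR,213,152,88,5,1,7,152
Moderate NPDR,176,111,583,129,3,4,184
Severe NPDR,0,0,6,65,0,0,1
PDR,0,0,1,8,0,0,3
PRP,5,5,28,20,28,0,16
Other,39,10,71,86,17,1,51
Disqualification,203,50,595,391,30,3,7097
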