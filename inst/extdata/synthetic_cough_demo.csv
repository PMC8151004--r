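doc_id,textbook,disease,ap_code,count
DEBG.cough,DEBG,cough,BL13,6
DEBG.cough,DEBG,cough,BL43,1
DEBG.cough,DEBG,cough,GV12,2
DEBG.cough,DEBG,cough,GV14,1
DEBG.cough,DEBG,cough,CV22,3
DEBG.cough,DEBG,cough,CV17,2
DEBG.cough,DEBG,cough,CV6,1
DEBG.cough,DEBG,cough,LU5,1
DEBG.cough,DEBG,cough,LU7,2
DEBG.cough,DEBG,cough,LU9,1
DEBG.cough,DEBG,cough,LU11,1
DEBG.cough,DEBG,cough,ST36,1
DEBG.cough,DEBG,cough,KI27,1
DEBG.cough,DEBG,cough,BL23,1
DEBG.cough,DEBG,cough,HT7,1
DEBG.cough,DEBG,cough,SP6,1
DEBG.cough,DEBG,cough,PC6,1
DEBG.cough,DEBG,cough,GB20,1
SADI.cough,SADI,cough,SP3,3
SADI.cough,SADI,cough,SP2,2
SADI.cough,SADI,cough,SP5,1
SADI.cough,SADI,cough,SP9,1
SADI.cough,SADI,cough,LU5,1
SADI.cough,SADI,cough,LU8,2
SADI.cough,SADI,cough,LU9,2
SADI.cough,SADI,cough,LU10,1
SADI.cough,SADI,cough,HT8,1
SADI.cough,SADI,cough,KI2,1
SADI.cough,SADI,cough,KI10,1
SADI.cough,SADI,cough,ST45,1
SADI.cough,SADI,cough,LR4,1
SADI.cough,SADI,cough,PC8,1
CGGHB.cough,CGGHB,cough,LI4,6
CGGHB.cough,CGGHB,cough,BL13,4
CGGHB.cough,CGGHB,cough,LU9,2
CGGHB.cough,CGGHB,cough,LU7,2
CGGHB.cough,CGGHB,cough,LU5,1
CGGHB.cough,CGGHB,cough,HT7,2
CGGHB.cough,CGGHB,cough,ST36,2
CGGHB.cough,CGGHB,cough,TE4,1
CGGHB.cough,CGGHB,cough,GB40,1
CGGHB.cough,CGGHB,cough,ST42,1
CGGHB.cough,CGGHB,cough,BL64,1
CGGHB.cough,CGGHB,cough,SI4,1
CGGHB.cough,CGGHB,cough,KI3,1
CGGHB.cough,CGGHB,cough,LR3,1
CGGHB.cough,CGGHB,cough,PC7,1
CGGHB.cough,CGGHB,cough,BL15,1
CGGHB.cough,CGGHB,cough,BL20,1
CGGHB.cough,CGGHB,cough,BL23,1
CGGHB.cough,CGGHB,cough,SP6,1
CGGHB.cough,CGGHB,cough,CV12,1
CGGHB.cough,CGGHB,cough,CV4,1
CGGHB.cough,CGGHB,cough,GV4,1
CGGHB.cough,CGGHB,cough,KI7,1
CGGHB.cough,CGGHB,cough,LI11,1
CGGHB.cough,CGGHB,cough,ST40,1
CGGHB.cough,CGGHB,cough,BL17,1
CGGHB.cough,CGGHB,cough,GB21,1
CGGHB.cough,CGGHB,cough,SI11,1
CGGHB.cough,CGGHB,cough,TE5,1
CGGHB.cough,CGGHB,cough,GB34,1
CGGHB.cough,CGGHB,cough,LR8,1
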