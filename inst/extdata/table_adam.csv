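row,class,precision,recall,f1,support
class,TUMOUR,1.00,1.00,1.00,10
class,STROMA,0.88,0.88,0.88,8
class,COMPLEX,0.88,1.00,0.93,7
class,LYMPHO,1.00,1.00,1.00,10
class,DEBRIS,0.80,0.80,0.80,5
class,MUCOSA,1.00,1.00,1.00,6
class,ADIPOSE,1.00,0.91,0.95,11
class,EMPTY,1.00,1.00,1.00,7
aggregate,Micro average,0.95,0.95,0.95,64
aggregate,Macro average,0.94,0.95,NA,64
aggregate,Weighted average,0.96,0.95,0.95,64
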