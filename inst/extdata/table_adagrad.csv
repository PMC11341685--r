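row,class,precision,recall,f1,support
class,TUMOUR,1.00,1.00,1.00,9
class,STROMA,0.43,0.75,0.55,4
class,COMPLEX,0.91,1.00,0.95,10
class,LYMPHO,1.00,1.00,1.00,2
class,DEBRIS,1.00,0.86,0.92,7
class,MUCOSA,0.92,1.00,0.96,11
class,ADIPOSE,1.00,0.70,0.82,10
class,EMPTY,1.00,0.91,0.95,11
aggregate,Micro average,0.91,0.91,0.91,64
aggregate,Macro average,0.91,0.90,0.89,64
aggregate,Weighted average,0.94,0.92,0.92,64
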