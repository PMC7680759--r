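effect_class,treatment,dose,n_wells,n_plates,significant,p_value
Diverse functions,NaBu,50 mM,16,2,Yes,0.011
Short chain fatty acids,Acetic acid,100 mM,16,2,No,0.408
DNA damage,Celastrol,20 uM,16,2,Yes,0.013
DNA damage,Cycloheximide,50 uM,16,2,Yes,0.013
DNA damage,Teniposide,500 uM,16,2,Borderline,0.041
Cell cycle delay,Bortezomib,1 uM,16,2,Borderline,0.047
Cell cycle delay,MG132,50 uM,16,2,Borderline,0.047
Cell cycle delay,Trametinib,250 nM,16,2,No,0.096
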