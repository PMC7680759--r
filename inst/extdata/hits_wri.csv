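effect_class,treatment,dose,n_wells,n_plates,significant,p_value
Diverse functions,NaBu,50 mM,16,2,Yes,< 0.001
Short chain fatty acids,Acetic acid,100 mM,16,2,Borderline,0.047
Short chain fatty acids,Propionic acid,10 mM,16,2,No,0.769
Short chain fatty acids,Valeric acid,5 mM,16,2,No,0.926
Chromatin modification,Quisinostat,1 uM,16,2,No,0.235
Chromatin modification,Trichostatin A,10 uM,16,2,No,0.696
Chromatin modification,Vorinostat/SAHA,75 uM,16,2,No,0.913
Chromatin modification,CUDC-101,250 uM,16,2,No,0.610
DNA damage,Celastrol,20 uM,16,2,Yes,0.001
DNA damage,Rotenone,10 uM,16,2,No,0.149
DNA damage,Cisplatin,100 uM,16,2,No,0.065
DNA damage,Camptothecin,50 uM,16,2,No,0.059
DNA damage,Teniposide,500 uM,16,2,Yes,< 0.001
DNA damage,Cycloheximide,50 uM,16,2,Yes,< 0.001
Cell cycle delay,Colchicine,2.5 uM,16,2,No,0.967
Cell cycle delay,Griseofulvin,300 uM,16,2,No,0.675
Cell cycle delay,Taxol,1 uM,16,2,No,0.774
Cell cycle delay,Apcin,300 uM,16,2,No,0.061
Cell cycle delay,TAME,20 mM,16,2,No,0.410
Cell cycle delay,Flavopiridol,10 uM,16,2,No,0.360
Cell cycle delay,Roscovitine,100 uM,16,2,No,0.175
Cell cycle delay,Bortezomib,1 uM,16,2,Yes,0.005
Cell cycle delay,MG132,50 uM,16,2,Yes,0.001
Cell cycle delay,Trametinib,250 nM,16,2,Yes,0.002
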