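experiment,strain,cross,hatch_rate_pct,eggs,females
mass-mating,wRi,control-cross,89,606,31
mass-mating,wRi,ci-control,10,712,41
mass-mating,wRi,rescue-control,92,575,35
mass-mating,wMel,control-cross,89,561,41
mass-mating,wMel,ci-control,4,546,38
mass-mating,wMel,rescue-control,92,820,42
single-pair,wRi,control-cross,90,679,35
single-pair,wRi,ci-control,10,672,43
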