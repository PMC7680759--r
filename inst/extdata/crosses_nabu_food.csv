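experiment,strain,condition,hatch_rate_pct,eggs,females
mass-mating,wRi,ci-control,10,454,30
mass-mating,wRi,ci-nabu,16,292,21
mass-mating,wMel,ci-control,4,382,29
mass-mating,wMel,ci-nabu,11,544,40
single-pair,wRi,ci-control,10,771,30
single-pair,wRi,ci-nabu,19,724,32
single-pair,wRi,rescue-control,94,741,30
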