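study_id,experiment_id,domain,x,y,z
smith2001,smith2001_1,pain,-2,4,6
smith2001,smith2001_1,pain,0,-30,22
jones2005,jones2005_1,touch,-14,8,50
smith2001,smith2001_1,pain,10,12,-8
jones2005,jones2005_1,touch,22,-6,-12
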