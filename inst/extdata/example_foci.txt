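// Study: smith2001
// Experiment: smith2001_1
// Domain: pain
-2	4	6
0	-30	22
10	12	-8

// Study: jones2005
// Experiment: jones2005_1
// Domain: touch;attention
-14	8	50
22	-6	-12
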