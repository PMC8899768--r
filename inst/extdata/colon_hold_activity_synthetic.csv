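"hold_h","normalized_activity","source"
0,1,"synthetic flat reconstruction of the stable colonic hold curve"
6,1,"synthetic flat reconstruction of the stable colonic hold curve"
16,1,"synthetic flat reconstruction of the stable colonic hold curve"
24,1,"synthetic flat reconstruction of the stable colonic hold curve"
40,1,"synthetic flat reconstruction of the stable colonic hold curve"
48,1,"synthetic flat reconstruction of the stable colonic hold curve"
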