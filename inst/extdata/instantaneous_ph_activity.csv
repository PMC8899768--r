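"ph","normalized_activity","sd","source"
3,0.04,0.002,"measured instantaneous activity after acid exposure"
3.5,0.04,0.003,"measured instantaneous activity after acid exposure"
4,0.24,0.007,"measured instantaneous activity after acid exposure"
4.5,0.28,0.006,"measured instantaneous activity after acid exposure"
5,0.3,0.002,"measured instantaneous activity after acid exposure"
5.5,0.47,0.02,"measured instantaneous activity after acid exposure"
6,0.52,0.02,"measured instantaneous activity after acid exposure"
6.5,0.71,0.11,"measured instantaneous activity after acid exposure"
7,1,0.03,"measured instantaneous activity after acid exposure"
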