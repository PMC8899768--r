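"o2_fraction","normalized_activity","sd","source"
0,0.74,0.05,"measured activity vs ambient oxygen"
0.07,0.79,0.29,"measured activity vs ambient oxygen"
0.21,1,0.01,"measured activity vs ambient oxygen"
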