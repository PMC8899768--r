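"stage","time_h","rate_umol_h_per_1e9_cells","sd","source"
"SGF",1,1.35,0.04,"measured in vitro GI simulation rates"
"SGF",2,1.52,0.08,"measured in vitro GI simulation rates"
"SIF",2,0.88,0.04,"measured in vitro GI simulation rates"
"SCF",0,0.2,0.14,"measured in vitro GI simulation rates"
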