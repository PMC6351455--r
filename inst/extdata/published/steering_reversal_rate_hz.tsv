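difficulty	back0	back1	back2	back3	back4
construction	0.012	0.012	0.017	0.013	0.018
non_construction	0.011	0.008	0.012	0.009	0.010
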