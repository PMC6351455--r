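difficulty	back0	back1	back2	back3	back4
construction	0.01	0.05	0.07	0.21	0.17
non_construction	0.01	0.02	0.13	0.05	0.08
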