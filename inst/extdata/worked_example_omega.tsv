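parent	child	relation	omega
GO:0000001	GO:0000002	is_a	0.85
GO:0000001	GO:0000003	is_a	0.98
GO:0000002	GO:0000004	is_a	0.97
GO:0000003	GO:0000004	is_a	0.84
GO:0000003	GO:0000005	is_a	0.71
GO:0000004	GO:0000006	is_a	0.65
GO:0000004	GO:0000007	is_a	0.71
GO:0000005	GO:0000007	is_a	0.72
GO:0000006	GO:0000008	is_a	0.67
GO:0000007	GO:0000008	is_a	0.84
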