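term	label	ic
GO:0000001	t1	0
GO:0000002	t2	0.01
GO:0000003	t3	0.02
GO:0000004	t4	0.04
GO:0000005	t5	0.05
GO:0000006	t6	0.07
GO:0000007	t7	0.09
GO:0000008	t8	0.18
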