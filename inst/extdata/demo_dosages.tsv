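sample_id	rs1001	rs1002	rs1003	rs1004	rs1005
ind01	0	1	1.82	0.4	2
ind02	1	0	0.96	1.1	1.7
ind03	2	0	1.04	0.2	2
ind04	1	1	0.13	1.9	1.9
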