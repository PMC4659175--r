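probe_id	infinium_type	chromosome	position	snp_in_cpg	snp_position	alt_base	freq_EUR	freq_EAS
cg04287289	II	chr16	46033	0	NA	NA	NA	NA
cg26513180	I	chr16	46041	0	NA	NA	NA	NA
cg26367031	II	chr3	128816	0	NA	NA	NA	NA
cg00862290	II	chr3	129042	0	NA	NA	NA	NA
cg23556238	II	chr7	89320	1	1	T	0.20	0.70
cg16310958	I	chr12	55187	1	2	A	0.15	0.65
cg10428733	I	chr2	201455	1	1	T	0.25	0.75
cg14175932	II	chr5	332018	1	1	T	0.30	0.80
cgx_clean	I	chr11	77210	0	NA	NA	NA	NA
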