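snp_id	p1	p2
rs_sim_001	0.20	0.70
rs_sim_002	0.15	0.65
rs_sim_003	0.25	0.75
rs_sim_004	0.30	0.80
rs_sim_005	0.05	0.55
rs_sim_006	0.40	0.90
rs_sim_007	0.10	0.45
rs_sim_008	0.35	0.60
rs_sim_009	0.50	0.85
rs_sim_010	0.12	0.52
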