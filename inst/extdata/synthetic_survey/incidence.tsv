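plant_id	OTU_001	OTU_002	OTU_003	OTU_004	OTU_005	OTU_006	OTU_007	OTU_008	OTU_009	OTU_010	OTU_011	OTU_012	OTU_013	OTU_014	OTU_015	OTU_016	OTU_017	OTU_018	OTU_019	OTU_020
plant_01	0	0	1	0	0	0	1	0	0	0	0	0	0	1	1	1	0	0	0	0
plant_02	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
plant_03	0	1	1	0	1	0	0	0	1	1	1	0	0	0	0	0	0	0	1	0
plant_04	0	0	1	0	1	0	1	0	0	0	0	0	0	0	1	0	1	1	0	1
plant_05	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	1	1	0	0
plant_06	0	1	0	0	1	1	0	0	1	1	0	0	0	0	1	0	0	0	1	0
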