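community_id	plant_id
comm_01	plant_02
comm_01	plant_03
comm_01	plant_06
comm_02	plant_04
comm_02	plant_05
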