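plant_id	family	locality	n_specimens
plant_01	Triuridaceae	loc_04	1
plant_02	Triuridaceae	loc_01	3
plant_02	Triuridaceae	loc_02	3
plant_03	Burmanniaceae	loc_02	5
plant_04	Burmanniaceae	loc_03	1
plant_05	Burmanniaceae	loc_03	4
plant_06	Burmanniaceae	loc_02	3
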