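(((plant_06:0.48032696005,plant_01:0.48032696005):0.0328843884128,((plant_02:0.166747619002,plant_03:0.166747619002):0.0795148766498,plant_04:0.246262495652):0.266948852812):0.486788651537,plant_05:1);
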