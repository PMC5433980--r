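(((OTU_016:0.555378757265,OTU_020:0.555378757265):0.258641389951,(OTU_011:0.488683943377,OTU_008:0.488683943377):0.32533620384):0.185979852784,((OTU_009:0.849211239868,((OTU_005:0.115394276632,OTU_003:0.115394276632):0.405525119988,(OTU_002:0.123209967747,((OTU_018:0.0386831806471,OTU_007:0.0386831806471):0.0709248339315,OTU_014:0.109608014579):0.0136019531684):0.397709428873):0.328291843248):0.062534769078,((((OTU_013:0.119363602059,OTU_010:0.119363602059):0.249599413441,((OTU_017:0.0109759965448,OTU_004:0.0109759965448):0.246821924953,OTU_019:0.257797921498):0.111165094002):0.158237263062,(OTU_012:0.224940639924,(OTU_001:0.196680101192,OTU_015:0.196680101192):0.028260538732):0.302259638637):0.0206157973518,OTU_006:0.547816075913):0.363929933033):0.0882539910542);
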